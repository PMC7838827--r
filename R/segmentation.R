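# Two-state HMM genome segmentation with a Poisson-log-normal emission.
# The emission likelihood P(k | mu, sigma) = E_Z[ Pois(k; exp(mu + sigma Z)) ]
# is integrated by Gauss-Hermite quadrature; Baum-Welch fits the model and
# Viterbi decoding turns maximal runs of the transcribed state into
# transcription units (TUs).

log_sum_exp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# log P(k | mu, sigma) for a vector of counts k, by Gauss-Hermite quadrature
# over the log-normal mixing density (nodes for the e^{-x^2} weight).
pln_logdens <- function(k, mu, sigma, gh) {
  lam <- exp(mu + sqrt(2) * sigma * gh$x)          # one rate per node
  lp <- outer(k, lam, function(kk, ll) dpois(kk, ll, log = TRUE))
  lw <- matrix(log(gh$w) - 0.5 * log(pi), nrow = length(k),
               ncol = length(lam), byrow = TRUE)
  log_sum_exp(lp + lw)
}

# Gather observation vectors out of the accepted coverage inputs: a
# binned_coverage (both strands), a list of them, a numeric vector, or a
# list of numeric vectors. Returns a named list of integer vectors.
coverage_obs <- function(coverage) {
  if (inherits(coverage, "binned_coverage")) {
    obs <- c(imap(coverage$plus, function(v, ch) v),
             imap(coverage$minus, function(v, ch) v))
    names(obs) <- c(paste0(names(coverage$plus), "/+"),
                    paste0(names(coverage$minus), "/-"))
    return(obs)
  }
  if (is.numeric(coverage)) return(list(seq1 = as.integer(coverage)))
  if (is.list(coverage) && all(map_lgl_(coverage, inherits, "binned_coverage"))) {
    out <- list()
    for (cv in coverage) {
      o <- coverage_obs(cv)
      names(o) <- paste0(cv$sample_id, "/", names(o))
      out <- c(out, o)
    }
    return(out)
  }
  if (is.list(coverage) && all(map_lgl_(coverage, is.numeric))) {
    return(map(coverage, as.integer))
  }
  abort("unsupported coverage input for segmentation")
}

map_lgl_ <- function(x, f, ...) vapply(x, f, logical(1), ...)

#' Fit a two-state Poisson-log-normal HMM to binned coverage
#'
#' Baum-Welch EM on the concatenated bins. The emission likelihood is
#' computed by fixed-node Gauss-Hermite quadrature over the log-normal
#' mixing density; the emission M-step is a numerical maximization of the
#' expected complete-data log-likelihood per state. States are ordered so
#' state 2 ("transcribed") has the larger marginal emission mean.
#'
#' @param coverage A [binned_coverage()], a list of them, or numeric count
#'   vector(s). All strands/chromosomes are concatenated for fitting.
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood gain drops to `tol` or below.
#' @param seed Seed for the k-means initialization.
#' @param n_nodes Gauss-Hermite node count.
#' @param sigma_floor Lower bound on the emission log-sd (avoids collapse to
#'   a pure Poisson).
#' @return An object of class `pln_hmm` with elements `transition` (2x2
#'   row-stochastic), `emission` (tibble: state, meanlog, sdlog, mean),
#'   `init`, `loglik_trace` (non-decreasing), `n_iter`, `converged`.
#' @export
fit_hmm <- function(coverage, max_iter = 100L, tol = 1e-4, seed = 1L,
                    n_nodes = 20L, sigma_floor = 1e-3) {
  obs <- coverage_obs(coverage)
  x <- unlist(obs, use.names = FALSE)
  if (length(x) < 100) abort("need at least 100 bins to fit the HMM")
  if (all(x == 0)) {
    abort("coverage is all zero; skip segmentation for this input")
  }
  gh <- pracma::gaussHermite(n_nodes)

  # --- initialization: k-means on log(1 + count) -------------------------
  km <- with_seed(seed, kmeans(log1p(x), centers = 2, nstart = 5))
  ord <- order(km$centers)
  cl <- match(km$cluster, ord)
  m1 <- max(mean(x[cl == 1]), 1e-3)
  m2 <- max(mean(x[cl == 2]), m1 * 1.5)
  mu <- c(log(m1), log(m2))
  sigma <- c(0.5, 0.5)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  pi0 <- c(mean(cl == 1), mean(cl == 2))
  pi0 <- pmax(pi0, 1e-6); pi0 <- pi0 / sum(pi0)

  u <- sort(unique(x))
  idx <- match(x, u)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  n_iter <- 0L

  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    logB_u <- cbind(pln_logdens(u, mu[1], sigma[1], gh),
                    pln_logdens(u, mu[2], sigma[2], gh))
    fb <- forward_backward(idx, logB_u, A, pi0)
    trace <- c(trace, fb$loglik)
    gain <- fb$loglik - prev
    if (gain <= tol) { converged <- TRUE; break }
    prev <- fb$loglik

    # --- M-step ----------------------------------------------------------
    A <- fb$xi / rowSums(fb$xi)
    pi0 <- fb$gamma1 / sum(fb$gamma1)
    W <- rowsum(fb$gamma, group = idx)           # unique-count weights
    for (s in 1:2) {
      w <- W[, s]
      objective <- function(par) {
        sg <- max(exp(par[2]), sigma_floor)
        -sum(w * pln_logdens(u, par[1], sg, gh))
      }
      fit <- optim(c(mu[s], log(max(sigma[s], sigma_floor))), objective,
                   method = "Nelder-Mead", control = list(maxit = 60))
      mu[s] <- fit$par[1]
      sigma[s] <- max(exp(fit$par[2]), sigma_floor)
    }
  }

  # order states by marginal emission mean: state 2 = transcribed
  mean_emis <- exp(mu + sigma^2 / 2)
  if (mean_emis[1] > mean_emis[2]) {
    mu <- rev(mu); sigma <- rev(sigma); pi0 <- rev(pi0)
    A <- A[2:1, 2:1]
    mean_emis <- rev(mean_emis)
  }
  structure(list(
    transition = A, init = pi0,
    emission = tibble(state = c("untranscribed", "transcribed"),
                      meanlog = mu, sdlog = sigma, mean = mean_emis),
    loglik_trace = trace, n_iter = n_iter, converged = converged,
    n_nodes = n_nodes
  ), class = "pln_hmm")
}

# Scaled forward-backward over one concatenated sequence. logB_u: unique
# counts x 2 state log-densities; idx maps positions to unique counts.
forward_backward <- function(idx, logB_u, A, pi0) {
  Tn <- length(idx)
  lB <- logB_u[idx, , drop = FALSE]
  rmax <- pmax(lB[, 1], lB[, 2])
  B <- exp(lB - rmax)                            # per-bin relative emissions
  alpha <- matrix(0, Tn, 2)
  cvec <- numeric(Tn)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  tA <- t(A)
  for (t in 2:Tn) {
    a <- (tA %*% alpha[t - 1, ])[, 1] * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, 2)
  beta[Tn, ] <- 1
  xi <- matrix(0, 2, 2)
  for (t in (Tn - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    xi_t <- A * (alpha[t, ] %o% bb)
    xi <- xi + xi_t / sum(xi_t)
    b <- (A %*% bb)[, 1]
    beta[t, ] <- b / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = sum(log(cvec)) + sum(rmax), gamma = gamma,
       gamma1 = gamma[1, ], xi = xi)
}

#' @export
print.pln_hmm <- function(x, ...) {
  cat(sprintf("<pln_hmm> 2-state Poisson-log-normal HMM, %d EM iteration(s)%s\n",
              x$n_iter, if (x$converged) " (converged)" else ""))
  cat(sprintf("  emission means: %.4g (untranscribed) / %.4g (transcribed)\n",
              x$emission$mean[1], x$emission$mean[2]))
  invisible(x)
}

#' @export
tidy.pln_hmm <- function(x, ...) {
  bind_cols(x$emission,
            tibble(p_stay = diag(x$transition), p_init = x$init))
}

#' @export
glance.pln_hmm <- function(x, ...) {
  tibble(logLik = tail(x$loglik_trace, 1), n_iter = x$n_iter,
         converged = x$converged,
         mean_ratio = x$emission$mean[2] / x$emission$mean[1])
}

#' Viterbi-decode transcription units
#'
#' Runs Viterbi decoding per chromosome and strand with the shared model;
#' each maximal run of the "transcribed" state becomes one TU with
#' bin-resolution boundaries. Ties in the dynamic program prefer the
#' untranscribed state (conservative calls).
#'
#' @param coverage A [binned_coverage()].
#' @param model A fitted [fit_hmm()] model.
#' @return Tibble of TUs: `chrom`, `start`, `end`, `strand`, `tu_id`.
#' @export
decode_tus <- function(coverage, model) {
  stopifnot(inherits(coverage, "binned_coverage"), inherits(model, "pln_hmm"))
  gh <- pracma::gaussHermite(model$n_nodes)
  w <- coverage$layout$bin_width
  out <- list()
  for (strand in c("+", "-")) {
    vecs <- if (strand == "+") coverage$plus else coverage$minus
    for (ch in names(vecs)) {
      path <- viterbi_path(vecs[[ch]], model, gh)
      r <- rle(path == 2L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      if (length(keep) == 0) next
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = (starts[keep] - 1L) * w,
        end = ends[keep] * w,
        strand = strand
      )
    }
  }
  tus <- if (length(out) > 0) {
    arrange(list_rbind(out), .data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character())
  }
  tus$tu_id <- if (nrow(tus) > 0) sprintf("TU%05d", seq_len(nrow(tus))) else character(0)
  tus
}

viterbi_path <- function(x, model, gh = pracma::gaussHermite(model$n_nodes)) {
  u <- sort(unique(x))
  idx <- match(x, u)
  logB_u <- cbind(pln_logdens(u, model$emission$meanlog[1], model$emission$sdlog[1], gh),
                  pln_logdens(u, model$emission$meanlog[2], model$emission$sdlog[2], gh))
  lA <- log(model$transition)
  Tn <- length(x)
  delta <- logB_u[idx[1], ] + log(model$init)
  psi <- matrix(1L, Tn, 2)
  dmat <- matrix(0, Tn, 2)
  dmat[1, ] <- delta
  for (t in 2:Tn) {
    for (s in 1:2) {
      cand <- dmat[t - 1, ] + lA[, s]
      # tie -> untranscribed predecessor (state 1)
      best <- if (cand[1] >= cand[2]) 1L else 2L
      psi[t, s] <- best
      dmat[t, s] <- cand[best] + logB_u[idx[t], s]
    }
  }
  path <- integer(Tn)
  path[Tn] <- if (dmat[Tn, 1] >= dmat[Tn, 2]) 1L else 2L
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Merge nearby transcription units
#'
#' Same-strand TUs separated by at most `max_gap_bp` are merged (the paper's
#' one-bin bridging of mappability/expression dropouts in non-coding calls).
#' With `scope = "noncoding"` and a `class` column present, mRNA TUs are
#' left untouched.
#'
#' @param tus TU tibble (sorted or not).
#' @param max_gap_bp Maximal gap to bridge, inclusive (default one 200-bp bin).
#' @param scope `"noncoding"` (default) or `"all"`.
#' @return TU tibble with merged records; `tu_id` regenerated, constituent
#'   classes carried in `class` when unambiguous (else "unclassified").
#' @export
merge_gaps <- function(tus, max_gap_bp = 200, scope = c("noncoding", "all")) {
  scope <- match.arg(scope)
  if (nrow(tus) == 0) return(tus)
  eligible <- if (scope == "noncoding" && "class" %in% names(tus)) {
    tus$class != "mRNA"
  } else rep(TRUE, nrow(tus))
  keep_as_is <- tus[!eligible, , drop = FALSE]
  mergeable <- tus[eligible, , drop = FALSE]
  merged <- list_rbind(map(split(mergeable, paste(mergeable$chrom, mergeable$strand)),
    function(g) {
      g <- arrange(g, .data$start)
      grp <- cumsum(c(1, as.integer(g$start[-1] - g$end[-nrow(g)] > max_gap_bp)))
      summarise(group_by(g, grp = grp),
                chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), strand = first(.data$strand),
                class = if ("class" %in% names(g)) {
                  cls <- unique(.data$class)
                  if (length(cls) == 1) cls else "unclassified"
                } else NA_character_,
                .groups = "drop") |>
        select(-"grp")
    }))
  out <- bind_rows(keep_as_is, merged)
  if (!"class" %in% names(tus)) out$class <- NULL
  out <- arrange(out, .data$chrom, .data$start)
  out$tu_id <- sprintf("TU%05d", seq_len(nrow(out)))
  out
}

#' Refine TU boundaries to bp precision
#'
#' For each TU boundary, a two-segment piecewise-constant curve is fitted to
#' per-bp coverage within the window spanned by the two bins around the
#' initial boundary, and the boundary moves to the change-point minimizing
#' the residual sum of squares. A boundary never moves farther than the
#' window; with flat coverage (no improving change-point) it is unchanged.
#'
#' @param tus TU tibble.
#' @param bp_coverage List with `plus` and `minus` components, each a named
#'   list (by chromosome) of per-bp coverage vectors.
#' @param window_bp Half-window around each boundary (default one bin).
#' @return TU tibble with adjusted `start`/`end`.
#' @export
refine_boundaries <- function(tus, bp_coverage, window_bp = 200) {
  if (nrow(tus) == 0) return(tus)
  for (i in seq_len(nrow(tus))) {
    vec <- if (tus$strand[i] == "-") bp_coverage$minus[[tus$chrom[i]]] else
      bp_coverage$plus[[tus$chrom[i]]]
    for (side in c("start", "end")) {
      b <- tus[[side]][i]
      lo <- max(0, b - window_bp)
      hi <- min(length(vec), b + window_bp)
      if (hi - lo < 4) next
      y <- vec[(lo + 1):hi]
      cp <- best_changepoint(y)
      if (!is.na(cp)) tus[[side]][i] <- lo + cp
    }
    if (tus$end[i] <= tus$start[i]) {           # degenerate refinement
      tus$end[i] <- tus$start[i] + 1L
    }
  }
  tus
}

# Index c (1-based offset; segment split [1..c] / [c+1..n]) minimizing the
# two-segment constant-fit RSS, or NA when no split beats a single constant.
best_changepoint <- function(y) {
  n <- length(y)
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  c_all <- seq_len(n - 1)
  ss1 <- cs2[c_all] - cs[c_all]^2 / c_all
  n2 <- n - c_all
  s2 <- cs[n] - cs[c_all]
  ss2 <- (cs2[n] - cs2[c_all]) - s2^2 / n2
  rss <- ss1 + ss2
  rss0 <- cs2[n] - cs[n]^2 / n
  best <- which.min(rss)
  if (rss[best] < rss0 - 1e-9) best else NA_integer_
}
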