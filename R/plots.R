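# ggplot2 views of the main result types.

#' @export
autoplot.pln_hmm <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loglik_trace),
               logLik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$logLik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = "Baum-Welch log-likelihood trace",
                  x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' Histogram of directionality scores
#'
#' @param scores Output of [promoter_directionality()] or
#'   [enhancer_directionality()].
#' @return A ggplot object (log2-ratio histogram over scored features).
#' @export
plot_directionality <- function(scores) {
  df <- filter(scores, is.finite(.data$ratio), .data$ratio > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ratio))) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 directionality ratio", y = "features") +
    ggplot2::theme_minimal()
}

#' Cell-type specificity score distribution
#'
#' @param spec Output of [specificity_scores()].
#' @return A ggplot object.
#' @export
plot_specificity <- function(spec) {
  ggplot2::ggplot(filter(spec, !is.na(.data$specificity)),
                  ggplot2::aes(x = .data$specificity)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0, fill = "darkorange",
                            color = "grey30") +
    ggplot2::labs(x = "overall cell-type specificity (0 = uniform, 1 = single line)",
                  y = "features") +
    ggplot2::theme_minimal()
}

#' Distance distribution of E-P pairs by method
#'
#' @param pairs One or more EPPair tibbles (rows bound together).
#' @return A ggplot object.
#' @export
plot_pair_distances <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$distance / 1000,
                                      fill = .data$method)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "enhancer-promoter distance (kbp)", y = "pairs") +
    ggplot2::theme_minimal()
}
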