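# End-to-end orchestration: generate -> segment -> classify -> annotate ->
# score -> pair -> enrich, driven by one config with a single master seed.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with the defaults used
#' throughout: FPK activity cutoffs (mean 20 / replicate 15 / pairing 30),
#' the classification rule distances, the correlation cutoff (0.6), the
#' pairing window (500 kbp), and resampling depths. The config round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chrom,chrom_length_bp,n_genes,n_enhancer_states Genome size.
#' @param n_cell_lines,n_replicates Experimental design.
#' @param frac_specific Fraction of single-line enhancers in the truth.
#' @param coupling E-P activity coupling coefficient.
#' @param background Background transcription rate per bin.
#' @param fpk_active_mean,fpk_active_replicate,fpk_promoter_pairing FPK
#'   thresholds (20 / 15 / 30).
#' @param min_r Pairing correlation cutoff (strict >).
#' @param pairing_window Pairing window, bp.
#' @param n_ep_null_sets,n_snp_null_sets Matched-null resample counts.
#' @param hmm_max_iter,hmm_tol,hmm_fit_bins HMM fitting controls
#'   (`hmm_fit_bins` caps the number of bins used for fitting; decoding
#'   always runs genome-wide).
#' @param rules A [classification_rules()] list.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_chrom = 1L, chrom_length_bp = 10e6,
                            n_genes = 100L, n_enhancer_states = 150L,
                            n_cell_lines = 14L, n_replicates = 2L,
                            frac_specific = 0.37, coupling = 0.8,
                            background = 0.05,
                            fpk_active_mean = 20, fpk_active_replicate = 15,
                            fpk_promoter_pairing = 30,
                            min_r = 0.6, pairing_window = 5e5,
                            n_ep_null_sets = 100L, n_snp_null_sets = 1000L,
                            hmm_max_iter = 50L, hmm_tol = 1e-3,
                            hmm_fit_bins = 20000L,
                            rules = classification_rules()) {
  cfg <- as.list(environment())
  num <- unlist(cfg[setdiff(names(cfg), c("rules", "seed", "background"))])
  if (any(num <= 0)) abort("all pipeline thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$rules <- unclass(lst$rules)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$rules <- do.call(classification_rules, lst$rules)
  do.call(pipeline_config, lst)
}

#' Run the full enhancer-annotation pipeline on synthetic data
#'
#' Executes every stage on generated data: genome + truth simulation,
#' per-cell-line segmentation of pooled replicate coverage, TU
#' classification, eRNA and enhancer annotation, cross-line union merge,
#' quantification and normalization, specificity scoring, E-P pairing by
#' all three strategies, and the enrichment analyses (super-enhancers,
#' interaction support with matched nulls, SNP enrichment). Deterministic
#' given the config (stage seeds derive from the master seed); every
#' result component is hash-logged.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory to write result tables to.
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_result` (see components in the
#'   vignette), including `hashes` and `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  log <- list()
  say <- function(stage, ...) {
    msg <- sprintf(...)
    log[[length(log) + 1]] <<- list(stage = stage, message = msg,
                                    elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # -- simulate ----------------------------------------------------------
  genome <- stage("simulate", generate_genome(
    n_chrom = config$n_chrom, chrom_length_bp = config$chrom_length_bp,
    n_genes = config$n_genes, n_enhancer_states = config$n_enhancer_states,
    seed = derive_seed(config$seed, "genome")))
  truth <- stage("simulate", generate_programs(
    genome, n_cell_lines = config$n_cell_lines,
    frac_specific = config$frac_specific, coupling = config$coupling,
    n_replicates = config$n_replicates,
    seed = derive_seed(config$seed, "programs")))
  coverage <- stage("simulate", simulate_coverage(
    genome, truth, seed = derive_seed(config$seed, "coverage"),
    background = config$background))
  ancillary <- stage("simulate", simulate_ancillary(
    genome, truth, seed = derive_seed(config$seed, "ancillary")))
  say("simulate", "%d genes, %d states, %d samples", nrow(genome$genes),
      nrow(genome$states), length(coverage))

  sample_lines <- setNames(truth$samples$line, truth$samples$sample)

  # -- normalization (size factors on gene counts) -----------------------
  gene_counts <- stage("normalize", sapply(coverage, function(cv) {
    count_fragments(genome$genes, cv, "sense")
  }))
  rownames(gene_counts) <- genome$genes$gene_id
  sf <- stage("normalize", size_factors(gene_counts))
  gene_act <- stage("normalize", fpk(gene_counts, sf,
                                     genome$genes$end - genome$genes$start,
                                     sample_lines))
  say("normalize", "size factors in [%.3g, %.3g]", min(sf), max(sf))

  # -- segmentation + annotation per cell line ---------------------------
  rules <- config$rules
  lines <- truth$lines
  per_line <- map(setNames(nm = lines), function(line) {
    reps <- truth$samples$sample[truth$samples$line == line]
    pooled <- pool_coverage(coverage[reps], sample_id = line)
    pooled_sf <- sum(sf[reps])
    obs <- unlist(c(pooled$plus, pooled$minus), use.names = FALSE)
    fit_obs <- if (length(obs) > config$hmm_fit_bins) {
      obs[seq_len(config$hmm_fit_bins)]   # contiguous chunk keeps run structure
    } else obs
    model <- stage("segment", fit_hmm(fit_obs, max_iter = config$hmm_max_iter,
                                      tol = config$hmm_tol,
                                      seed = derive_seed(config$seed, paste0("hmm_", line))))
    tus <- stage("segment", decode_tus(pooled, model))
    tus <- stage("classify", classify_tus(tus, genome$genes, genome$exons, rules))
    tus <- stage("classify", merge_gaps(tus, scope = "noncoding"))
    tus <- stage("classify", classify_tus(tus, genome$genes, genome$exons, rules))
    # expression filter: replicate-averaged FPK >= 20, each replicate >= 15
    tu_counts <- sapply(coverage[reps], function(cv) count_fragments(tus, cv, "sense"))
    if (is.null(dim(tu_counts))) tu_counts <- matrix(tu_counts, nrow = nrow(tus))
    tu_fpk <- sweep(sweep(tu_counts, 2, sf[reps], "/"), 1,
                    (tus$end - tus$start) / 1000, "/")
    expressed <- rowMeans(tu_fpk) >= config$fpk_active_mean &
      apply(tu_fpk, 1, function(r) all(r >= config$fpk_active_replicate))
    ernas <- stage("annotate", call_ernas(tus[expressed & tus$class %in% c("asRNA", "intergenic"), ],
                                          genome$states, genome$genes, rules = rules))
    ernas <- stage("annotate", filter_antisense(ernas, tus, pooled, pooled_sf, rules))
    pairs_bd <- stage("annotate", pair_bidirectional(ernas, tus, rules))
    ernas_final <- filter(ernas, .data$kind == "antisense" |
                            .data$erna_id %in% pairs_bd$erna_id |
                            .data$tu_id %in% pairs_bd$partner_id)
    enh <- stage("annotate", define_enhancers(pairs_bd, ernas_final,
                                              layout = genome$layout))
    list(model = model, tus = tus, ernas = ernas_final, enhancers = enh)
  })
  say("annotate", "per-line enhancers: %s",
      paste(map_int(per_line, ~ nrow(.x$enhancers)), collapse = "/"))

  # -- union annotation + quantification ---------------------------------
  merged_enh <- stage("merge", merge_across_cell_lines(
    map(per_line, "enhancers")))
  merged_ernas <- stage("merge", merge_across_cell_lines(
    map(per_line, function(x) mutate(x$ernas, kind = .data$kind))))
  enh_act <- stage("quantify", quantify_enhancers(merged_enh, coverage, sf,
                                                  sample_lines))
  say("quantify", "%d merged enhancers, %d merged eRNAs",
      nrow(merged_enh), nrow(merged_ernas))

  # -- scores ------------------------------------------------------------
  enh_spec <- stage("score", specificity_scores(enh_act$by_line))
  gene_spec <- stage("score", specificity_scores(gene_act$by_line))

  # -- pairing -----------------------------------------------------------
  prom_fpk <- gene_act$by_line
  active_any <- apply(prom_fpk, 1, max) >= config$fpk_promoter_pairing
  promoters_active <- genome$genes[active_any, , drop = FALSE]
  pairs_n <- stage("pair", pair_nearest(merged_enh, promoters_active,
                                        config$pairing_window))
  pairs_cn <- stage("pair", pair_correlated_neighboring(
    merged_enh, promoters_active, enh_act$by_line, prom_fpk,
    config$min_r, config$pairing_window))
  pairs_cw <- stage("pair", pair_correlated_window(
    merged_enh, promoters_active, enh_act$by_line, prom_fpk,
    config$min_r, config$pairing_window, keep_all = TRUE))
  say("pair", "N/CN/CW pairs: %d/%d/%d", nrow(pairs_n), nrow(pairs_cn),
      nrow(pairs_cw))

  # -- enrichment --------------------------------------------------------
  ses <- stage("enrich", call_super_enhancers(ancillary$peaks))
  promoters_cov <- mutate(promoters_active,
                          activity = apply(prom_fpk[active_any, , drop = FALSE], 1, max),
                          specificity = gene_spec$specificity[match(
                            .data$gene_id, gene_spec$feature)])
  promoters_cov$specificity[is.na(promoters_cov$specificity)] <- 0
  ep_null <- stage("enrich", sample_matched_ep_nulls(
    pairs_cn, merged_enh, promoters_cov, ancillary$interactions,
    genome$layout, genome$genes, n_sets = config$n_ep_null_sets,
    seed = derive_seed(config$seed, "ep_null")))
  snp_null <- stage("enrich", sample_matched_snp_nulls(
    filter(ancillary$snps, .data$set == "trait"),
    filter(ancillary$snps, .data$set == "background"),
    merged_enh, n_sets = config$n_snp_null_sets,
    seed = derive_seed(config$seed, "snp_null")))
  say("enrich", "%d super-enhancers; CHi-C p = %.3g; SNP p = %.3g",
      sum(ses$is_super), ep_null$p, snp_null$p)

  result <- list(
    config = config, genome = genome, truth = truth,
    size_factors = sf, gene_activity = gene_act,
    per_line = per_line,
    enhancers = merged_enh, ernas = merged_ernas,
    enhancer_activity = enh_act,
    enhancer_specificity = enh_spec, gene_specificity = gene_spec,
    pairs = list(N = pairs_n, CN = pairs_cn, CW = pairs_cw),
    super_enhancers = ses, ep_null = ep_null, snp_null = snp_null,
    log = log
  )
  result$hashes <- map_chr(list(
    enhancers = merged_enh, ernas = merged_ernas,
    pairs_n = pairs_n, pairs_cn = pairs_cn, pairs_cw = pairs_cw,
    size_factors = sf, super = ses$is_super
  ), content_hash)
  class(result) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d cell lines | %d merged enhancers | N/CN/CW pairs %d/%d/%d | %d super-enhancers\n",
    length(x$per_line), nrow(x$enhancers), nrow(x$pairs$N), nrow(x$pairs$CN),
    nrow(x$pairs$CW), sum(x$super_enhancers$is_super)))
  invisible(x)
}

#' Write the main pipeline tables to a directory
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$enhancers, "enhancers.tsv")
  wt(result$ernas, "ernas.tsv")
  for (m in names(result$pairs)) wt(result$pairs[[m]], sprintf("pairs_%s.tsv", m))
  wt(result$enhancer_specificity, "enhancer_specificity.tsv")
  wt(as.data.frame(result$super_enhancers), "super_enhancers.tsv")
  write_null_ensemble(result$ep_null, file.path(outdir, "ep_null"))
  write_null_ensemble(result$snp_null, file.path(outdir, "snp_null"))
  jsonlite::write_json(as.list(result$hashes), file.path(outdir, "hashes.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
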