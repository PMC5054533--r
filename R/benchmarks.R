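#' Validation benchmarks on synthetic cohorts
#'
#' Each benchmark regenerates a ground-truthed cohort under stated study
#' conditions, runs the relevant pipeline stages, and measures how well the
#' truth is recovered. They back the package's validation suite and the
#' `analysis/` drivers.
#'
#' @name benchmarks
NULL

#' @describeIn benchmarks Monte-Carlo check of the PECA null law: the lower
#'   median of `n` independent U(0,1) draws against the Beta(k, n-k+1) CDF,
#'   `k = ceiling(n/2)`. Returns the sup CDF distance per `n`.
#' @param seed master seed.
#' @param n_peptides peptide counts to test.
#' @param reps Monte-Carlo replicates.
#' @export
benchmark_order_statistic <- function(seed, n_peptides = c(1, 3, 5, 8),
                                      reps = 100000) {
  set.seed(split_seed(seed, 401L))
  vapply(n_peptides, function(n) {
    k <- ceiling(n / 2)
    draws <- matrix(stats::runif(reps * n), ncol = n)
    med <- if (n == 1) draws[, 1] else {
      apply(draws, 1, function(r) sort(r)[k])
    }
    x <- sort(med)
    theo <- stats::pbeta(x, k, n - k + 1)
    i <- seq_along(x)
    max(max(i / reps - theo), max(theo - (i - 1) / reps))
  }, numeric(1)) |> stats::setNames(paste0("n", n_peptides))
}

## shared: simulate a cohort and run it to protein results
.run_cohort <- function(seed, n_proteins, de_fraction, effect_size,
                        groups = c("A", "B"), samples_per_batch = 6,
                        n_batches = 2, law = peptide_count_law(),
                        noise = noise_spec(), n_spike = 50,
                        affine = NULL, contrast = NULL, ...) {
  design <- generate_design(n_batches, samples_per_batch, groups, seed = seed)
  truth <- generate_truth(n_proteins, law = law, de_fraction = de_fraction,
                          effect_size = effect_size, n_spike_proteins = n_spike,
                          seed = seed, ...)
  psm <- simulate_psm_table(truth, design, noise = noise, seed = seed,
                            affine = affine)
  pm <- collapse_to_peptides(filter_psms(psm), design)
  parts <- split_spike(pm, design$spike_taxon_tag)
  model <- fit_stabilizer(parts$anchor)
  glog <- apply_stabilizer(parts$endogenous, model)
  if (is.null(contrast)) contrast <- list(groups[1], groups[2])
  de <- differential_analysis(glog, design, contrast[[1]], contrast[[2]])
  list(design = design, truth = truth, psm = psm, model = model,
       glog = glog, de = de)
}

#' @describeIn benchmarks Type-I error calibration under a global null
#'   (no planted effects): fraction of protein PECA p-values below 0.05 and
#'   mean count of BH discoveries at q < 0.05, averaged over seeds.
#' @param n_seeds number of independent cohorts.
#' @param n_proteins endogenous proteins per cohort.
#' @export
benchmark_null_calibration <- function(seed, n_seeds = 5,
                                       n_proteins = 2000) {
  per_seed <- vapply(seq_len(n_seeds), function(i) {
    run <- .run_cohort(split_seed(seed, 500L + i), n_proteins,
                       de_fraction = 0, effect_size = 0)
    r <- run$de$protein_results
    c(frac_p05 = mean(r$p_peca < 0.05),
      n_bh05 = sum(r$q_bh < 0.05))
  }, numeric(2))
  c(type1_rate = mean(per_seed["frac_p05", ]),
    mean_bh_discoveries = mean(per_seed["n_bh05", ]))
}

#' @describeIn benchmarks Detection power and effect recovery: planted
#'   10% DE at |delta| = 1 log2 with the median-3 multiplicity law; reports
#'   the AUROC of the PECA p ranking against the planted DE labels and the
#'   median absolute error of the estimated log2 fold change on DE proteins.
#' @export
benchmark_detection <- function(seed, n_proteins = 1000,
                                de_fraction = 0.1, effect_size = 1) {
  run <- .run_cohort(split_seed(seed, 600L), n_proteins, de_fraction,
                     effect_size, law = peptide_count_law(prob = 0.25))
  r <- run$de$protein_results
  tl <- true_logfc(run$truth, run$design, "A", "B")
  is_de <- tl[r$protein] != 0
  rk <- rank(r$p_peca)
  n1 <- sum(is_de); n0 <- sum(!is_de)
  auroc <- (sum(rk[!is_de]) - n0 * (n0 + 1) / 2) / (n1 * n0)
  mae <- stats::median(abs(r$logfc_median[is_de] - tl[r$protein][is_de]))
  c(auroc = auroc, logfc_mae = mae, n_proteins_tested = nrow(r))
}

#' @describeIn benchmarks Calibration recovery: plants the extreme channel
#'   scale ratios (b in \{0.5, 2\}) with random additive backgrounds at
#'   cv_mult = 0.1 and ~200 complete-case spike peptides over 2 batches x 10
#'   channels; reports the worst relative error of the fitted scale ratios
#'   and the fold-reduction in pooled spike SD versus the naive (a = 0,
#'   b = 1) glog2 transform.
#' @export
benchmark_normalization <- function(seed) {
  s <- split_seed(seed, 700L)
  design <- generate_design(2, 9, c("A", "B"), seed = s)
  truth <- generate_truth(20, de_fraction = 0, n_spike_proteins = 45,
                          seed = s)
  ch <- design$channels
  set.seed(split_seed(s, 701L))
  aff <- data.frame(batch = ch$batch, channel = ch$channel,
                    a = stats::runif(nrow(ch), 0, 1000),
                    b = rep(c(0.5, 2), length.out = nrow(ch)))
  ns <- noise_spec(cv_mult = 0.1, missing_rate = 0, decoy_rate = 0,
                   contaminant_rate = 0)
  psm <- simulate_psm_table(truth, design, noise = ns, seed = s,
                            affine = aff)
  anchor <- split_spike(collapse_to_peptides(filter_psms(psm), design))$anchor
  model <- fit_stabilizer(anchor)
  bt <- aff$b / exp(mean(log(aff$b)))
  bf <- model$b / exp(mean(log(model$b)))
  y <- apply_stabilizer(anchor, model)$values
  naive <- asinh(anchor$values) / log(2)
  pooled_sd <- function(M) sqrt(mean(apply(M, 1, stats::sd)^2))
  c(scale_ratio_max_rel_err = max(abs(bf / bt - 1)),
    spike_sd_reduction = pooled_sd(naive) / pooled_sd(y),
    n_anchor_peptides = nrow(anchor$values))
}

#' @describeIn benchmarks Cohort structure recovery: 18 samples in 3 groups
#'   of 6 with planted group signatures; Adjusted Rand Index of hierarchical
#'   clustering at k = 3 and of clustering on the first two principal
#'   component scores, both against the true group labels.
#' @param effect_size planted log2 group effect.
#' @export
benchmark_clustering <- function(seed, effect_size = 1.5,
                                 de_fraction = 0.2, n_proteins = 1000) {
  s <- split_seed(seed, 800L)
  design <- generate_design(2, 9, c("HGSC", "CCC", "ENOC"), seed = s)
  truth <- generate_truth(n_proteins, de_fraction = de_fraction,
                          effect_size = effect_size, n_spike_proteins = 50,
                          seed = s)
  psm <- simulate_psm_table(truth, design, seed = s)
  pm <- collapse_to_peptides(filter_psms(psm), design)
  parts <- split_spike(pm, design$spike_taxon_tag)
  model <- fit_stabilizer(parts$anchor)
  glog <- apply_stabilizer(parts$endogenous, model)
  prot <- summarize_to_proteins(glog)
  rel <- complete_case_matrix(median_center(prot))
  samples <- design_samples(design)
  rel <- rel[, samples, drop = FALSE]
  labels <- design$group_of_sample[samples]

  hc <- hierarchical_cluster(rel, k = 3)
  pca <- pca_decompose(rel)
  pc_scores <- t(pca$scores[, 1:2])
  hc_pca <- hierarchical_cluster(pc_scores, distance = "euclidean", k = 3)
  c(ari_hclust = .ari(hc$labels[samples], labels),
    ari_pca = .ari(hc_pca$labels[samples], labels),
    n_complete_proteins = nrow(rel))
}

## adjusted Rand index (contingency-table form)
.ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  maxi <- (row_c + col_c) / 2
  if (maxi == expected) return(1)
  (idx - expected) / (maxi - expected)
}

#' @describeIn benchmarks Zero-noise end-to-end identity: a noise-free,
#'   identity-affine cohort at high reporter abundance run through the full
#'   pipeline; reports the worst absolute deviation of the estimated protein
#'   log2 fold changes from the planted truth, and whether thresholding the
#'   BH q-values recovers exactly the planted DE set.
#' @export
benchmark_zero_noise <- function(seed, n_proteins = 200) {
  s <- split_seed(seed, 900L)
  design <- generate_design(2, 6, c("A", "B"), seed = s)
  truth <- generate_truth(n_proteins, de_fraction = 0.1, effect_size = 1,
                          n_spike_proteins = 30, seed = s,
                          baseline_mean = 22, baseline_sd = 1,
                          peptide_sd = 0.5, spike_baseline_mean = 23,
                          spike_baseline_sd = 0.5)
  aff <- data.frame(batch = design$channels$batch,
                    channel = design$channels$channel, a = 0, b = 1)
  ns <- noise_spec(cv_mult = 0, additive_sd = 0, missing_rate = 0,
                   decoy_rate = 0, contaminant_rate = 0)
  psm <- simulate_psm_table(truth, design, noise = ns, seed = s, affine = aff)
  pm <- collapse_to_peptides(filter_psms(psm), design)
  parts <- split_spike(pm, design$spike_taxon_tag)
  model <- fit_stabilizer(parts$anchor)
  glog <- apply_stabilizer(parts$endogenous, model)
  de <- differential_analysis(glog, design, "A", "B")
  r <- de$protein_results
  tl <- true_logfc(truth, design, "A", "B")[r$protein]
  flagged <- r$protein[r$q_bh < 0.5]
  c(max_abs_logfc_error = max(abs(r$logfc_median - tl)),
    de_set_exact = as.numeric(setequal(flagged, names(tl)[tl != 0])),
    min_null_p = min(r$p_peca[tl == 0]))
}
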