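#' Default peptide-multiplicity law
#'
#' Truncated geometric law on {1, ..., max} for the number of distinct
#' peptides observed per protein. The default success probability 0.2 puts
#' roughly 20% of proteins on a single peptide, the multiplicity statistic
#' typical of isobaric MS cohorts of this kind.
#'
#' @param prob geometric success probability; `P(n = 1)` is approximately
#'   `prob` for moderate truncation.
#' @param max truncation point (inclusive).
#' @return a list describing the law, accepted by [generate_truth()].
#' @export
peptide_count_law <- function(prob = 0.2, max = 30L) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  list(type = "truncated_geometric", prob = prob, max = as.integer(max))
}

## inverse-CDF sampler for the truncated geometric (support 1..max)
.sample_peptide_counts <- function(n, law) {
  if (is.function(law)) {
    k <- law(n)
    if (any(k < 1)) stop("peptide_count_law must yield integers >= 1")
    return(as.integer(k))
  }
  p_max <- stats::pgeom(law$max - 1L, law$prob)
  as.integer(stats::qgeom(stats::runif(n) * p_max, law$prob) + 1L)
}

#' Generate the ground truth of a synthetic isobaric cohort
#'
#' Draws per-protein baseline log2 abundances, per-peptide ionization-efficiency
#' offsets, peptide multiplicities, a sign-balanced set of differentially
#' expressed (DE) proteins carrying a planted group effect, and a block of
#' spike-in proteins that are constant across all channels by construction
#' (their planted effect is zero in every group).
#'
#' @param n_proteins number of endogenous proteins.
#' @param law peptide multiplicity law from [peptide_count_law()], or a
#'   function `n -> integer counts >= 1`.
#' @param de_fraction fraction of endogenous proteins carrying a planted
#'   effect; exactly `round(de_fraction * n_proteins)` proteins are marked DE.
#' @param effect_size magnitude of the planted log2 effect; signs are
#'   balanced (+/-) across the DE set.
#' @param n_spike_proteins number of spike-in proteins (accessions carry the
#'   `"ECOLI"` tag; planted effect 0).
#' @param seed master seed.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution of
#'   endogenous proteins (defaults 10 and 1.5: raw reporter signals around
#'   10^3 with ~10-fold biological spread).
#' @param peptide_sd sd of peptide-level log2 ionization offsets.
#' @param spike_baseline_mean,spike_baseline_sd log2 baseline of spike-in
#'   proteins (defaults 11 and 2: a whole-cell lysate spike spans the full
#'   abundance range, which is what identifies per-channel background
#'   offsets during calibration).
#' @return an object of class `synthetic_truth`: list with `proteins`
#'   (data frame: `protein`, `is_spike`, `is_de`, `delta`, `n_peptides`,
#'   `baseline`), `peptides` (data frame: `peptide`, `protein`, `offset`),
#'   and the generating parameters.
#' @export
generate_truth <- function(n_proteins, law = peptide_count_law(),
                           de_fraction = 0, effect_size = 1,
                           n_spike_proteins = 0, seed = 1,
                           baseline_mean = 10, baseline_sd = 1.5,
                           peptide_sd = 1,
                           spike_baseline_mean = 11, spike_baseline_sd = 2) {
  if (de_fraction < 0 || de_fraction > 1) {
    stop("parameter error: de_fraction must lie in [0, 1]")
  }
  set.seed(split_seed(seed, 202L))

  prot_endo <- sprintf("PROT%05d", seq_len(n_proteins))
  prot_spike <- if (n_spike_proteins > 0) {
    sprintf("ECOLI_SPK%04d", seq_len(n_spike_proteins))
  } else character(0)
  protein <- c(prot_endo, prot_spike)
  is_spike <- c(rep(FALSE, n_proteins), rep(TRUE, n_spike_proteins))

  n_pep <- .sample_peptide_counts(length(protein), law)
  baseline <- c(stats::rnorm(n_proteins, baseline_mean, baseline_sd),
                stats::rnorm(n_spike_proteins, spike_baseline_mean,
                             spike_baseline_sd))

  n_de <- round(de_fraction * n_proteins)
  is_de <- rep(FALSE, length(protein))
  delta <- rep(0, length(protein))
  if (n_de > 0) {
    de_idx <- sort(sample.int(n_proteins, n_de))
    signs <- rep(c(1, -1), length.out = n_de)
    is_de[de_idx] <- TRUE
    delta[de_idx] <- sample(signs) * effect_size
  }

  peptides <- data.frame(
    peptide = unlist(lapply(seq_along(protein), function(i) {
      sprintf("%s_pep%02d", protein[i], seq_len(n_pep[i]))
    }), use.names = FALSE),
    protein = rep(protein, n_pep),
    offset = stats::rnorm(sum(n_pep), 0, peptide_sd),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      proteins = data.frame(protein = protein, is_spike = is_spike,
                            is_de = is_de, delta = delta,
                            n_peptides = n_pep, baseline = baseline,
                            stringsAsFactors = FALSE),
      peptides = peptides,
      params = list(n_proteins = n_proteins, law = law,
                    de_fraction = de_fraction, effect_size = effect_size,
                    n_spike_proteins = n_spike_proteins,
                    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                    peptide_sd = peptide_sd),
      seed = seed
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$proteins
  cat("synthetic_truth:", sum(!p$is_spike), "endogenous proteins (",
      sum(p$is_de), "DE ),", sum(p$is_spike), "spike-in proteins,",
      nrow(x$peptides), "peptides\n")
  invisible(x)
}

#' Deterministic assignment of DE proteins to target groups
#'
#' Each DE protein expresses its planted effect in exactly one group of the
#' design; DE proteins are assigned to groups by cycling through the design's
#' group levels in protein-id order. This gives every group its own planted
#' signature (as tumour histotypes have in real cohorts) without extra
#' randomness.
#'
#' @param truth a `synthetic_truth`.
#' @param design a `study_design`.
#' @return named character vector over DE protein ids -> target group label.
#' @export
assign_de_groups <- function(truth, design) {
  de <- truth$proteins$protein[truth$proteins$is_de]
  if (length(de) == 0) return(stats::setNames(character(0), character(0)))
  g <- design$group_levels[(seq_along(de) - 1L) %% length(design$group_levels) + 1L]
  stats::setNames(g, de)
}

#' Expected log2 fold change of every protein under a two-group contrast
#'
#' The planted truth implied by [assign_de_groups()]: a DE protein targeted at
#' a group contributes `+delta` when that group is on side A of the contrast,
#' `-delta` when on side B, and 0 otherwise.
#'
#' @param truth a `synthetic_truth`.
#' @param design a `study_design`.
#' @param group_a,group_b character vectors of group labels on each side.
#' @return named numeric vector over all protein ids.
#' @export
true_logfc <- function(truth, design, group_a, group_b) {
  tg <- assign_de_groups(truth, design)
  out <- stats::setNames(rep(0, nrow(truth$proteins)), truth$proteins$protein)
  if (length(tg)) {
    d <- stats::setNames(truth$proteins$delta, truth$proteins$protein)[names(tg)]
    out[names(tg)[tg %in% group_a]] <- d[tg %in% group_a]
    out[names(tg)[tg %in% group_b]] <- -d[tg %in% group_b]
  }
  out
}
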