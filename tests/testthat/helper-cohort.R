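# Shared builders for simulated cohorts and small fixtures.

# zero-distortion noise: no stochastic components, no nuisance rows
quiet_noise <- function() {
  noise_spec(cv_mult = 0, additive_sd = 0, missing_rate = 0,
             decoy_rate = 0, contaminant_rate = 0)
}

# identity affine truth (a = 0, b = 1) for a design
identity_affine <- function(design) {
  data.frame(batch = design$channels$batch,
             channel = design$channels$channel,
             a = 0, b = 1, stringsAsFactors = FALSE)
}

# simulate and ingest a cohort down to the split peptide matrices
sim_cohort <- function(seed, n_batches = 2, samples_per_batch = 6,
                       groups = c("A", "B"), n_proteins = 500,
                       n_spike = 40, de_fraction = 0, effect_size = 1,
                       law = peptide_count_law(), noise = noise_spec(),
                       affine = NULL, ...) {
  design <- generate_design(n_batches, samples_per_batch, groups, seed = seed)
  truth <- generate_truth(n_proteins, law = law, de_fraction = de_fraction,
                          effect_size = effect_size,
                          n_spike_proteins = n_spike, seed = seed, ...)
  psm <- simulate_psm_table(truth, design, noise = noise, seed = seed,
                            affine = affine)
  pm <- collapse_to_peptides(filter_psms(psm), design)
  parts <- split_spike(pm, design$spike_taxon_tag)
  list(design = design, truth = truth, psm = psm, pm = pm,
       anchor = parts$anchor, endogenous = parts$endogenous)
}

# a tiny hand-written PSM table (canonical dialect) used by ingest tests
tiny_psm_table <- function() {
  data.frame(
    peptide = c("PEPA", "PEPA", "PEPB", "PEPC", "PEPD"),
    proteins = c("P1", "P1", "P1;P2", "P3", "DECOY_P1"),
    q_value = c(0.001, 0.004, 0.002, 0.2, 0.5),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    is_contaminant = FALSE,
    reporter_B1_126 = c(100, 200, 10, 5, 7),
    reporter_B1_131 = c(50, NA, 20, 6, 8),
    stringsAsFactors = FALSE
  )
}

tiny_design <- function() {
  generate_design(1, 1, "A", seed = 1)
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# AUROC of a score that should be LOW for positives (e.g. p-values)
auroc_low <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[!is_positive]) - n0 * (n0 + 1) / 2) / (n1 * n0)
}
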