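# Shared settings for the analysis drivers: one 18-tumour-style cohort
# (2 TMT 10-plex batches, 9 individuals + 1 pooled reference each, three
# histotype groups of 6, E. coli spike-in), regenerated deterministically
# from one seed so every script is self-contained.

library(tmtpeca)

COHORT_SEED <- 1123
RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch/analysis"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, recursive = TRUE, showWarnings = FALSE)

build_cohort <- function(seed = COHORT_SEED) {
  design <- generate_design(2, 9, c("HGSC", "CCC", "ENOC"), seed = seed)
  truth <- generate_truth(1500, de_fraction = 0.15, effect_size = 1.5,
                          n_spike_proteins = 50, seed = seed)
  psm <- simulate_psm_table(truth, design, seed = seed)
  list(design = design, truth = truth, psm = psm)
}

ingest_cohort <- function(cohort) {
  filtered <- filter_psms(cohort$psm, q_max = 0.05)
  pm <- collapse_to_peptides(filtered, cohort$design)
  parts <- split_spike(pm, cohort$design$spike_taxon_tag)
  model <- fit_stabilizer(parts$anchor)
  glog <- apply_stabilizer(parts$endogenous, model)
  list(filtered = filtered, pm = pm, anchor = parts$anchor,
       endogenous = parts$endogenous, model = model, glog = glog)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
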