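# Identification filtering, unique-peptide aggregation, and the
# spike-anchored arsinh-affine calibration. Reports the filtering funnel and
# how much spike (technical-only) variation the calibration removes.

source("analysis/00_common.R")

cohort <- build_cohort()

# demonstrate the round trip through the canonical on-disk dialect
psm_path <- file.path(SCRATCH_DIR, "cohort", "psms.tsv")
if (!file.exists(psm_path)) {
  write_synthetic_cohort(cohort$psm, cohort$truth,
                         file.path(SCRATCH_DIR, "cohort"))
}
psm <- read_psm_table(psm_path)
message("PSM rows read: ", nrow(psm))

filtered <- filter_psms(psm, q_max = 0.05)
message(sprintf("identification filter (q <= 0.05, no decoys/contaminants): %d -> %d rows",
                nrow(psm), nrow(filtered)))

pm <- collapse_to_peptides(filtered, cohort$design)
message("unique peptides quantified: ", nrow(pm$values))

parts <- split_spike(pm, cohort$design$spike_taxon_tag)
message("complete-case spike anchor peptides: ", nrow(parts$anchor$values))

model <- fit_stabilizer(parts$anchor)
print(model)
write_normalization_model(model,
                          file.path(RESULTS_DIR, "02_normalization_model.tsv"))

y <- apply_stabilizer(parts$anchor, model)$values
naive <- asinh(parts$anchor$values) / log(2)
pooled_sd <- function(M) sqrt(mean(apply(M, 1, sd)^2))
message(sprintf(
  "pooled spike SD: %.3f calibrated vs %.3f naive glog2 (%.1f-fold reduction)",
  pooled_sd(y), pooled_sd(naive), pooled_sd(naive) / pooled_sd(y)))

write_tsv(data.frame(
  stage = c("psm_rows", "after_id_filter", "unique_peptides",
            "spike_anchor_peptides", "endogenous_peptides"),
  count = c(nrow(psm), nrow(filtered), nrow(pm$values),
            nrow(parts$anchor$values), nrow(parts$endogenous$values))),
  "02_filter_funnel.tsv")
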