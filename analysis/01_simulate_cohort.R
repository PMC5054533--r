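# Simulate the ground-truthed isobaric cohort used by the rest of the
# analysis and record what was planted. The full PSM table goes to scratch
# (it is bulky and fully reproducible from the seed); the truth summaries
# go to results/.

source("analysis/00_common.R")

cohort <- build_cohort()

write_synthetic_cohort(cohort$psm, cohort$truth,
                       file.path(SCRATCH_DIR, "cohort"))

p <- cohort$truth$proteins
message(sprintf(
  "cohort: %d endogenous proteins (%d DE at |delta| = %.1f log2), %d spike-in proteins, %d peptides, %d PSM rows",
  sum(!p$is_spike), sum(p$is_de), 1.5, sum(p$is_spike),
  nrow(cohort$truth$peptides), nrow(cohort$psm)))
message(sprintf("single-peptide proteins: %.1f%%",
                100 * mean(p$n_peptides[!p$is_spike] == 1)))

de_groups <- assign_de_groups(cohort$truth, cohort$design)
write_tsv(data.frame(protein = names(de_groups), target_group = de_groups,
                     delta = p$delta[match(names(de_groups), p$protein)]),
          "01_planted_de_proteins.tsv")
write_tsv(as.data.frame(table(group = cohort$design$group_of_sample)),
          "01_cohort_groups.tsv")
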