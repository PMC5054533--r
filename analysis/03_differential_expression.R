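# Peptide-level differential expression with PECA protein inference:
# HGSC vs CCC and one-vs-rest contrasts per histotype, recovery of the
# planted effects, the top-1000 differential peptide feature set, and the
# fold-change agreement between two independently simulated replicate
# cohorts (biological-replicate style comparison).

source("analysis/00_common.R")

cohort <- build_cohort()
ing <- ingest_cohort(cohort)

## HGSC vs CCC
de <- differential_analysis(ing$glog, cohort$design, "HGSC", "CCC")
res <- de$protein_results
write_tsv(res, "03_protein_results_HGSC_vs_CCC.tsv")
message(sprintf("HGSC vs CCC: %d proteins tested, %d at q < 0.05",
                nrow(res), sum(res$q_bh < 0.05)))

tl <- true_logfc(cohort$truth, cohort$design, "HGSC", "CCC")[res$protein]
hits <- res$q_bh < 0.05
message(sprintf("  planted-nonzero among hits: %d / %d; median |logFC error| on planted DE: %.3f",
                sum(tl[hits] != 0), sum(hits),
                median(abs(res$logfc_median[tl != 0] - tl[tl != 0]))))

## one-vs-rest signatures per histotype
for (g in cohort$design$group_levels) {
  rest <- setdiff(cohort$design$group_levels, g)
  ovr <- differential_analysis(ing$glog, cohort$design, g, rest,
                               prior = de$prior)
  up <- select_de_genes(ovr$protein_results, lfc_min = 0.5, q_max = 0.05,
                        direction = "up")
  message(sprintf("%s vs rest: %d enriched proteins (logFC > 0.5, q < 0.05)",
                  g, length(up)))
  write_tsv(data.frame(protein = up), sprintf("03_de_list_%s.tsv", g))
}

## top-1000 differential peptides as a clustering feature set
top <- top_differential_peptides(de$peptide_stats, n = 1000)
message(sprintf("top 1000 differential peptides map to %d unique proteins",
                top$n_proteins))
write_tsv(top$table[, c("peptide", "protein", "logfc", "t_mod", "p")],
          "03_top1000_peptides.tsv")

## replicate cohort: same truth, independent noise -> fold-change agreement
psm_b <- simulate_psm_table(cohort$truth, cohort$design, seed = COHORT_SEED + 1)
pm_b <- collapse_to_peptides(filter_psms(psm_b), cohort$design)
parts_b <- split_spike(pm_b, cohort$design$spike_taxon_tag)
glog_b <- apply_stabilizer(parts_b$endogenous, fit_stabilizer(parts_b$anchor))
de_b <- differential_analysis(glog_b, cohort$design, "HGSC", "CCC")
fa <- setNames(res$logfc_median, res$protein)
fb <- setNames(de_b$protein_results$logfc_median, de_b$protein_results$protein)
fc <- fold_change_correlation(fa, fb)
message(sprintf("replicate fold-change correlation: r = %.3f (r^2 = %.3f, %d shared proteins)",
                fc$r, fc$r2, fc$n_shared))
write_tsv(data.frame(r = fc$r, r2 = fc$r2, n_shared = fc$n_shared),
          "03_replicate_correlation.tsv")
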