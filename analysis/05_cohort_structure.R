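# Cohort structure: protein-level relative (median-centered) expression,
# PCA, the top-500 variance-contributing proteins, and unsupervised
# hierarchical clustering of the 18 samples against the true histotypes.

source("analysis/00_common.R")

cohort <- build_cohort()
ing <- ingest_cohort(cohort)

prot <- summarize_to_proteins(ing$glog)
rel <- complete_case_matrix(median_center(prot))
samples <- names(cohort$design$group_of_sample)
rel <- rel[, samples]
labels <- cohort$design$group_of_sample[samples]
message(sprintf("%d proteins quantified in all %d tumours", nrow(rel),
                ncol(rel)))

pca <- pca_decompose(rel)
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance",
                100 * pca$var_explained[1], 100 * pca$var_explained[2]))
write_tsv(data.frame(sample = rownames(pca$scores), group = labels,
                     round(pca$scores[, 1:3], 4)),
          "05_pca_scores.tsv")

top500 <- top_variance_contributors(pca, k = 500, n_components = 2)
writeLines(top500, file.path(RESULTS_DIR, "05_top500_contributors.txt"))

hc_all <- hierarchical_cluster(rel, k = 3)
hc_top <- hierarchical_cluster(rel[top500, ], k = 3)
write_dendrogram_newick(hc_all, file.path(RESULTS_DIR, "05_dendrogram.nwk"))

ari <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  (sc(tab) - sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)) /
    ((sc(rowSums(tab)) + sc(colSums(tab))) / 2 -
       sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2))
}
message(sprintf("clustering vs truth: ARI = %.3f (all proteins), %.3f (top 500)",
                ari(hc_all$labels[samples], labels),
                ari(hc_top$labels[samples], labels)))
write_tsv(data.frame(sample = samples, group = labels,
                     cluster_all = hc_all$labels[samples],
                     cluster_top500 = hc_top$labels[samples]),
          "05_cluster_labels.tsv")
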