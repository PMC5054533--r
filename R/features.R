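#' Summarize a peptide matrix to protein-level expression
#'
#' Collapses stabilized peptide values to one row per protein by the
#' per-sample median over the protein's peptides (observed values only) —
#' the expression summary used for cohort-structure analyses. Statistical
#' testing stays at the peptide level; this summary is for visualization,
#' clustering and PCA.
#'
#' @param matrix a `peptide_matrix` (typically glog2 scale).
#' @return a numeric matrix, protein x sample.
#' @export
summarize_to_proteins <- function(matrix) {
  prot <- matrix$protein[rownames(matrix$values)]
  groups <- sort(unique(prot))
  out <- do.call(rbind, lapply(groups, function(p) {
    rows <- matrix$values[prot == p, , drop = FALSE]
    apply(rows, 2, stats::median, na.rm = TRUE)
  }))
  rownames(out) <- groups
  out[is.nan(out)] <- NA_real_
  out
}

#' Drop features with any missing value
#'
#' Restricts a protein (or peptide) by sample matrix to rows quantified in
#' every sample — the "identified with an expression value across all
#' tumours" matrix used for unsupervised clustering.
#'
#' @param matrix numeric matrix, features x samples.
#' @return the complete-case matrix; warns when empty.
#' @export
complete_case_matrix <- function(matrix) {
  keep <- rowSums(is.na(matrix)) == 0
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no complete-case rows remain")
  out
}

#' Principal component analysis of a cohort matrix
#'
#' PCA with samples as observations and features (proteins) as variables:
#' singular-value decomposition of the feature-centered matrix, no scaling
#' (the default of the standard PCA tool this mirrors). Component signs are
#' fixed so the largest-magnitude loading of each component is positive,
#' making outputs deterministic.
#'
#' @param matrix numeric matrix, features x samples (typically
#'   median-centered relative log2 values); no missing values.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components), `sdev`, `var_explained` (fractions summing
#'   to 1).
#' @export
pca_decompose <- function(matrix) {
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("need at least 2 features and 2 samples")
  }
  if (any(is.na(matrix))) stop("matrix must be complete-case for PCA")
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  if (all(pc$sdev < 1e-12)) stop("degenerate-variance error: constant matrix")
  for (j in seq_along(pc$sdev)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       center = pc$center,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Features contributing most variance to the leading components
#'
#' Ranks features by their eigenvalue-weighted squared loadings summed over
#' the first `n_components` components,
#' `contribution_g = sum_j lambda_j loading_gj^2`, and returns the top `k`
#' (ties broken lexically by feature id).
#'
#' @param pca output of [pca_decompose()].
#' @param k number of features (default 500).
#' @param n_components leading components included (default 2, matching a
#'   two-dimensional PCA display).
#' @return character vector of feature ids, ordered by contribution.
#' @export
top_variance_contributors <- function(pca, k = 500, n_components = 2) {
  J <- min(n_components, length(pca$sdev))
  L <- pca$loadings[, seq_len(J), drop = FALSE]
  lambda <- pca$sdev[seq_len(J)]^2
  contrib <- as.vector(L^2 %*% lambda)
  names(contrib) <- rownames(L)
  if (k > length(contrib)) k <- length(contrib)
  ord <- order(-contrib, names(contrib))
  names(contrib)[ord][seq_len(k)]
}

#' Agglomerative clustering of samples
#'
#' Hierarchical clustering of the sample columns on 1 - Pearson correlation
#' distance with average linkage (the proteomics heat-map convention); both
#' are configurable. Tie handling is deterministic by column order.
#'
#' @param matrix numeric matrix, features x samples.
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, and `labels` (named integer vector) when `k`
#'   is given.
#' @export
hierarchical_cluster <- function(matrix, distance = c("correlation",
                                                      "euclidean"),
                                 linkage = "average", k = NULL) {
  distance <- match.arg(distance)
  if (ncol(matrix) < 2) stop("need at least 2 columns to cluster")
  if (distance == "correlation") {
    sds <- apply(matrix, 2, stats::sd, na.rm = TRUE)
    if (any(sds == 0 | is.na(sds))) {
      stop("zero-variance column(s) under correlation distance: ",
           paste(colnames(matrix)[sds == 0 | is.na(sds)], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(matrix, use = "pairwise.complete.obs"))
  } else {
    d <- stats::dist(t(matrix))
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' Export a dendrogram as Newick
#' @param hc an `hclust` object (or the list from [hierarchical_cluster()]).
#' @param path output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (is.list(hc) && !inherits(hc, "hclust")) hc <- hc$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pearson correlation of fold changes between two result sets
#'
#' Computed over the proteins shared by both sets (at least 3 required).
#'
#' @param res_a,res_b named numeric vectors, protein -> log2 fold change.
#' @return list with `r`, `r2`, `n_shared`.
#' @export
fold_change_correlation <- function(res_a, res_b) {
  shared <- intersect(names(res_a), names(res_b))
  if (length(shared) < 3) {
    stop("insufficient-overlap error: ", length(shared),
         " shared proteins (< 3)")
  }
  r <- stats::cor(res_a[shared], res_b[shared], method = "pearson")
  list(r = r, r2 = r^2, n_shared = length(shared))
}

#' Collapse probe-level values to one measurement per gene
#'
#' Condenses multiple probes assigned to the same gene into the median of
#' their values.
#'
#' @param values numeric vector of probe values.
#' @param genes character vector of gene symbols, parallel to `values`.
#' @return named numeric vector, gene -> median value.
#' @export
collapse_by_gene_median <- function(values, genes) {
  if (length(values) != length(genes)) {
    stop("values and genes must have equal length")
  }
  res <- tapply(values, genes, stats::median, na.rm = TRUE)
  out <- as.numeric(res)
  names(out) <- names(res)
  out[order(names(out))]
}
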