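#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene symbols. Members are case-normalized to upper case and
#' deduplicated.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors (set name -> member symbols).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    members <- unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])]))
    if (length(f) < 3 || length(members) == 0) {
      stop("format error: line ", i,
           " has no members (expect name, description, members)")
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Keep gene sets sufficiently covered by the measured universe
#'
#' Retains sets for which at least `min_frac` of the members have measured
#' values in the data (default 50%), and restricts the retained members to
#' the universe.
#'
#' @param collection named list of member vectors.
#' @param universe character vector of measured symbols.
#' @param min_frac minimum covered fraction.
#' @return the filtered collection with a `"coverage"` attribute (named
#'   numeric vector of coverage fractions of the retained sets).
#' @export
filter_sets_by_coverage <- function(collection, universe, min_frac = 0.5) {
  if (length(universe) == 0) stop("universe must be nonempty")
  universe <- toupper(universe)
  cov <- vapply(collection, function(s) {
    mean(toupper(s) %in% universe)
  }, numeric(1))
  keep <- cov >= min_frac
  out <- lapply(collection[keep], function(s) {
    intersect(toupper(s), universe)
  })
  attr(out, "coverage") <- cov[keep]
  out
}

#' Mean-difference gene-set statistic
#'
#' The mean of the per-gene statistic over the measured set members minus the
#' mean over the measured complement — the descriptive enrichment score of a
#' set relative to the rest of the measured data (log2 units when fed log2
#' statistics).
#'
#' @param gene_stats named numeric vector, symbol -> statistic.
#' @param set character vector of member symbols.
#' @return the mean difference.
#' @export
set_mean_difference <- function(gene_stats, set) {
  in_set <- toupper(names(gene_stats)) %in% toupper(set)
  if (!any(in_set)) {
    stop("undefined-statistic error: no set member has a measured value")
  }
  if (all(in_set)) {
    stop("undefined-statistic error: complement is empty (set covers the ",
         "whole universe)")
  }
  mean(gene_stats[in_set]) - mean(gene_stats[!in_set])
}

## exact null distribution of the (2x midrank) sum of m of N values,
## by dynamic programming over subset sums
.rank_sum_exact_tail <- function(r2, in_set, W2) {
  N <- length(r2)
  m <- sum(in_set)
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  ## f[j+1, t+1] = number of size-j subsets with 2x-rank sum t
  f <- matrix(0, m + 1, maxs + 1)
  f[1, 1] <- 1
  for (i in seq_len(N)) {
    jmax <- min(i, m)
    for (j in jmax:1) {
      t_idx <- which(f[j, ] > 0)
      shifted <- t_idx + r2[i]
      ok <- shifted <= maxs + 1
      f[j + 1, shifted[ok]] <- f[j + 1, shifted[ok]] + f[j, t_idx[ok]]
    }
  }
  counts <- f[m + 1, ]
  total <- sum(counts)
  sums <- 0:maxs
  list(p_up = sum(counts[sums >= W2 - 1e-9]) / total,
       p_down = sum(counts[sums <= W2 + 1e-9]) / total)
}

#' Competitive gene-set rank test
#'
#' Wilcoxon rank-sum comparison of the statistics of set members against the
#' measured complement. For small problems (set size <= 10 and universe
#' <= 25) the p-value is computed by exact enumeration of the tie-aware
#' rank-sum null distribution; otherwise by normal approximation with tie
#' correction and continuity correction. The two-sided p-value is twice the
#' smaller tail, capped at 1.
#'
#' @param gene_stats named numeric vector, symbol -> statistic.
#' @param set character vector of member symbols.
#' @param alternative `"two.sided"`, `"up"` (set statistics larger) or
#'   `"down"`.
#' @return the p-value.
#' @export
gene_set_rank_test <- function(gene_stats, set,
                               alternative = c("two.sided", "up", "down")) {
  alternative <- match.arg(alternative)
  in_set <- toupper(names(gene_stats)) %in% toupper(set)
  N <- length(gene_stats)
  m <- sum(in_set)
  if (m < 1 || m == N) {
    stop("need at least one member and a nonempty complement")
  }
  if (length(unique(gene_stats)) == 1) return(1)

  r <- rank(gene_stats)
  W <- sum(r[in_set])

  if (m <= 10 && N <= 25) {
    tails <- .rank_sum_exact_tail(as.integer(round(2 * r)), in_set,
                                  as.integer(round(2 * W)))
    p_up <- tails$p_up; p_down <- tails$p_down
  } else {
    mu <- m * (N + 1) / 2
    tie_tab <- table(gene_stats)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m * (N - m) / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    sigma <- sqrt(sigma2)
    p_up <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    p_down <- stats::pnorm((W - mu + 0.5) / sigma)
  }
  switch(alternative,
         up = p_up, down = p_down,
         two.sided = min(1, 2 * min(p_up, p_down)))
}

#' Compile a differential-expression gene list from protein results
#'
#' Proteins with median log2 fold change strictly above `lfc_min` (in the
#' requested direction) and BH-adjusted p-value strictly below `q_max` —
#' the conventional cutoffs are `lfc_min = 0.5`, `q_max = 0.05`.
#'
#' @param results a `ProteinResult` data frame from [peca_aggregate()].
#' @param lfc_min log2 fold-change cutoff (strict).
#' @param q_max adjusted-p cutoff (strict).
#' @param direction `"up"` (logFC > lfc_min) or `"down"` (logFC < -lfc_min).
#' @return character vector of protein/gene ids.
#' @export
select_de_genes <- function(results, lfc_min = 0.5, q_max = 0.05,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  hit <- if (direction == "up") {
    results$logfc_median > lfc_min
  } else {
    results$logfc_median < -lfc_min
  }
  results$protein[hit & results$q_bh < q_max]
}

#' Fisher over-representation test of a gene list in a set
#'
#' One-tailed enrichment: hypergeometric upper tail
#' `P(X >= overlap)` with population `N = |universe|`, successes
#' `K = |set intersect universe|`, draws `n = |hits|`. The odds ratio is the
#' sample odds ratio of the 2x2 table, with the Haldane 0.5 continuity
#' correction applied to all cells when any cell is zero.
#'
#' @param hits character vector of selected genes (must lie in `universe`).
#' @param universe character vector of all measured genes.
#' @param set character vector of set members.
#' @return list with `odds_ratio`, `p`, `overlap`, `table` (the 2x2 matrix).
#' @export
fisher_ora <- function(hits, universe, set) {
  if (length(universe) == 0) stop("input error: empty universe")
  universe <- unique(toupper(universe))
  hits <- unique(toupper(hits))
  if (!all(hits %in% universe)) {
    stop("input error: hits must be a subset of the universe")
  }
  set <- intersect(unique(toupper(set)), universe)
  N <- length(universe)
  K <- length(set)
  n <- length(hits)
  k <- length(intersect(hits, set))

  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)

  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2, 2,
                dimnames = list(c("in_set", "not_in_set"),
                                c("hit", "not_hit")))
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p = p, overlap = k, table = tab)
}

#' Run the full gene-set analysis over a collection
#'
#' For every set passing the coverage filter: the mean-difference statistic,
#' the rank-test p-value, and the Fisher over-representation p-value of a DE
#' gene list, with BH adjustment of each p-value family across sets.
#'
#' @param gene_stats named numeric vector of per-gene statistics (the
#'   measured universe).
#' @param collection named list of gene sets.
#' @param de_genes character vector of DE genes for the ORA column.
#' @param min_frac coverage floor.
#' @param alternative passed to [gene_set_rank_test()].
#' @return a data frame: `set`, `n_members`, `coverage`, `mean_diff`,
#'   `p_rank`, `q_rank`, `odds_ratio`, `p_ora`, `q_ora`.
#' @export
gene_set_analysis <- function(gene_stats, collection, de_genes = character(0),
                              min_frac = 0.5,
                              alternative = "two.sided") {
  universe <- toupper(names(gene_stats))
  names(gene_stats) <- universe
  kept <- filter_sets_by_coverage(collection, universe, min_frac)
  if (length(kept) == 0) {
    return(data.frame(set = character(0), n_members = integer(0),
                      coverage = numeric(0), mean_diff = numeric(0),
                      p_rank = numeric(0), q_rank = numeric(0),
                      odds_ratio = numeric(0), p_ora = numeric(0),
                      q_ora = numeric(0)))
  }
  cov <- attr(kept, "coverage")
  rows <- lapply(names(kept), function(nm) {
    s <- kept[[nm]]
    md <- if (length(s) < length(universe)) {
      set_mean_difference(gene_stats, s)
    } else NA_real_
    pr <- gene_set_rank_test(gene_stats, s, alternative)
    ora <- fisher_ora(de_genes, universe, s)
    data.frame(set = nm, n_members = length(s), coverage = cov[[nm]],
               mean_diff = md, p_rank = pr, odds_ratio = ora$odds_ratio,
               p_ora = ora$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_rank <- bh_adjust(out$p_rank)
  out$q_ora <- bh_adjust(out$p_ora)
  out[, c("set", "n_members", "coverage", "mean_diff", "p_rank", "q_rank",
          "odds_ratio", "p_ora", "q_ora")]
}
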