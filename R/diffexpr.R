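#' Peptide-level two-group statistics
#'
#' For each peptide, computes the log2 fold change (mean of side A minus mean
#' of side B over observed values), the pooled within-group variance, its
#' residual degrees of freedom `d_g = n_A + n_B - 2`, and the ordinary
#' two-sample t-statistic. Peptides with no observation on one side are
#' dropped (with the reason recorded in the `"dropped"` attribute); peptides
#' with `d_g = 0` keep their fold change but are flagged and excluded from
#' variance moderation.
#'
#' One-vs-rest contrasts are expressed by passing a group and its complement.
#'
#' @param matrix a glog2-scale `peptide_matrix`.
#' @param design a `study_design`.
#' @param group_a,group_b character vectors of group labels forming the two
#'   sides of the contrast (A minus B).
#' @return a data frame with columns `peptide`, `protein`, `logfc`, `s2`,
#'   `df`, `n_a`, `n_b`, `t_ord`.
#' @export
peptide_group_stats <- function(matrix, design, group_a, group_b) {
  if (matrix$scale != "glog2") {
    stop("peptide_group_stats expects a stabilized (glog2) matrix")
  }
  sa <- design_samples(design, group_a)
  sb <- design_samples(design, group_b)
  if (length(sa) == 0 || length(sb) == 0) {
    stop("both contrast sides must contain at least one sample")
  }
  A <- matrix$values[, intersect(colnames(matrix$values), sa), drop = FALSE]
  B <- matrix$values[, intersect(colnames(matrix$values), sb), drop = FALSE]

  n_a <- rowSums(!is.na(A))
  n_b <- rowSums(!is.na(B))
  ok <- n_a >= 1 & n_b >= 1
  dropped <- rownames(matrix$values)[!ok]

  mean_a <- rowMeans(A, na.rm = TRUE)
  mean_b <- rowMeans(B, na.rm = TRUE)
  ss_a <- rowSums((A - mean_a)^2, na.rm = TRUE)
  ss_b <- rowSums((B - mean_b)^2, na.rm = TRUE)
  df <- n_a + n_b - 2L
  s2 <- ifelse(df >= 1, (ss_a + ss_b) / pmax(df, 1), NA_real_)
  logfc <- mean_a - mean_b
  se <- sqrt(s2 * (1 / n_a + 1 / n_b))
  t_ord <- ifelse(df >= 1, .safe_ratio(logfc, se), NA_real_)

  out <- data.frame(
    peptide = rownames(matrix$values),
    protein = unname(matrix$protein[rownames(matrix$values)]),
    logfc = logfc, s2 = s2, df = as.integer(df),
    n_a = as.integer(n_a), n_b = as.integer(n_b), t_ord = t_ord,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

## x / se with the 0/0 -> 0 and x/0 -> +-Inf conventions
.safe_ratio <- function(x, se) {
  r <- x / se
  r[se == 0 & x == 0] <- 0
  r[se == 0 & x > 0] <- Inf
  r[se == 0 & x < 0] <- -Inf
  r
}

#' Invert the trigamma function (Newton iteration)
#' @keywords internal
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance moderation prior
#'
#' Fits a scaled inverse-chi-square prior (prior variance `s0^2`, prior
#' degrees of freedom `d0`) to the observed peptide residual variances by
#' method of moments on the log scale: with
#' `e_g = ln s_g^2 - digamma(d_g/2) + ln(d_g/2)`, `d0` solves
#' `trigamma(d0/2) = max(0, var(e) - mean(trigamma(d_g/2)))` via the
#' trigamma inverse, and `s0^2 = exp(mean(e) + digamma(d0/2) - ln(d0/2))`.
#' When the excess spread is non-positive (all variances consistent with a
#' single value), `d0` is capped at 1e6 — the infinite-shrinkage limit in
#' which every moderated variance equals `s0^2` and statistics are normal.
#'
#' @param stats a data frame from [peptide_group_stats()].
#' @param min_variances minimum number of usable variances.
#' @return a `moderation_prior`: list with `d0`, `s0_2`, `capped`.
#' @export
fit_moderation_prior <- function(stats, min_variances = 30) {
  use <- !is.na(stats$s2) & stats$df >= 1
  s2 <- stats$s2[use]
  d <- stats$df[use]
  if (length(s2) < min_variances) {
    stop("prior-fit error: only ", length(s2), " peptide variances (< ",
         min_variances, "); consider a d0 = 0 passthrough ",
         "(moderation_prior(0, 1))")
  }
  pos <- s2 > 0
  if (!any(pos)) {
    ## degenerate: every residual variance is exactly zero
    return(moderation_prior(1e6, 0, capped = TRUE))
  }
  if (any(!pos)) {
    warning(sum(!pos), " zero residual variances excluded from prior fit")
    s2 <- s2[pos]; d <- d[pos]
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2 * n / (n - 1)) - mean(trigamma(d / 2))
  d0 <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
  if (d0 >= 1e6) {
    ## infinite-shrinkage limit: every moderated variance collapses onto the
    ## prior, whose maximum-likelihood value is the plain mean of the s2
    moderation_prior(1e6, mean(s2), capped = TRUE)
  } else {
    moderation_prior(d0, exp(ebar + digamma(d0 / 2) - log(d0 / 2)),
                     capped = FALSE)
  }
}

#' Construct a moderation prior directly
#'
#' `d0 = 0` is the no-shrinkage passthrough (moderated t equals ordinary t);
#' `d0 >= 1e6` is treated as infinite shrinkage (normal reference
#' distribution).
#'
#' @param d0 prior degrees of freedom.
#' @param s0_2 prior variance.
#' @param capped whether `d0` represents the infinite limit.
#' @export
moderation_prior <- function(d0, s0_2, capped = d0 >= 1e6) {
  if (d0 < 0 || s0_2 < 0) stop("d0 and s0_2 must be non-negative")
  structure(list(d0 = d0, s0_2 = s0_2, capped = capped),
            class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat("moderation_prior: d0 =", if (x$capped) "Inf (capped)" else
    signif(x$d0, 4), ", s0^2 =", signif(x$s0_2, 4), "\n")
  invisible(x)
}

#' Moderate peptide statistics with a fitted prior
#'
#' Shrinks each residual variance toward the prior,
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, forms the moderated
#' t-statistic on `d0 + d_g` degrees of freedom, and computes two-sided
#' p-values (normal reference when `d0` is capped at the infinite limit).
#' Peptides with `d_g = 0` are excluded from moderation: their moderated
#' fields stay `NA`.
#'
#' @param stats a data frame from [peptide_group_stats()].
#' @param prior a `moderation_prior`.
#' @return `stats` with added columns `s2_mod`, `t_mod`, `df_total`, `p`.
#' @export
moderate <- function(stats, prior) {
  d <- stats$df
  s2 <- stats$s2
  ok <- !is.na(s2) & d >= 1
  s2_mod <- rep(NA_real_, nrow(stats))
  if (prior$d0 == 0) {
    s2_mod[ok] <- s2[ok]
  } else {
    s2_mod[ok] <- (prior$d0 * prior$s0_2 + d[ok] * s2[ok]) / (prior$d0 + d[ok])
  }
  se <- sqrt(s2_mod * (1 / stats$n_a + 1 / stats$n_b))
  t_mod <- rep(NA_real_, nrow(stats))
  t_mod[ok] <- .safe_ratio(stats$logfc[ok], se[ok])
  df_total <- prior$d0 + d
  p <- rep(NA_real_, nrow(stats))
  if (prior$capped) {
    p[ok] <- 2 * stats::pnorm(-abs(t_mod[ok]))
  } else {
    p[ok] <- 2 * stats::pt(-abs(t_mod[ok]), df = df_total[ok])
  }
  ## keep p in (0, 1]: infinite statistics underflow to the smallest double
  p[ok] <- pmax(p[ok], .Machine$double.xmin)
  stats$s2_mod <- s2_mod
  stats$t_mod <- t_mod
  stats$df_total <- df_total
  stats$p <- p
  stats
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) m / j`, restored to input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("input error: p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Aggregate moderated peptide statistics to proteins (PECA)
#'
#' Protein-level inference by peptide-level expression change averaging: for
#' a protein with `n` peptides, the peptide p-values are sorted ascending and
#' the lower median `p_(k)`, `k = ceiling(n/2)`, is referred to its exact
#' null law — the `k`-th order statistic of `n` independent U(0,1) draws,
#' `Beta(k, n - k + 1)`:
#' \deqn{p_{\mathrm{protein}} = F_{\mathrm{Beta}(k,\, n-k+1)}\big(p_{(k)}\big).}
#' The reported effect and statistic are the standard medians of the peptide
#' log fold changes and moderated t; direction is the sign of the median
#' fold change. Protein p-values are BH-adjusted across proteins.
#'
#' @param stats a moderated data frame from [moderate()]; peptides with `NA`
#'   p-values (no residual df) are ignored.
#' @return a `ProteinResult` data frame: `protein`, `n_peptides`,
#'   `logfc_median`, `t_median`, `p_peca`, `q_bh`, `direction`.
#' @export
peca_aggregate <- function(stats) {
  use <- stats[!is.na(stats$p), , drop = FALSE]
  if (nrow(use) == 0) stop("no peptides with defined p-values")
  sp <- split(use, use$protein)
  res <- do.call(rbind, lapply(sp, function(g) {
    n <- nrow(g)
    k <- ceiling(n / 2)
    pk <- sort(g$p)[k]
    p_prot <- max(stats::pbeta(pk, k, n - k + 1), .Machine$double.xmin)
    data.frame(protein = g$protein[1], n_peptides = n,
               logfc_median = stats::median(g$logfc),
               t_median = stats::median(g$t_mod),
               p_peca = p_prot, stringsAsFactors = FALSE)
  }))
  res <- res[order(res$protein), , drop = FALSE]
  res$q_bh <- bh_adjust(res$p_peca)
  res$direction <- sign(res$logfc_median)
  rownames(res) <- NULL
  res
}

#' Select the top differential peptides as a feature set
#'
#' Ranks peptides by ascending moderated p-value, breaking ties by descending
#' absolute moderated t and then lexically by peptide id, and returns the top
#' `n` together with the number of unique parent proteins they map to — the
#' feature-set construction used for replicate-vs-replicate histotype
#' clustering heat maps.
#'
#' @param stats a moderated data frame from [moderate()].
#' @param n number of peptides requested (default 1000).
#' @return list with `peptides`, `proteins`, `n_proteins`, and the ranked
#'   `table`.
#' @export
top_differential_peptides <- function(stats, n = 1000) {
  use <- stats[!is.na(stats$p), , drop = FALSE]
  if (n > nrow(use)) {
    warning("requested ", n, " peptides but only ", nrow(use),
            " available; truncating")
    n <- nrow(use)
  }
  ord <- order(use$p, -abs(use$t_mod), use$peptide)
  top <- use[ord[seq_len(n)], , drop = FALSE]
  rownames(top) <- NULL
  list(peptides = top$peptide, proteins = unique(top$protein),
       n_proteins = length(unique(top$protein)), table = top)
}

#' Full two-group differential analysis from a stabilized matrix
#'
#' Convenience wrapper chaining [peptide_group_stats()],
#' [fit_moderation_prior()], [moderate()] and [peca_aggregate()].
#'
#' @inheritParams peptide_group_stats
#' @param prior optional fixed `moderation_prior`; fitted when `NULL`.
#' @return list with `peptide_stats` (moderated) and `protein_results`.
#' @export
differential_analysis <- function(matrix, design, group_a, group_b,
                                  prior = NULL) {
  st <- peptide_group_stats(matrix, design, group_a, group_b)
  if (is.null(prior)) prior <- fit_moderation_prior(st)
  st <- moderate(st, prior)
  list(peptide_stats = st, protein_results = peca_aggregate(st),
       prior = prior)
}
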