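#' HPA-style categorical expression score
#'
#' Aggregates categorical immunohistochemistry calls over tissue blocks into
#' one rough expression estimate per protein: each block scores 9 for
#' 'High', 6 for 'Medium', 3 for 'Low' and 0 for 'Not detected', and the
#' weighted counts are summed. Absent categories count as zero blocks.
#'
#' @param high,medium,low,not_detected non-negative integer block counts
#'   (vectorized).
#' @return numeric score(s).
#' @examples
#' hpa_expression_score(high = 2, medium = 1, not_detected = 3)  # 24
#' @export
hpa_expression_score <- function(high = 0, medium = 0, low = 0,
                                 not_detected = 0) {
  counts <- cbind(high, medium, low, not_detected)
  if (any(counts < 0)) stop("input error: block counts must be non-negative")
  as.numeric(9 * counts[, 1] + 6 * counts[, 2] + 3 * counts[, 3] +
               0 * counts[, 4])
}

#' Overall score of duplicate tissue-microarray cores
#'
#' Staining of each tumour is scored on duplicate cores with the ordinal
#' scale 0 = negative, 1 = weak or variable, 2 = strong. Equal cores give
#' that score; cores that disagree give an overall score of 1 (variable
#' staining); a single available core gives its own score.
#'
#' @param core1,core2 core scores in `{0, 1, 2}` (vectorized; `NA` = core
#'   missing).
#' @return integer overall score(s).
#' @export
tma_aggregate <- function(core1, core2) {
  chk <- c(core1, core2)
  if (any(!is.na(chk) & !(chk %in% 0:2))) {
    stop("input error: core scores must lie in {0, 1, 2}")
  }
  out <- ifelse(is.na(core1), core2,
                ifelse(is.na(core2), core1,
                       ifelse(core1 == core2, core1, 1L)))
  as.integer(out)
}

## exact permutation null of the Mann-Whitney U (ties included) by
## enumeration of all group-A assignments
.mw_exact_tails <- function(x, n_a, u_obs) {
  n <- length(x)
  combos <- utils::combn(n, n_a)
  r <- rank(x)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - n_a * (n_a + 1) / 2
  list(p_up = mean(u_all >= u_obs - 1e-9),
       p_down = mean(u_all <= u_obs + 1e-9),
       u_all = u_all)
}

#' Mann-Whitney U test for ordinal staining scores
#'
#' Rank-sum comparison of two groups of ordinal scores, with 0.5 credit for
#' ties in U. Because the scores take only a few values, ties dominate: the
#' normal approximation uses the tie-corrected variance (plus continuity
#' correction), and for small problems (`n_A + n_B <= 12`) the p-value comes
#' from exact enumeration of the permutation distribution of U.
#'
#' @param group_a,group_b numeric vectors of scores.
#' @param alternative `"two.sided"`, `"up"` (A tends larger) or `"down"`.
#' @return list with `u` (U of group A), `p`, and `exact` flag.
#' @export
mann_whitney_ordinal <- function(group_a, group_b,
                                 alternative = c("two.sided", "up", "down")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("input error: both groups must be nonempty")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  x <- c(group_a, group_b)
  r <- rank(x)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  if (n_a + n_b <= 12) {
    tails <- .mw_exact_tails(x, n_a, u)
    p_up <- tails$p_up; p_down <- tails$p_down
    exact <- TRUE
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    tie_tab <- table(x)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p_up <- p_down <- 1
    } else {
      sigma <- sqrt(sigma2)
      p_up <- stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE)
      p_down <- stats::pnorm((u - mu + 0.5) / sigma)
    }
    exact <- FALSE
  }
  p <- switch(alternative, up = p_up, down = p_down,
              two.sided = min(1, 2 * min(p_up, p_down)))
  list(u = u, p = p, exact = exact)
}

#' Read per-case TMA core scores from TSV
#'
#' Expected columns: `tumour`, `histotype`, `core1`, `core2`.
#'
#' @param path TSV path.
#' @return data frame with an added `overall` column from [tma_aggregate()].
#' @export
read_tma_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tumour", "histotype", "core1", "core2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  df$overall <- tma_aggregate(df$core1, df$core2)
  df
}
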