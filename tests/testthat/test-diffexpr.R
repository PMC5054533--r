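# a peptide_matrix on the stabilized scale built directly from a value matrix
glog_pm <- function(vals, protein) {
  structure(list(values = vals,
                 protein = setNames(protein, rownames(vals)),
                 scale = "glog2"),
            class = "peptide_matrix")
}

# design with 2 groups of 3 samples (S001..S006), no batch structure needed
design_3v3 <- function() {
  d <- generate_design(1, 6, c("A", "B"), seed = 1)
  # make groups deterministic for hand-computed fixtures
  d$group_of_sample[] <- rep(c("A", "B"), each = 3)
  d
}

test_that("peptide group statistics match the pooled-variance t by hand", {
  d <- design_3v3()
  vals <- rbind(pep1 = c(1, 2, 3, 4, 5, 6),
                pep2 = c(2, 2, 2, 2, 2, 2))
  colnames(vals) <- names(d$group_of_sample)
  st <- peptide_group_stats(glog_pm(vals, c("P1", "P1")), d, "A", "B")
  i <- which(st$peptide == "pep1")
  expect_equal(st$logfc[i], -3)
  expect_equal(st$s2[i], 1)
  expect_equal(st$df[i], 4L)
  expect_equal(st$t_ord[i], -3 / sqrt(1 * (2 / 3)), tolerance = 1e-12)
  expect_equal(round(st$t_ord[i], 3), -3.674)
  # identical groups
  j <- which(st$peptide == "pep2")
  expect_equal(st$logfc[j], 0)
  expect_equal(st$t_ord[j], 0)
})

test_that("df bookkeeping flags singleton peptides and drops one-sided ones", {
  d <- design_3v3()
  vals <- rbind(single = c(5, NA, NA, 7, NA, NA),
                onesided = c(1, 2, 3, NA, NA, NA))
  colnames(vals) <- names(d$group_of_sample)
  st <- peptide_group_stats(glog_pm(vals, c("P1", "P2")), d, "A", "B")
  expect_equal(st$peptide, "single")
  expect_equal(st$logfc, -2)
  expect_equal(st$df, 0L)
  expect_true(is.na(st$s2))
  expect_equal(attr(st, "dropped"), "onesided")
  # singleton is excluded from moderation: moderated fields stay NA
  mod <- moderate(st, moderation_prior(4, 1))
  expect_true(is.na(mod$p))
})

test_that("moderation prior recovers the variance hierarchy (MC + limma cross-check)", {
  set.seed(101)
  n <- 5000
  d0_true <- 4
  s0_true <- 0.05
  dg <- 4L
  sigma2 <- s0_true * d0_true / rchisq(n, d0_true)     # inverse-chi-square
  s2 <- sigma2 * rchisq(n, dg) / dg
  st <- data.frame(s2 = s2, df = dg)
  pr <- fit_moderation_prior(st)
  expect_false(pr$capped)
  expect_lt(abs(pr$d0 - d0_true) / d0_true, 0.2)
  expect_lt(abs(pr$s0_2 - s0_true) / s0_true, 0.2)
  # independent implementation of the same moment estimator
  skip_if_not_installed("limma")
  fd <- limma::fitFDist(s2, dg)
  expect_equal(pr$d0, fd$df2, tolerance = 0.05)
  expect_equal(pr$s0_2, fd$scale, tolerance = 0.05)
})

test_that("moderation limits behave as stated", {
  # all variances identical -> capped prior, moderated variance = common value
  st <- data.frame(s2 = rep(0.25, 40), df = 4L,
                   logfc = rnorm(40), n_a = 3L, n_b = 3L)
  pr <- fit_moderation_prior(st)
  expect_true(pr$capped)
  expect_equal(pr$s0_2, 0.25, tolerance = 1e-9)
  mod <- moderate(st, pr)
  expect_equal(unname(mod$s2_mod), rep(0.25, 40), tolerance = 1e-6)

  # capped prior gives z-statistic behavior: p = 2 pnorm(-|t|)
  st2 <- data.frame(s2 = 1, df = 4L, logfc = 1.96 * sqrt(2 / 3),
                    n_a = 3L, n_b = 3L)
  mod2 <- moderate(st2, moderation_prior(1e6, 1))
  expect_equal(mod2$p, 0.05, tolerance = 1e-3)

  # d0 = 0 passthrough: moderated t equals the ordinary t exactly
  d <- design_3v3()
  set.seed(5)
  vals <- matrix(rnorm(60), 10, 6,
                 dimnames = list(sprintf("p%02d", 1:10),
                                 names(d$group_of_sample)))
  st3 <- peptide_group_stats(glog_pm(vals, rep("P1", 10)), d, "A", "B")
  mod3 <- moderate(st3, moderation_prior(0, 1))
  expect_equal(mod3$t_mod, st3$t_ord, tolerance = 1e-12)
  expect_equal(mod3$p, 2 * pt(-abs(st3$t_ord), df = 4), tolerance = 1e-12)

  # t = 0 -> p = 1
  st4 <- data.frame(s2 = 1, df = 4L, logfc = 0, n_a = 3L, n_b = 3L)
  expect_equal(moderate(st4, moderation_prior(0, 1))$p, 1)
})

test_that("PECA aggregation follows the beta order-statistic law", {
  mk <- function(p, prot) {
    data.frame(peptide = sprintf("pep%02d", seq_along(p)), protein = prot,
               logfc = 1, t_mod = 1, p = p)
  }
  # n = 1: Beta(1,1) CDF is the identity
  r1 <- peca_aggregate(mk(0.037, "P1"))
  expect_equal(r1$p_peca, 0.037)
  # n = 3, lower median is the 2nd order statistic, Beta(2,2): 3x^2 - 2x^3
  r3 <- peca_aggregate(mk(c(0.01, 0.04, 0.50), "P2"))
  expect_equal(r3$p_peca, 3 * 0.04^2 - 2 * 0.04^3, tolerance = 1e-12)
  expect_equal(r3$p_peca, 0.004672, tolerance = 1e-9)
  # even n uses the lower median k = n/2
  p4 <- c(0.1, 0.2, 0.3, 0.4)
  r4 <- peca_aggregate(mk(p4, "P3"))
  expect_equal(r4$p_peca, pbeta(0.2, 2, 3), tolerance = 1e-12)
  # medians of effect and statistic are the standard medians
  df <- mk(c(0.5, 0.5, 0.5), "P4")
  df$logfc <- c(-1, 0, 2)
  df$t_mod <- c(-3, 1, 5)
  r <- peca_aggregate(df)
  expect_equal(r$logfc_median, 0)
  expect_equal(r$t_median, 1)
  expect_equal(r$direction, 0)
})

test_that("lower-median order statistic follows Beta(k, n-k+1) (MC oracle)", {
  set.seed(77)
  for (n in c(3, 5, 8)) {
    k <- ceiling(n / 2)
    draws <- matrix(runif(20000 * n), ncol = n)
    med <- apply(draws, 1, function(r) sort(r)[k])
    x <- sort(med)
    emp_hi <- seq_along(x) / length(x)
    emp_lo <- (seq_along(x) - 1) / length(x)
    theo <- pbeta(x, k, n - k + 1)
    expect_lt(max(abs(emp_hi - theo), abs(theo - emp_lo)), 0.02)
  }
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "input error")
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in ranked order
})

test_that("top differential peptides rank by p with |t| and id tie-breaks", {
  st <- data.frame(
    peptide = c("b", "a", "c", "d", "e"),
    protein = c("P1", "P1", "P2", "P2", "P3"),
    logfc = 1, t_mod = c(2, -5, 3, 3, 1),
    p = c(0.01, 0.01, 0.02, 0.02, 0.5)
  )
  top <- top_differential_peptides(st, 3)
  # tie at p = 0.01 broken by larger |t|: "a" (|t|=5) before "b"
  expect_equal(top$peptides, c("a", "b", "c"))
  expect_equal(top$n_proteins, 2)
  # permutation of input does not change the selection
  top2 <- top_differential_peptides(st[c(4, 2, 5, 1, 3), ], 3)
  expect_equal(top2$peptides, top$peptides)
  expect_warning(top_differential_peptides(st, 10), "truncating")
})

test_that("swapping contrast sides negates effects but keeps p-values", {
  co <- sim_cohort(41, n_proteins = 120, n_spike = 20, de_fraction = 0.2)
  m <- fit_stabilizer(co$anchor)
  g <- apply_stabilizer(co$endogenous, m)
  ab <- differential_analysis(g, co$design, "A", "B")
  ba <- differential_analysis(g, co$design, "B", "A",
                              prior = ab$prior)
  expect_equal(ba$peptide_stats$logfc, -ab$peptide_stats$logfc)
  expect_equal(ba$peptide_stats$t_mod, -ab$peptide_stats$t_mod)
  expect_equal(ba$peptide_stats$p, ab$peptide_stats$p)
  expect_equal(ba$protein_results$p_peca, ab$protein_results$p_peca)
  expect_equal(ba$protein_results$q_bh, ab$protein_results$q_bh)
  expect_true(all(ab$protein_results$q_bh >= ab$protein_results$p_peca))
})
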