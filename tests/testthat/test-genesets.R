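write_gmt_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT parsing deduplicates members and validates lines", {
  path <- write_gmt_lines(c(
    "SET_A\tdesc\tTP53\tWT1\tCRABP2",
    "SET_B\tdesc\tNAPSA\tnapsa\tHNF1B"
  ))
  gs <- read_gmt(path)
  expect_equal(length(gs), 2)
  expect_setequal(gs$SET_A, c("TP53", "WT1", "CRABP2"))
  expect_equal(length(gs$SET_B), 2)  # case-insensitive duplicate counted once

  bad <- write_gmt_lines(c("SET_A\tdesc\tTP53", "SET_B\tdesc"))
  expect_error(read_gmt(bad), "line 2")
})

test_that("coverage filter applies the 50% representation rule", {
  sets <- list(half = paste0("G", 1:10),       # 5 of 10 measured
               sparse = paste0("H", 1:10))     # 4 of 10 measured
  universe <- c(paste0("G", 1:5), paste0("H", 1:4), "X1")
  kept <- filter_sets_by_coverage(sets, universe, min_frac = 0.5)
  expect_equal(names(kept), "half")
  expect_setequal(kept$half, paste0("G", 1:5))
  expect_equal(unname(attr(kept, "coverage")), 0.5)
  # min_frac = 0 keeps everything
  all_kept <- filter_sets_by_coverage(sets, universe, min_frac = 0)
  expect_equal(length(all_kept), 2)
})

test_that("set mean difference compares members against the complement", {
  stats <- c(a = 2, b = 2, c = 0, d = 0)
  expect_equal(set_mean_difference(stats, c("a", "b")), 2)
  expect_error(set_mean_difference(stats, c("x", "y")),
               "undefined-statistic")
  expect_error(set_mean_difference(stats, names(stats)),
               "undefined-statistic")
  # antisymmetric under set/complement exchange at equal sizes
  set.seed(9)
  s <- setNames(rnorm(10), paste0("g", 1:10))
  expect_equal(set_mean_difference(s, paste0("g", 1:5)),
               -set_mean_difference(s, paste0("g", 6:10)))
})

test_that("rank test exact path matches enumeration and known cases", {
  stats <- c(w = 3, x = 2, y = 1, z = 0)
  # top-2 set: only 1 of C(4,2)=6 subsets reaches that rank sum
  expect_equal(gene_set_rank_test(stats, c("w", "x"), "up"), 1 / 6)
  # degenerate: all statistics equal
  expect_equal(gene_set_rank_test(c(a = 1, b = 1, c = 1), "a"), 1)

  # brute-force subset enumeration oracle, including ties
  set.seed(31)
  for (rep in 1:5) {
    vals <- sample(c(rnorm(6), rep(0.5, 6)))
    names(vals) <- paste0("g", 1:12)
    m <- sample(2:5, 1)
    set <- paste0("g", sample(12, m))
    r <- rank(vals)
    w_obs <- sum(r[names(vals) %in% set])
    combos <- combn(12, m)
    w_all <- apply(combos, 2, function(idx) sum(r[idx]))
    p_up_oracle <- mean(w_all >= w_obs - 1e-9)
    p_dn_oracle <- mean(w_all <= w_obs + 1e-9)
    expect_equal(gene_set_rank_test(vals, set, "up"), p_up_oracle)
    expect_equal(gene_set_rank_test(vals, set, "down"), p_dn_oracle)
    expect_equal(gene_set_rank_test(vals, set, "two.sided"),
                 min(1, 2 * min(p_up_oracle, p_dn_oracle)))
  }
})

test_that("rank test normal approximation is close to permutation sampling", {
  set.seed(55)
  stats <- setNames(rnorm(1000), paste0("g", 1:1000))
  set <- paste0("g", sample(1000, 20))
  p_norm <- gene_set_rank_test(stats, set, "up")
  r <- rank(stats)
  w_obs <- sum(r[names(stats) %in% set])
  w_perm <- replicate(20000, sum(sample(r, 20)))
  p_perm <- mean(w_perm >= w_obs)
  expect_lt(abs(p_norm - p_perm), 0.01)
})

test_that("rank test p-values are near-uniform under the null", {
  set.seed(66)
  stats <- setNames(rnorm(200), paste0("g", 1:200))
  pvals <- replicate(1000, {
    gene_set_rank_test(stats, paste0("g", sample(200, 15)), "up")
  })
  d <- suppressWarnings(ks.test(pvals, "punif"))$statistic
  expect_lt(unname(d), 0.05)
})

test_that("DE gene selection uses the strict >0.5 / <0.05 cutoffs", {
  res <- data.frame(
    protein = paste0("P", 1:5),
    logfc_median = c(0.6, 0.4, 0.6, -0.8, 0.51),
    q_bh = c(0.01, 0.001, 0.05, 0.01, 0.049)
  )
  expect_setequal(select_de_genes(res), c("P1", "P5"))  # P3 fails q == 0.05
  expect_equal(select_de_genes(res, direction = "down"), "P4")
  expect_false("P2" %in% select_de_genes(res))          # lfc 0.4 below cutoff
})

test_that("Fisher over-representation matches hypergeometric enumeration", {
  # N=10, K=4, n=5: P(overlap >= 4) = C(4,4) C(6,1) / C(10,5) = 6/252
  u <- paste0("g", 1:10)
  r <- fisher_ora(u[1:5], u, u[c(1, 2, 3, 4)])
  expect_equal(r$p, 6 / 252, tolerance = 1e-12)
  expect_equal(r$overlap, 4)
  # zero overlap -> p = 1
  expect_equal(fisher_ora(u[5:6], u, u[1:2])$p, 1)
  # hits = universe: overlap is forced to K, p = 1
  expect_equal(fisher_ora(u, u, u[1:3])$p, 1)
  expect_error(fisher_ora(c("zzz"), u, u[1:2]), "subset")
  expect_error(fisher_ora("g1", character(0), "g1"), "empty universe")

  # monotone non-increasing in overlap at fixed margins
  p_at <- vapply(0:4, function(k) {
    phyper(k - 1, 4, 6, 5, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
  # implementation agrees with fisher.test's one-sided p
  ft <- fisher.test(matrix(c(4, 1, 0, 5), 2, 2), alternative = "greater")
  expect_equal(r$p, ft$p.value, tolerance = 1e-9)
})

test_that("gene_set_analysis assembles coverage, scores and BH columns", {
  set.seed(12)
  gene_stats <- setNames(c(rnorm(20), rnorm(10, 3)), paste0("g", 1:30))
  sets <- list(up_set = paste0("g", 21:30),
               null_set = paste0("g", 1:10),
               uncovered = c(paste0("g", 1:3), paste0("zz", 1:7)))
  out <- gene_set_analysis(gene_stats, sets,
                           de_genes = paste0("g", 25:30))
  expect_setequal(out$set, c("up_set", "null_set"))  # uncovered fails 50%
  up <- out[out$set == "up_set", ]
  expect_gt(up$mean_diff, 1)
  expect_lt(up$p_rank, 0.01)
  expect_lt(up$p_ora, 0.01)
  expect_true(all(out$q_rank >= out$p_rank))
})
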