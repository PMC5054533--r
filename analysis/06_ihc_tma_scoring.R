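# Categorical IHC scoring: HPA-style 9/6/3/0 block scores for a marker
# panel, and a simulated duplicate-core TMA (0/1/2 staining, disagreeing
# cores scored 1 = variable) compared across histotypes with the
# Mann-Whitney U test.

source("analysis/00_common.R")

## HPA-style block counts for a small marker panel (synthetic counts)
panel <- data.frame(
  protein = c("FOLR1", "CRIP1", "MSLN", "CTH", "GPC3"),
  high = c(5, 3, 4, 0, 1),
  medium = c(4, 5, 3, 1, 2),
  low = c(2, 3, 3, 2, 4),
  not_detected = c(1, 1, 2, 9, 5)
)
panel$hpa_score <- hpa_expression_score(panel$high, panel$medium,
                                        panel$low, panel$not_detected)
print(panel)
write_tsv(panel, "06_hpa_scores.tsv")

## simulated TMA: a marker depleted in HGSC relative to CCC/ENOC
set.seed(split_seed(COHORT_SEED, 6L))
simulate_cores <- function(n, probs) {
  core1 <- sample(0:2, n, replace = TRUE, prob = probs)
  flip <- runif(n) < 0.2          # 20% of duplicate cores disagree
  core2 <- ifelse(flip, pmin(2, core1 + sample(c(-1, 1), n, TRUE)), core1)
  data.frame(core1 = core1, core2 = pmax(0L, as.integer(core2)))
}
tma <- rbind(
  cbind(histotype = "HGSC", simulate_cores(120, c(0.70, 0.20, 0.10))),
  cbind(histotype = "CCC", simulate_cores(60, c(0.25, 0.30, 0.45))),
  cbind(histotype = "ENOC", simulate_cores(60, c(0.35, 0.35, 0.30)))
)
tma$tumour <- sprintf("T%03d", seq_len(nrow(tma)))
tma$overall <- tma_aggregate(tma$core1, tma$core2)
write_tsv(tma[, c("tumour", "histotype", "core1", "core2", "overall")],
          "06_tma_scores.tsv")

pos <- tapply(tma$overall > 0, tma$histotype, mean)
message("positively staining fraction by histotype:")
print(round(100 * pos, 1))

pairs <- combn(c("HGSC", "CCC", "ENOC"), 2)
tests <- apply(pairs, 2, function(pr) {
  a <- tma$overall[tma$histotype == pr[1]]
  b <- tma$overall[tma$histotype == pr[2]]
  mw <- mann_whitney_ordinal(a, b)
  data.frame(group_a = pr[1], group_b = pr[2], u = mw$u, p = mw$p,
             exact = mw$exact)
})
tests <- do.call(rbind, tests)
print(tests, digits = 3)
write_tsv(tests, "06_tma_mann_whitney.tsv")
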