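test_that("analytic gradient of the calibration objective matches finite differences", {
  set.seed(42)
  X <- matrix(2^rnorm(60, 8, 1), 15, 4)
  for (rep in 1:3) {
    par <- c(rnorm(4, 0, 5), rnorm(4, 0, 0.3))
    num <- vapply(seq_along(par), function(i) {
      h <- 1e-6 * max(1, abs(par[i]))
      pp <- pm <- par
      pp[i] <- par[i] + h
      pm[i] <- par[i] - h
      (tmtpeca:::.glog_objective(pp, X) -
         tmtpeca:::.glog_objective(pm, X)) / (2 * h)
    }, numeric(1))
    ana <- tmtpeca:::.glog_gradient(par, X)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("noiseless planted-affine anchors are driven to constant rows", {
  d <- generate_design(1, 9, "A", seed = 4)
  tr <- generate_truth(5, n_spike_proteins = 50, seed = 4)
  aff <- data.frame(batch = "B1", channel = d$channels$channel,
                    a = seq(0, 900, length.out = 10),
                    b = 2^seq(-1, 1, length.out = 10))
  psm <- simulate_psm_table(tr, d, noise = quiet_noise(), seed = 4,
                            affine = aff)
  pm <- collapse_to_peptides(filter_psms(psm), d)
  anchor <- split_spike(pm)$anchor
  m <- fit_stabilizer(anchor)
  y <- apply_stabilizer(anchor, m)$values
  expect_lt(max(apply(y, 1, sd)), 1e-6)
})

test_that("identical channels at zero noise give equal fitted scales", {
  d <- generate_design(1, 9, "A", seed = 8)
  tr <- generate_truth(5, n_spike_proteins = 30, seed = 8)
  psm <- simulate_psm_table(tr, d, noise = quiet_noise(), seed = 8,
                            affine = identity_affine(d))
  anchor <- split_spike(collapse_to_peptides(filter_psms(psm), d))$anchor
  m <- fit_stabilizer(anchor)
  expect_lt(diff(range(m$b)) / mean(m$b), 1e-6)
  y <- apply_stabilizer(anchor, m)$values
  expect_lt(max(apply(y, 1, sd)), 1e-9)
})

test_that("planted scale ratios are recovered within 10% under noise", {
  d <- generate_design(2, 9, c("A", "B"), seed = 7)
  tr <- generate_truth(20, de_fraction = 0, n_spike_proteins = 45, seed = 7)
  ch <- d$channels
  set.seed(split_seed(7, 9999))
  aff <- data.frame(batch = ch$batch, channel = ch$channel,
                    a = runif(nrow(ch), 0, 1000),
                    b = rep(c(0.5, 2), length.out = nrow(ch)))
  ns <- noise_spec(cv_mult = 0.1, missing_rate = 0, decoy_rate = 0,
                   contaminant_rate = 0)
  psm <- simulate_psm_table(tr, d, noise = ns, seed = 7, affine = aff)
  anchor <- split_spike(collapse_to_peptides(filter_psms(psm), d))$anchor
  expect_gte(nrow(anchor$values), 150)
  m <- fit_stabilizer(anchor)
  # scales are identified up to a common factor: compare geometric-mean-
  # normalized ratios
  bt <- aff$b / exp(mean(log(aff$b)))
  bf <- m$b / exp(mean(log(m$b)))
  expect_lt(max(abs(bf / bt - 1)), 0.10)

  # calibration shrinks spike variation at least 5-fold vs naive glog2
  y <- apply_stabilizer(anchor, m)$values
  naive <- asinh(anchor$values) / log(2)
  pooled_sd <- function(M) sqrt(mean(apply(M, 1, sd)^2))
  expect_gte(pooled_sd(naive) / pooled_sd(y), 5)

  # variance-mean dependence is flattened over the anchor
  row_sd <- apply(y, 1, sd)
  slope <- coef(lm(row_sd ~ rank(rowMeans(y))))[2]
  expect_lt(abs(slope), 0.02)
})

test_that("the stabilized transform has the stated pointwise behavior", {
  d <- generate_design(1, 1, "A", seed = 2)
  model <- structure(list(samples = c("S001", "REF_B1"),
                          a = c(S001 = 0, REF_B1 = 0),
                          b = c(S001 = 1, REF_B1 = 1),
                          objective = 0, converged = TRUE, iterations = 0,
                          gradient_norm = 0),
                     class = "normalization_model")
  vals <- matrix(c(0, -5, 2^20, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("S001", "REF_B1")))
  pm <- structure(list(values = vals, protein = c(p1 = "X", p2 = "Y"),
                       scale = "raw"), class = "peptide_matrix")
  y <- apply_stabilizer(pm, model)
  expect_equal(y$scale, "glog2")
  expect_equal(y$values["p1", "S001"], 0)                  # arsinh(0) = 0
  expect_equal(y$values["p2", "S001"], 21, tolerance = 1e-6)  # ~ log2
  expect_true(is.finite(y$values["p1", "REF_B1"]))         # below background
  expect_lt(y$values["p1", "REF_B1"], 0)

  # monotonicity: rank order within a sample is preserved
  x <- sort(runif(50, -10, 1e5))
  yy <- asinh((x - 3) / 7) / log(2)
  expect_true(all(diff(yy) > 0))

  bad <- pm
  colnames(bad$values)[1] <- "S999"
  expect_error(apply_stabilizer(bad, model), "model-mismatch")
})

test_that("fit_stabilizer validates its inputs", {
  X <- matrix(1:10, 5, 2)
  expect_error(fit_stabilizer(X, min_peptides = 10), "anchor-too-small")
  Xna <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(fit_stabilizer(Xna), "complete-case")
})

test_that("median centering yields zero-median rows and drops empty rows", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                1, NA, 3,
                NA, NA, NA), 4, 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), paste0("s", 1:3)))
  out <- median_center(m)
  expect_equal(nrow(out), 3)
  expect_equal(unname(out["r1", ]), c(-1, 0, 1))
  expect_equal(unname(out["r2", ]), c(0, 0, 0))
  expect_equal(unname(out["r3", ]), c(-1, NA, 1))
  meds <- apply(out, 1, median, na.rm = TRUE)
  expect_true(all(meds == 0))
})
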