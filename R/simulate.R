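#' Default noise settings of the synthetic cohort
#'
#' Two-component error model: multiplicative log-normal noise (coefficient of
#' variation `cv_mult`) on the true signal plus additive Gaussian background
#' noise (`additive_sd`, raw reporter units) — the mixed error structure that
#' motivates the generalized-log transform. The default `additive_sd = 20`
#' is 2% of the median raw endogenous signal under the default baseline
#' (2^10 ~ 1000); per-channel background offsets are drawn up to
#' `20 * additive_sd`, so backgrounds reach ~40% of the median signal while
#' the additive noise stays subdominant at typical intensities.
#'
#' @param cv_mult multiplicative coefficient of variation.
#' @param additive_sd sd of additive background noise (raw units).
#' @param missing_rate per-cell probability a reporter value is missing.
#' @param decoy_rate,contaminant_rate fractions of the final PSM table made of
#'   decoy / contaminant rows.
#' @return a named list of noise parameters.
#' @export
noise_spec <- function(cv_mult = 0.15, additive_sd = 20, missing_rate = 0.02,
                       decoy_rate = 0.05, contaminant_rate = 0.02) {
  ns <- list(cv_mult = cv_mult, additive_sd = additive_sd,
             missing_rate = missing_rate, decoy_rate = decoy_rate,
             contaminant_rate = contaminant_rate)
  rates <- unlist(ns[c("missing_rate", "decoy_rate", "contaminant_rate")])
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cv_mult < 0 || additive_sd < 0) stop("noise magnitudes must be >= 0")
  if (ns$decoy_rate + ns$contaminant_rate >= 1) {
    stop("decoy_rate + contaminant_rate must be < 1")
  }
  ns
}

#' Simulate a PSM-level reporter intensity table
#'
#' Generates a peptide-spectrum-match table with the structure the analysis
#' assumes. For peptide p of protein i measured in channel s the raw reporter
#' value is
#' \deqn{x = b_s 2^{\beta_i + e_{ip} + \delta\text{-term} + \epsilon_m} + a_s + \epsilon_a,}
#' where \eqn{(a_s, b_s)} is the per-channel affine distortion (additive
#' background and loading scale), \eqn{\epsilon_m} is log-normal multiplicative
#' noise and \eqn{\epsilon_a \sim N(0, \mathtt{additive\_sd})}; negative raw
#' values are floored at 0. The pooled-reference channel of each batch carries
#' the arithmetic mean of that batch's clean sample signals, then receives its
#' own noise and affine distortion. True PSMs get q-values ~ U(0, 0.01) (so the
#' 0.05 identification filter keeps all of them); decoy and contaminant rows
#' get q ~ U(0, 1) and their flags set.
#'
#' @param truth a `synthetic_truth` from [generate_truth()].
#' @param design a `study_design` from [generate_design()].
#' @param noise a list from [noise_spec()].
#' @param seed master seed.
#' @param psm_reps PSMs per peptide (each an independent measurement; the
#'   ingest step sums them).
#' @param affine optional data frame (`batch`, `channel`, `a`, `b`) fixing the
#'   per-channel affine truth; by default `b` is drawn log-uniformly from
#'   `[0.5, 2]` and `a` uniformly from `[0, 20 * additive_sd]`.
#' @return a data frame in the canonical PSM dialect (columns `peptide`,
#'   `proteins`, `q_value`, `is_decoy`, `is_contaminant`, then
#'   `reporter_<batch>_<channel>`), with attributes `channel_truth` (the
#'   affine truth used) and `de_groups` (DE protein -> target group).
#' @export
simulate_psm_table <- function(truth, design, noise = noise_spec(), seed = 1,
                               psm_reps = 1L, affine = NULL) {
  noise <- do.call(noise_spec, noise[names(noise) %in% names(formals(noise_spec))])
  set.seed(split_seed(seed, 303L))

  ch <- design$channels
  nC <- nrow(ch)
  pep <- truth$peptides
  prot <- truth$proteins
  nP <- nrow(pep)

  ## per-channel affine truth
  if (is.null(affine)) {
    affine <- data.frame(batch = ch$batch, channel = ch$channel,
                         a = stats::runif(nC, 0, 20 * noise$additive_sd),
                         b = 2^stats::runif(nC, -1, 1),
                         stringsAsFactors = FALSE)
  } else {
    key <- paste(ch$batch, ch$channel)
    affine <- affine[match(key, paste(affine$batch, affine$channel)), ]
    if (any(is.na(affine$b)) || any(affine$b <= 0)) {
      stop("affine truth must cover every design channel with b > 0")
    }
  }

  ## clean per-(peptide, channel) log2 signal for sample channels
  base <- prot$baseline[match(pep$protein, prot$protein)] + pep$offset
  de_groups <- assign_de_groups(truth, design)
  ch_group <- design$group_of_sample[ch$sample]   # NA for reference channels
  eff <- matrix(0, nP, nC)
  if (length(de_groups)) {
    d <- stats::setNames(prot$delta, prot$protein)
    tg <- de_groups[pep$protein]                  # NA for non-DE peptides
    for (s in which(!ch$is_reference)) {
      hit <- !is.na(tg) & tg == ch_group[s]
      eff[hit, s] <- d[pep$protein[hit]]
    }
  }
  clean_lin <- 2^(base + eff)                     # nP x nC, refs pending

  ## pooled reference = arithmetic mean of the batch's clean sample signals
  for (s in which(ch$is_reference)) {
    in_batch <- which(ch$batch == ch$batch[s] & !ch$is_reference)
    clean_lin[, s] <- rowMeans(clean_lin[, in_batch, drop = FALSE])
  }

  sd_mult_log2 <- sqrt(log1p(noise$cv_mult^2)) / log(2)

  one_rep <- function() {
    lin <- clean_lin
    if (sd_mult_log2 > 0) {
      lin <- lin * 2^matrix(stats::rnorm(nP * nC, 0, sd_mult_log2), nP, nC)
    }
    x <- sweep(sweep(lin, 2, affine$b, "*"), 2, affine$a, "+")
    if (noise$additive_sd > 0) {
      x <- x + matrix(stats::rnorm(nP * nC, 0, noise$additive_sd), nP, nC)
    }
    x[x < 0] <- 0
    if (noise$missing_rate > 0) {
      x[matrix(stats::runif(nP * nC) < noise$missing_rate, nP, nC)] <- NA_real_
    }
    x
  }

  reps <- lapply(seq_len(psm_reps), function(r) one_rep())
  X <- do.call(rbind, reps)
  n_true <- nrow(X)

  true_rows <- data.frame(
    peptide = rep(pep$peptide, psm_reps),
    proteins = rep(pep$protein, psm_reps),
    q_value = stats::runif(n_true, 0, 0.01),
    is_decoy = FALSE, is_contaminant = FALSE,
    stringsAsFactors = FALSE
  )

  ## nuisance rows sized so their share of the final table equals the rates
  denom <- 1 - noise$decoy_rate - noise$contaminant_rate
  n_decoy <- round(n_true * noise$decoy_rate / denom)
  n_cont <- round(n_true * noise$contaminant_rate / denom)
  nuisance <- function(n, prefix_pep, prefix_prot, flag) {
    if (n == 0) return(NULL)
    vals <- matrix(2^stats::rnorm(n * nC, 8, 1.5), n, nC)
    vals <- sweep(sweep(vals, 2, affine$b, "*"), 2, affine$a, "+")
    df <- data.frame(
      peptide = sprintf("%s%05d", prefix_pep, seq_len(n)),
      proteins = sprintf("%s%05d", prefix_prot, seq_len(n)),
      q_value = stats::runif(n, 0, 1),
      is_decoy = flag == "decoy", is_contaminant = flag == "contaminant",
      stringsAsFactors = FALSE
    )
    list(df = df, vals = vals)
  }
  dec <- nuisance(n_decoy, "DECOYPEP", "DECOY_P", "decoy")
  con <- nuisance(n_cont, "CONTPEP", "CONT_P", "contaminant")

  meta <- rbind(true_rows, if (!is.null(dec)) dec$df, if (!is.null(con)) con$df)
  vals <- rbind(X, if (!is.null(dec)) dec$vals, if (!is.null(con)) con$vals)
  colnames(vals) <- sprintf("reporter_%s_%s", ch$batch, ch$channel)

  out <- cbind(meta, as.data.frame(vals))
  rownames(out) <- NULL
  attr(out, "channel_truth") <- affine
  attr(out, "de_groups") <- de_groups
  out
}

#' Write a simulated cohort to disk (PSM table plus truth sidecars)
#'
#' Emits the canonical tab-separated PSM table plus two sidecars: a protein
#' truth table (`protein`, `is_spike`, `is_de`, `delta`, `peptide_count`) and
#' a channel truth table (`batch`, `channel`, `a`, `b`).
#'
#' @param psm a table from [simulate_psm_table()].
#' @param truth the `synthetic_truth` it was generated from.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_synthetic_cohort <- function(psm, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("psms.tsv", "truth_proteins.tsv",
                            "truth_channels.tsv"))
  utils::write.table(psm, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pt <- truth$proteins[, c("protein", "is_spike", "is_de", "delta",
                           "n_peptides")]
  names(pt)[5] <- "peptide_count"
  utils::write.table(pt, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(attr(psm, "channel_truth"), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
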