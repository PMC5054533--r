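#' TMT 10-plex reporter channel labels
#' @keywords internal
.TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                     "129N", "129C", "130N", "130C", "131")

#' Generate a multi-batch isobaric study design
#'
#' Lays out a cohort across TMT 10-plex batches: each batch carries up to nine
#' individual sample channels plus one pooled-reference channel (a mixture of
#' all samples, run as the 10th channel of every batch to bridge batches).
#' Samples are assigned to biological groups (e.g. tumour histotypes)
#' round-robin and then shuffled under the seed, so group sizes are as equal
#' as the totals allow while the batch/group layout is randomized.
#'
#' @param n_batches number of 10-plex batches.
#' @param samples_per_batch individual samples per batch (at most 9; the 10th
#'   channel is always the pooled reference).
#' @param groups character vector of group labels covering the cohort.
#' @param seed master seed controlling the group shuffle.
#' @param spike_taxon_tag substring of protein accessions that marks spike-in
#'   (exogenous standard) proteins, default `"ECOLI"`.
#' @return an object of class `study_design`: a list with `channels`
#'   (data frame: `batch`, `channel`, `sample`, `is_reference`),
#'   `group_of_sample` (named character vector over non-reference samples),
#'   `group_levels` (the `groups` argument, in order), and `spike_taxon_tag`.
#' @examples
#' d <- generate_design(2, 9, c("HGSC", "CCC", "ENOC"), seed = 1)
#' table(d$group_of_sample)
#' @export
generate_design <- function(n_batches, samples_per_batch, groups, seed,
                            spike_taxon_tag = "ECOLI") {
  if (n_batches < 1) stop("n_batches must be at least 1")
  if (samples_per_batch < 1) stop("samples_per_batch must be at least 1")
  if (samples_per_batch > 9) {
    stop("capacity error: a 10-plex batch holds at most 9 individual samples ",
         "plus the pooled reference channel")
  }
  groups <- as.character(groups)
  if (length(groups) == 0) stop("groups must be nonempty")

  n_samples <- n_batches * samples_per_batch
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  grp <- rep(groups, length.out = n_samples)        # round-robin
  set.seed(split_seed(seed, 101L))
  grp <- sample(grp)                                 # shuffled by seed
  names(grp) <- sample_ids

  channels <- do.call(rbind, lapply(seq_len(n_batches), function(b) {
    idx <- (b - 1L) * samples_per_batch + seq_len(samples_per_batch)
    data.frame(
      batch = sprintf("B%d", b),
      channel = .TMT10_CHANNELS[c(seq_len(samples_per_batch), 10L)],
      sample = c(sample_ids[idx], sprintf("REF_B%d", b)),
      is_reference = c(rep(FALSE, samples_per_batch), TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(channels) <- NULL

  structure(
    list(channels = channels, group_of_sample = grp,
         group_levels = groups, spike_taxon_tag = spike_taxon_tag,
         seed = seed),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  n_ref <- sum(x$channels$is_reference)
  cat("study_design:", length(x$group_of_sample), "samples in",
      length(unique(x$channels$batch)), "batch(es),", n_ref,
      "pooled reference channel(s)\n")
  print(table(x$group_of_sample))
  invisible(x)
}

#' Non-reference samples of a design, optionally restricted to groups
#' @keywords internal
design_samples <- function(design, groups = NULL) {
  s <- names(design$group_of_sample)
  if (!is.null(groups)) s <- s[design$group_of_sample %in% groups]
  s
}
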