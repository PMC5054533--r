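#' Read a PSM export table in the canonical tab-separated dialect
#'
#' The canonical dialect mirrors a search-engine quantification export:
#' columns `peptide` (modified sequence string), `proteins`
#' (semicolon-separated accessions), `q_value`, `is_decoy`, `is_contaminant`,
#' then one `reporter_<batch>_<channel>` column per reporter channel. Foreign
#' exports can be remapped with `dialect`, a named list mapping canonical
#' names to the file's column names and optionally giving `reporter_prefix`.
#' Absent reporter cells (empty or `NA`) are recorded as missing, never zero.
#'
#' @param path path to a tab-separated file.
#' @param dialect optional column remapping, e.g.
#'   `list(peptide = "Sequence", q_value = "Percolator qValue")`.
#' @return a `PsmTable` data frame in canonical column order.
#' @export
read_psm_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- list(peptide = "peptide", proteins = "proteins",
              q_value = "q_value", is_decoy = "is_decoy",
              is_contaminant = "is_contaminant",
              reporter_prefix = "reporter_")
  if (!is.null(dialect)) map[names(dialect)] <- dialect

  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  for (col in c("peptide", "proteins", "q_value", "is_decoy",
                "is_contaminant")) {
    if (!map[[col]] %in% names(raw)) {
      stop("format error: required column '", map[[col]], "' (", col,
           ") is missing from ", path)
    }
  }
  rep_cols <- grep(paste0("^", map$reporter_prefix), names(raw), value = TRUE)
  if (length(rep_cols) == 0) {
    stop("format error: no reporter columns with prefix '",
         map$reporter_prefix, "' in ", path)
  }

  out <- data.frame(
    peptide = raw[[map$peptide]],
    proteins = raw[[map$proteins]],
    q_value = as.numeric(raw[[map$q_value]]),
    is_decoy = .parse_flag(raw[[map$is_decoy]]),
    is_contaminant = .parse_flag(raw[[map$is_contaminant]]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$q_value) & !is.na(raw[[map$q_value]]))) {
    bad <- which(is.na(out$q_value) & !is.na(raw[[map$q_value]]))[1]
    stop("format error: non-numeric q_value at data line ", bad)
  }
  if (any(is.na(out$q_value)) || any(out$q_value < 0 | out$q_value > 1)) {
    stop("format error: q_value must lie in [0, 1]")
  }
  for (rc in rep_cols) {
    v <- suppressWarnings(as.numeric(raw[[rc]]))
    bad <- which(is.na(v) & !is.na(raw[[rc]]))
    if (length(bad)) {
      stop("format error: non-numeric reporter cell in column '", rc,
           "' at data line ", bad[1])
    }
    canon <- if (startsWith(rc, "reporter_")) rc else {
      sub(paste0("^", map$reporter_prefix), "reporter_", rc)
    }
    out[[canon]] <- v
  }
  out
}

.parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  res <- v %in% c("true", "t", "1", "yes")
  res[is.na(x)] <- FALSE
  res
}

#' Apply the identification filters to a PSM table
#'
#' Removes decoy rows, contaminant rows, and PSMs whose identification
#' q-value exceeds `q_max` (default 0.05, the permissive PSM-level cutoff
#' under which downstream peptide-level statistics control false
#' conclusions). Row order is preserved; the operation is idempotent.
#'
#' @param table a `PsmTable`.
#' @param q_max maximum PSM q-value retained.
#' @return the filtered `PsmTable`.
#' @export
filter_psms <- function(table, q_max = 0.05) {
  keep <- !table$is_decoy & !table$is_contaminant & table$q_value <= q_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse filtered PSMs to a unique-peptide by sample matrix
#'
#' PSMs sharing a modified peptide sequence are combined per channel by
#' summation over observed values (missing cells stay missing; a peptide
#' missing in every PSM of a channel stays `NA`, never 0). Peptides whose
#' accession field lists more than one protein — or that are assigned to
#' different proteins in different rows — are dropped: quantification uses
#' unique peptides only. Channels are mapped to sample ids via the design.
#'
#' @param table a filtered `PsmTable`.
#' @param design a `study_design`.
#' @param combine `"sum"` (default; preserves the counting statistics of
#'   signal-to-noise values) or `"mean"`.
#' @return a `peptide_matrix`: list with `values` (peptide x sample matrix,
#'   reference channels included as their own columns), `protein` (named
#'   character vector peptide -> accession) and `scale = "raw"`.
#' @export
collapse_to_peptides <- function(table, design, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  rep_cols <- grep("^reporter_", names(table), value = TRUE)
  key <- sub("^reporter_", "", rep_cols)
  design_key <- paste(design$channels$batch, design$channels$channel, sep = "_")
  unknown <- setdiff(key, design_key)
  if (length(unknown)) {
    stop("design-mismatch error: channel(s) ", paste(unknown, collapse = ", "),
         " present in the table but absent from the design")
  }
  samples <- design$channels$sample[match(key, design_key)]

  ## unique-peptide rule
  multi <- grepl(";", table$proteins, fixed = TRUE)
  tab <- table[!multi, , drop = FALSE]
  n_prot <- tapply(tab$proteins, tab$peptide, function(p) length(unique(p)))
  ambiguous <- names(n_prot)[n_prot > 1]
  tab <- tab[!(tab$peptide %in% ambiguous), , drop = FALSE]
  if (nrow(tab) == 0) stop("no unique peptides left after collapsing")

  vals <- as.matrix(tab[, rep_cols, drop = FALSE])
  grp <- factor(tab$peptide, levels = sort(unique(tab$peptide)))
  obs <- rowsum((!is.na(vals)) * 1, grp)
  z <- vals
  z[is.na(z)] <- 0
  summed <- rowsum(z, grp)
  if (combine == "mean") summed <- summed / pmax(obs, 1)
  summed[obs == 0] <- NA_real_
  colnames(summed) <- samples

  prot <- tapply(tab$proteins, grp, function(p) p[1])
  structure(
    list(values = summed,
         protein = stats::setNames(as.character(prot), levels(grp)),
         scale = "raw"),
    class = "peptide_matrix"
  )
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat("peptide_matrix [", x$scale, "]: ", nrow(x$values), " peptides x ",
      ncol(x$values), " samples, ", length(unique(x$protein)),
      " proteins\n", sep = "")
  invisible(x)
}

#' Split a peptide matrix into the spike-in anchor and endogenous peptides
#'
#' The anchor contains spike-in peptides (accession matches the spike taxon
#' tag) observed in *all* samples — complete cases only, as required for the
#' calibration fit. Endogenous peptides are all non-spike peptides, at any
#' completeness.
#'
#' @param matrix a raw-scale `peptide_matrix`.
#' @param spike_taxon_tag accession substring marking spike-in proteins.
#' @return list with elements `anchor` and `endogenous`, both
#'   `peptide_matrix` objects.
#' @export
split_spike <- function(matrix, spike_taxon_tag = "ECOLI") {
  if (matrix$scale != "raw") stop("split_spike expects a raw-scale matrix")
  is_spike <- grepl(spike_taxon_tag, matrix$protein[rownames(matrix$values)],
                    fixed = TRUE)
  complete <- rowSums(is.na(matrix$values)) == 0
  anchor_rows <- is_spike & complete
  if (!any(anchor_rows)) {
    stop("anchor-empty error: no spike-in peptide observed in all samples; ",
         "fall back to self-calibration on complete-case endogenous peptides ",
         "(fit_stabilizer with trim_fraction = 0.9)")
  }
  subset_pm <- function(rows) {
    structure(list(values = matrix$values[rows, , drop = FALSE],
                   protein = matrix$protein[rownames(matrix$values)[rows]],
                   scale = "raw"),
              class = "peptide_matrix")
  }
  list(anchor = subset_pm(anchor_rows), endogenous = subset_pm(!is_spike))
}

#' Write a PSM table in the canonical dialect
#' @param table a `PsmTable`.
#' @param path output path.
#' @export
write_psm_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
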