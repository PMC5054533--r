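## deterministic polynomial hash of a string, as 8 hex digits (run manifest)
.string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.known_config_keys <- c("seed", "out_dir", "simulate", "ingest", "normalize",
                        "diff", "genesets", "features", "ihc", "input")

#' Run the analysis pipeline from a configuration
#'
#' Orchestrates simulate -> ingest -> normalize -> differential expression ->
#' gene sets -> cohort features behind one call, writing result tables, model
#' sidecars, a log with the row counts after every filter, and a run manifest
#' (package version, seed, configuration hash). Stages are selected by the
#' presence of their configuration blocks; all randomness flows from the
#' single `seed` key, so two runs with the same configuration produce
#' byte-identical outputs.
#'
#' Configuration keys (YAML file or list):
#' \describe{
#'   \item{seed}{master seed (required).}
#'   \item{simulate}{`n_batches`, `samples_per_batch`, `groups`,
#'     `n_proteins`, `n_spike_proteins`, `de_fraction`, `effect_size`,
#'     `peptide_prob`, plus optional `noise` sub-block.}
#'   \item{input}{alternatively, `psms` (path) and `design` fields for real
#'     data; a design block is then required.}
#'   \item{ingest}{`q_max` (default 0.05).}
#'   \item{normalize}{`trim_fraction` (default 1).}
#'   \item{diff}{`group_a`, `group_b` (defaults: first two design groups).}
#'   \item{genesets}{`gmt` path, `lfc_min`, `q_max`.}
#'   \item{features}{`top_k`, `n_components`, `cluster_k`.}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (default: `out_dir` key, else tempdir).
#' @return invisibly, a list with the in-memory stage results and the output
#'   directory.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("config error: 'seed' is required")
  if (is.null(out_dir)) out_dir <- cfg$out_dir %||% tempfile("run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(paste0(paste(...), "\n"), file = log_path, append = TRUE)
  }
  cat("", file = log_path)  # truncate
  res <- list(out_dir = out_dir)

  ## --- simulate or load -----------------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    design <- generate_design(sc$n_batches %||% 2,
                              sc$samples_per_batch %||% 9,
                              sc$groups %||% c("HGSC", "CCC", "ENOC"),
                              seed = cfg$seed)
    truth <- generate_truth(sc$n_proteins %||% 1000,
                            law = peptide_count_law(sc$peptide_prob %||% 0.2),
                            de_fraction = sc$de_fraction %||% 0.1,
                            effect_size = sc$effect_size %||% 1,
                            n_spike_proteins = sc$n_spike_proteins %||% 50,
                            seed = cfg$seed)
    noise <- do.call(noise_spec, as.list(sc$noise %||% list()))
    psm <- simulate_psm_table(truth, design, noise = noise, seed = cfg$seed)
    write_synthetic_cohort(psm, truth, out_dir)
    logf("simulate: ", nrow(psm), " PSM rows, ",
         nrow(truth$peptides), " true peptides, ",
         sum(truth$proteins$is_de), " planted DE proteins")
    res$design <- design; res$truth <- truth; res$psm <- psm
  } else if (!is.null(cfg$input)) {
    if (is.null(cfg$input$design)) {
      stop("config error: real input requires a 'design' block under 'input'")
    }
    dsc <- cfg$input$design
    design <- generate_design(dsc$n_batches, dsc$samples_per_batch,
                              dsc$groups, seed = cfg$seed,
                              spike_taxon_tag = dsc$spike_taxon_tag %||%
                                "ECOLI")
    psm <- read_psm_table(cfg$input$psms)
    logf("ingest: read ", nrow(psm), " PSM rows from ", cfg$input$psms)
    res$design <- design; res$psm <- psm
  } else {
    stop("config error: either a 'simulate' or an 'input' block is required")
  }

  ## --- ingest ----------------------------------------------------------
  q_max <- (cfg$ingest %||% list())$q_max %||% 0.05
  filtered <- filter_psms(res$psm, q_max = q_max)
  logf("filter_psms: ", nrow(res$psm), " -> ", nrow(filtered),
       " rows (q <= ", q_max, ", decoys/contaminants removed)")
  pm <- collapse_to_peptides(filtered, res$design)
  logf("collapse_to_peptides: ", nrow(filtered), " PSMs -> ",
       nrow(pm$values), " unique peptides")
  parts <- split_spike(pm, res$design$spike_taxon_tag)
  logf("split_spike: anchor ", nrow(parts$anchor$values),
       " complete-case spike peptides; endogenous ",
       nrow(parts$endogenous$values), " peptides")
  res$peptides <- parts

  ## --- normalize -------------------------------------------------------
  nc <- cfg$normalize %||% list()
  model <- fit_stabilizer(parts$anchor,
                          trim_fraction = nc$trim_fraction %||% 1)
  write_normalization_model(model,
                            file.path(out_dir, "normalization_model.tsv"))
  glog <- apply_stabilizer(parts$endogenous, model)
  logf("normalize: converged = ", model$converged,
       "; b range [", signif(min(model$b), 4), ", ",
       signif(max(model$b), 4), "]")
  res$model <- model; res$glog <- glog

  ## --- differential expression ----------------------------------------
  dc <- cfg$diff %||% list()
  groups <- res$design$group_levels
  group_a <- dc$group_a %||% groups[1]
  group_b <- dc$group_b %||% groups[2]
  de <- differential_analysis(glog, res$design, group_a, group_b)
  utils::write.table(de$protein_results,
                     file.path(out_dir, "protein_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(de$peptide_stats,
                     file.path(out_dir, "peptide_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("diffexpr: ", nrow(de$peptide_stats), " peptides -> ",
       nrow(de$protein_results), " proteins; ",
       sum(de$protein_results$q_bh < 0.05), " at q < 0.05 (",
       group_a, " vs ", group_b, ")")
  res$de <- de

  ## --- gene sets -------------------------------------------------------
  if (!is.null(cfg$genesets)) {
    gc <- cfg$genesets
    collection <- read_gmt(gc$gmt)
    gene_stats <- stats::setNames(de$protein_results$t_median,
                                  de$protein_results$protein)
    de_genes <- select_de_genes(de$protein_results,
                                lfc_min = gc$lfc_min %||% 0.5,
                                q_max = gc$q_max %||% 0.05)
    gs <- gene_set_analysis(gene_stats, collection, de_genes,
                            min_frac = gc$min_frac %||% 0.5)
    utils::write.table(gs, file.path(out_dir, "geneset_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("genesets: ", length(collection), " sets read, ", nrow(gs),
         " pass the coverage filter; ", length(de_genes), " DE genes")
    res$genesets <- gs
  }

  ## --- cohort features -------------------------------------------------
  fc <- cfg$features %||% list()
  prot_mat <- summarize_to_proteins(glog)
  rel <- median_center(prot_mat)
  cc <- complete_case_matrix(rel)
  logf("features: ", nrow(rel), " proteins -> ", nrow(cc),
       " complete-case rows")
  if (nrow(cc) >= 2) {
    pca <- pca_decompose(cc)
    top <- top_variance_contributors(pca, k = fc$top_k %||% 500,
                                     n_components = fc$n_components %||% 2)
    hc <- hierarchical_cluster(cc, k = fc$cluster_k %||%
                                 length(res$design$group_levels))
    utils::write.table(
      data.frame(sample = rownames(pca$scores),
                 round(pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                  drop = FALSE], 6)),
      file.path(out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines(top, file.path(out_dir, "top_contributors.txt"))
    utils::write.table(
      data.frame(sample = names(hc$labels), cluster = hc$labels),
      file.path(out_dir, "cluster_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_dendrogram_newick(hc, file.path(out_dir, "dendrogram.nwk"))
    res$pca <- pca; res$top_contributors <- top; res$clusters <- hc
  }

  ## --- manifest --------------------------------------------------------
  manifest <- list(
    package = "tmtpeca",
    version = as.character(utils::packageVersion("tmtpeca")),
    seed = cfg$seed,
    config_hash = .string_hash(as.character(
      jsonlite::toJSON(cfg, auto_unbox = TRUE))),
    stages = names(Filter(Negate(is.null),
                          cfg[c("simulate", "input", "ingest", "normalize",
                                "diff", "genesets", "features")]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
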