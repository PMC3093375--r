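# Full-analysis orchestration: QC -> subsample -> distances -> tree ->
# validation -> rank summaries -> composition, emitting a report bundle
# that mirrors the tables and figure data of a barcode diversity study.

#' Pipeline run configuration
#'
#' Every analysis parameter surfaced in one place; nothing is hardcoded
#' downstream.
#'
#' @param fasta,taxonomy input paths (or NULL when a dataset is passed to
#'   \code{\link{run_pipeline}} directly)
#' @param out_dir output directory for the report bundle
#' @param cluster_threshold MOTU / problem-species divergence threshold
#'   (fraction, default 0.02)
#' @param numt_threshold intraspecific distance above which records are
#'   numt/misidentification suspects (default 0.10)
#' @param freq_threshold bin edge for the intraspecific frequency report
#'   (fraction, default 0.03)
#' @param max_per_species per-species record cap before analysis
#'   (default 10)
#' @param min_length QC minimum ungapped length (default 500)
#' @param family_min_sequences,family_min_species family-filter bounds for
#'   per-family summaries (defaults 50 and 6)
#' @param trim_length bases kept for composition analysis (default 500)
#' @param gc_sd,branch_factor numt-flag thresholds (see
#'   \code{\link{flag_numt_suspects}})
#' @param seed integer seed for the subsampling draws
#' @return A \code{run_config} list.
#' @export
run_config <- function(fasta = NULL, taxonomy = NULL, out_dir = NULL,
                       cluster_threshold = 0.02, numt_threshold = 0.10,
                       freq_threshold = 0.03, max_per_species = 10,
                       min_length = 500, family_min_sequences = 50,
                       family_min_species = 6, trim_length = 500,
                       gc_sd = 3, branch_factor = 5, seed = 1) {
  stopifnot(cluster_threshold > 0, cluster_threshold < 1,
            numt_threshold > 0, numt_threshold < 1,
            freq_threshold > 0, freq_threshold < 1)
  structure(list(fasta = fasta, taxonomy = taxonomy, out_dir = out_dir,
                 cluster_threshold = cluster_threshold,
                 numt_threshold = numt_threshold,
                 freq_threshold = freq_threshold,
                 max_per_species = max_per_species,
                 min_length = min_length,
                 family_min_sequences = family_min_sequences,
                 family_min_species = family_min_species,
                 trim_length = trim_length, gc_sd = gc_sd,
                 branch_factor = branch_factor, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{run_config}} arguments
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full diversity-assessment pipeline
#'
#' Stages: load, quality control, per-species subsampling, K2P distance
#' matrix, NJ tree (midpoint-rooted), numt-suspect flagging,
#' problem-species flagging, variant construction and sampling-bias tests,
#' rank and family divergence summaries with a Kruskal-Wallis comparison,
#' MOTU clustering, and composition analysis on the validated dataset.
#' Deterministic given (inputs, config): the only randomness is the seeded
#' subsampling draw.
#'
#' @param config a \code{\link{run_config}}
#' @param dataset optionally, a \code{\link{barcode_dataset}} to analyse
#'   instead of reading \code{config$fasta}/\code{config$taxonomy}
#' @return The report bundle (list); written to \code{config$out_dir} as
#'   TSV/JSON/newick files when that is set. Elements: \code{qc_report},
#'   \code{record_flags}, \code{species_flags}, \code{rank_summary},
#'   \code{family_summary}, \code{kruskal}, \code{bias}, \code{clusters},
#'   \code{composition}, \code{nucleotide_freq}, \code{tree},
#'   \code{dataset} (validated records) and \code{log}.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  t0 <- Sys.time()
  log <- list(seed = config$seed,
              thresholds = config[c("cluster_threshold", "numt_threshold",
                                    "freq_threshold", "max_per_species",
                                    "min_length", "trim_length")])
  if (is.null(dataset)) {
    dataset <- stage("load",
                     read_fasta_with_taxonomy(config$fasta, config$taxonomy))
  }
  log$n_input <- nrow(dataset)

  qc <- stage("qc", qc_filter(dataset, min_length = config$min_length))
  log$n_after_qc <- qc$report$kept

  sub <- stage("subsample",
               subsample_per_species(qc$dataset, config$max_per_species,
                                     seed = config$seed))
  log$n_after_subsample <- nrow(sub)

  D <- stage("distances", distance_matrix(sub))
  tree <- stage("tree", build_nj(D))
  rooted <- stage("root", midpoint_root(tree))

  record_flags <- stage("numt_flags",
    flag_numt_suspects(sub, D, tree = tree,
                       max_intraspecific = config$numt_threshold,
                       gc_sd = config$gc_sd,
                       branch_factor = config$branch_factor))

  species_flags <- stage("species_flags",
    flag_problem_species(sub, D, rooted,
                         threshold = config$cluster_threshold))

  variants <- stage("variants", make_variants(sub, D, species_flags))
  bias <- stage("bias", bias_report(variants))
  validated <- variants$B_dataset
  log$n_validated <- nrow(validated)

  Dv <- stage("distances_validated", distance_matrix(validated))
  ranks <- stage("rank_summary", rank_summary_table(validated, Dv))
  fams <- stage("family_summary",
    family_summaries(validated, Dv,
                     min_sequences = config$family_min_sequences,
                     min_species = config$family_min_species))
  part <- partition_pairs(validated, Dv)
  kw_groups <- split(part$pairs$distance, part$pairs$rank)
  kw_groups <- kw_groups[intersect(c("S", "G", "F"), names(kw_groups))]
  kw <- if (length(kw_groups) >= 2L) kruskal_wallis(kw_groups) else NULL

  clusters <- stage("clusters",
                    threshold_clusters(Dv, config$cluster_threshold))
  comp <- stage("composition",
                composition_table(validated, group_by = "family",
                                  trim = config$trim_length))
  comp_order <- composition_table(validated, group_by = "order",
                                  trim = config$trim_length)
  trimmed <- validated
  trimmed$sequence <- vapply(trimmed$sequence, trim_for_composition,
                             character(1), length = config$trim_length,
                             USE.NAMES = FALSE)
  freqs <- nucleotide_frequencies(trimmed)

  log$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  bundle <- list(qc_report = qc$report, record_flags = record_flags,
                 species_flags = species_flags, rank_summary = ranks,
                 family_summary = fams, kruskal = kw, bias = bias,
                 clusters = clusters, composition = comp,
                 composition_order = comp_order, nucleotide_freq = freqs,
                 tree = tree, dataset = validated, log = log)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(data.frame(reason = c("kept", names(bundle$qc_report$removed_by_reason)),
                       count = c(bundle$qc_report$kept,
                                 unname(bundle$qc_report$removed_by_reason))),
            p("qc_report.tsv"))
  rf <- bundle$record_flags
  write_tsv(data.frame(record_id = names(rf),
                       flags = vapply(rf, paste, "", collapse = ",")),
            p("record_flags.tsv"))
  sf <- bundle$species_flags
  write_tsv(data.frame(species = names(sf),
                       flags = vapply(sf, paste, "", collapse = ",")),
            p("species_flags.tsv"))
  write_tsv(bundle$rank_summary, p("rank_summary.tsv"))
  write_tsv(bundle$family_summary, p("family_summary.tsv"))
  write_tsv(bundle$bias$comparisons, p("bias_report.tsv"))
  jsonlite::write_json(list(comparisons = bundle$bias$comparisons,
                            freq_below_3pct = as.list(bundle$bias$freq_below_3pct),
                            alpha = bundle$bias$alpha),
                       p("bias_report.json"), auto_unbox = TRUE, digits = NA)
  cl <- bundle$clusters
  write_tsv(data.frame(cluster = rep(seq_along(cl), lengths(cl)),
                       record_id = unlist(cl)),
            p("clusters.tsv"))
  write_tsv(bundle$composition, p("composition_families.tsv"))
  write_tsv(bundle$composition_order, p("composition_order.tsv"))
  ape::write.tree(bundle$tree, p("tree.nwk"))
  jsonlite::write_json(bundle$log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
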