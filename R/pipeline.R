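# End-to-end orchestration: read inputs, preprocess, profile, GC, enrichment
# regressions; write schema-tagged TSV outputs and a provenance manifest.

#' Assemble a pipeline run configuration
#'
#' @param otu,taxonomy,metadata paths to the three mandatory inputs.
#' @param fasta optional path to representative sequences; when absent, all
#'   GC-dependent analyses are skipped with a warning.
#' @param out_dir output directory.
#' @param depth rarefaction depth (default 9000).
#' @param seed_rarefy,seed_equalize seeds for the two random preprocessing
#'   steps; recorded in the manifest.
#' @param outlier_k outlier threshold multiplier (default 3, report-only).
#' @param drop_samples explicit sample ids to remove (manual curation).
#' @param drop_flagged remove outlier-flagged samples (default `FALSE`).
#' @param replicates target replicates per condition (`"auto"`).
#' @param top_fraction fraction of classes kept in the stacked-bar summary.
#' @param dispersion `"sd"` or `"se"` dispersion for enrichment records.
#' @param holm add Holm-adjusted p-values to the regression table.
#' @param samples_in_rows orientation of the OTU TSV.
#' @return list of class `rt_config`.
#' @export
rt_config <- function(otu, taxonomy, metadata, fasta = NULL, out_dir,
                      depth = 9000, seed_rarefy = 1, seed_equalize = 1,
                      outlier_k = 3, drop_samples = NULL,
                      drop_flagged = FALSE, replicates = "auto",
                      top_fraction = 0.15, dispersion = "sd", holm = FALSE,
                      samples_in_rows = TRUE) {
  cfg <- list(otu = otu, taxonomy = taxonomy, metadata = metadata,
              fasta = fasta, out_dir = out_dir, depth = depth,
              seed_rarefy = seed_rarefy, seed_equalize = seed_equalize,
              outlier_k = outlier_k, drop_samples = drop_samples,
              drop_flagged = drop_flagged, replicates = replicates,
              top_fraction = top_fraction, dispersion = dispersion,
              holm = holm, samples_in_rows = samples_in_rows)
  for (p in c(cfg$otu, cfg$taxonomy, cfg$metadata, cfg$fasta))
    if (!file.exists(p)) stop("input not found: ", p)
  structure(cfg, class = "rt_config")
}

#' Run the full analysis pipeline
#'
#' Executes read -> preprocess -> class profiles -> GC -> enrichment
#' regressions, writes every output table (schema-tagged TSV) plus a JSON
#' manifest with parameters, seeds and file checksums, and returns the
#' in-memory results invisibly. Reruns with an identical configuration are
#' byte-identical.
#'
#' @param cfg an [rt_config()].
#' @return invisibly, a list with `table`, `class_table`, `profiles`,
#'   `collapsed`, `diversity`, `gc`, `records`, `regressions`, `report`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "rt_config"))
  table <- read_otu_table(cfg$otu, samples_in_rows = cfg$samples_in_rows)
  taxonomy <- read_taxonomy(cfg$taxonomy)
  metadata <- read_metadata(cfg$metadata)
  seqs <- if (!is.null(cfg$fasta)) read_fasta(cfg$fasta) else NULL
  if (is.null(seqs))
    warning("no FASTA supplied: GC-dependent analyses skipped")
  assert_join_closure(table, taxonomy, metadata, seqs)

  pp <- preprocess(table, metadata, depth = cfg$depth,
                   seed_rarefy = cfg$seed_rarefy,
                   outlier_k = cfg$outlier_k,
                   drop_samples = cfg$drop_samples,
                   drop_flagged = cfg$drop_flagged,
                   replicates = cfg$replicates,
                   seed_equalize = cfg$seed_equalize)
  ct <- aggregate_to_class(pp$table, taxonomy)
  prof <- condition_profiles(ct, metadata)
  collapsed <- collapse_low_abundance(prof, top_fraction = cfg$top_fraction)
  div <- diversity_indices(pp$table)
  div_kw <- diversity_test(div, metadata)

  gc <- records <- regs <- NULL
  if (!is.null(seqs)) {
    gc <- class_weighted_gc(taxonomy, seqs, otu_weights(pp$table))
    res <- analyze_enrichment(prof, gc, dispersion = cfg$dispersion,
                              holm = cfg$holm)
    records <- merge(res$records, gc[, c("class_label", "weighted_gc")],
                     by = "class_label", all.x = TRUE, sort = TRUE)
    regs <- res$regressions
    regs$note <- ifelse(regs$assumptions_ok, "", "•")
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_otu_table(pp$table, out("rarefied_table.tsv"))
  ct_df <- data.frame(sample_id = rownames(ct), ct, check.names = FALSE)
  write_tsv_tagged(ct_df, out("class_table.tsv"))
  write_tsv_tagged(prof, out("condition_profiles.tsv"))
  write_tsv_tagged(collapsed, out("stacked_bar.tsv"))
  write_tsv_tagged(div, out("diversity.tsv"))
  write_tsv_tagged(div_kw, out("diversity_kruskal.tsv"))
  write_tsv_tagged(pp$report$outlier_scores, out("outlier_scores.tsv"))
  removed <- data.frame(
    sample_id = c(pp$report$dropped_shallow, pp$report$removed_outliers,
                  pp$report$removed_for_balance),
    reason = rep(c("below_rarefaction_depth", "outlier_or_manual",
                   "replicate_balance"),
                 c(length(pp$report$dropped_shallow),
                   length(pp$report$removed_outliers),
                   length(pp$report$removed_for_balance))),
    stringsAsFactors = FALSE)
  write_tsv_tagged(removed, out("removed_samples.tsv"))
  if (!is.null(seqs)) {
    write_tsv_tagged(gc, out("class_gc.tsv"))
    write_tsv_tagged(records, out("enrichment.tsv"))
    write_tsv_tagged(regs, out("regressions.tsv"))
  }

  files <- list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rtshift")),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    inputs = as.list(tools::md5sum(
      unlist(cfg[c("otu", "taxonomy", "metadata", "fasta")]))),
    outputs = as.list(tools::md5sum(files)),
    report = pp$report[c("dropped_shallow", "flagged_outliers",
                         "removed_outliers", "removed_for_balance",
                         "final_replicates_per_condition")])
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)

  invisible(list(table = pp$table, class_table = ct, profiles = prof,
                 collapsed = collapsed, diversity = div,
                 diversity_kruskal = div_kw, gc = gc, records = records,
                 regressions = regs, report = pp$report,
                 manifest = manifest))
}

#' Figure-ready long-format tables
#'
#' Builds plot-ready data.frames from pipeline results: the stacked-bar
#' class-abundance summary (per-condition means summing to 1), the
#' enrichment-vs-GC table (one row per class and condition pair), and the
#' per-sample diversity table.
#'
#' @param results list returned by [run_pipeline()].
#' @return list with `stacked_bar`, `enrichment_gc`, `diversity`
#'   data.frames.
#' @export
export_figure_tables <- function(results) {
  enr <- results$records
  if (!is.null(enr))
    enr <- data.frame(class_label = enr$class_label,
                      pair = paste(enr$condition_a, "vs", enr$condition_b),
                      enrichment = enr$enrichment,
                      enrichment_sd = enr$enrichment_sd,
                      weighted_gc = enr$weighted_gc,
                      stringsAsFactors = FALSE)
  list(stacked_bar = results$collapsed, enrichment_gc = enr,
       diversity = results$diversity)
}
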