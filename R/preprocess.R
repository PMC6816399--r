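# Sampling-effort and replicate-structure normalization: rarefy to even
# depth, score within-condition outliers, equalize replicate counts.
# The stage order is fixed: rarefy -> flag_outliers -> equalize_replicates.

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement (a multivariate
#' hypergeometric draw) down to `depth`. Samples with fewer total reads than
#' `depth` are dropped and listed. A single draw is taken per sample; the
#' result is deterministic given `seed`.
#'
#' @param table OTU count matrix (samples x OTUs).
#' @param depth target reads per sample (default 9000).
#' @param seed optional integer seed for the subsampling draw.
#' @param drop_below drop samples shallower than `depth` (default `TRUE`);
#'   when `FALSE` such samples are an error.
#' @return list with `table` (rarefied integer matrix, every row summing to
#'   `depth`) and `dropped_shallow` (character vector of dropped sample ids).
#' @export
rarefy <- function(table, depth = 9000, seed = NULL, drop_below = TRUE) {
  table <- validate_otu_table(table)
  if (length(depth) != 1L || is.na(depth) || depth < 1)
    stop("depth must be a positive integer")
  totals <- rowSums(table)
  shallow <- totals < depth
  if (all(shallow)) stop("no samples survive rarefaction at depth ", depth)
  if (any(shallow) && !drop_below)
    stop("sample(s) shallower than depth ", depth, ": ",
         paste(rownames(table)[shallow], collapse = ", "))
  kept <- table[!shallow, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # vegan heuristically warns when every count exceeds 1; counts here are
  # validated integers, so that warning is noise
  rar <- withCallingHandlers(
    vegan::rrarefy(kept, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(rar) <- "integer"
  list(table = rar, dropped_shallow = rownames(table)[shallow])
}

#' Score within-condition outlier samples
#'
#' For each sample, the score is its mean Bray-Curtis dissimilarity (computed
#' on relative abundances) to the other replicates of the same condition. A
#' sample is flagged when its score exceeds the within-condition
#' median + `k` * MAD. Report-only: nothing is removed here.
#'
#' @param table OTU count matrix.
#' @param metadata sample metadata (see [read_metadata()]).
#' @param k threshold multiplier (default 3); `Inf` disables flagging.
#' @return data.frame with columns `sample_id`, `condition`, `score`,
#'   `threshold`, `flagged`.
#' @export
flag_outliers <- function(table, metadata, k = 3) {
  assert_join_closure(table, data.frame(otu_id = colnames(table)), metadata)
  meta <- metadata[match(rownames(table), metadata$sample_id), ]
  out <- list()
  for (cond in unique(meta$condition)) {
    ids <- meta$sample_id[meta$condition == cond]
    if (length(ids) < 2L) {
      warning("condition '", cond, "' has < 2 samples; outlier scoring skipped")
      next
    }
    sub <- table[ids, , drop = FALSE]
    rel <- sub / rowSums(sub)
    d <- as.matrix(vegan::vegdist(rel, method = "bray"))
    score <- vapply(seq_along(ids),
                    function(i) mean(d[i, -i]), numeric(1L))
    thr <- stats::median(score) + k * stats::mad(score)
    if (is.nan(thr)) thr <- Inf  # k = Inf with zero MAD
    out[[cond]] <- data.frame(sample_id = ids, condition = cond,
                              score = score, threshold = thr,
                              flagged = score > thr,
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_id = character(), condition = character(),
                      score = numeric(), threshold = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equalize replicate counts across conditions
#'
#' Removes uniformly chosen samples from over-represented conditions so that
#' every condition retains exactly `n` replicates. Deterministic given
#' `seed`.
#'
#' @param table OTU count matrix.
#' @param metadata sample metadata.
#' @param n target replicate count, or `"auto"` for the minimum count over
#'   conditions.
#' @param seed optional integer seed for the removal draw.
#' @return list with `table` (balanced matrix) and `removed` (character
#'   vector of removed sample ids).
#' @export
equalize_replicates <- function(table, metadata, n = "auto", seed = NULL) {
  meta <- metadata[metadata$sample_id %in% rownames(table), ]
  counts <- table(meta$condition)
  if (identical(n, "auto")) n <- min(counts)
  n <- as.integer(n)
  if (any(counts < n)) {
    low <- names(counts)[counts < n]
    stop("condition(s) with fewer than ", n, " replicates: ",
         paste(low, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  removed <- character()
  for (cond in names(counts)) {
    ids <- meta$sample_id[meta$condition == cond]
    excess <- length(ids) - n
    if (excess > 0L) removed <- c(removed, sample(ids, excess))
  }
  keep <- setdiff(rownames(table), removed)
  list(table = table[keep, , drop = FALSE], removed = removed)
}

#' Run the full preprocessing stage
#'
#' Applies, in fixed order: rarefaction to even depth, outlier scoring
#' (report-only unless `drop_flagged` or an explicit `drop_samples` list),
#' and replicate equalization.
#'
#' @param table OTU count matrix.
#' @param metadata sample metadata.
#' @param depth rarefaction depth (default 9000).
#' @param seed_rarefy,seed_equalize seeds for the two random steps.
#' @param outlier_k outlier threshold multiplier (default 3).
#' @param drop_samples explicit sample ids to remove after rarefaction
#'   (manual curation list).
#' @param drop_flagged also remove samples flagged by the outlier rule
#'   (default `FALSE`).
#' @param replicates target replicates per condition (`"auto"` = minimum).
#' @return list with `table` (the final matrix) and `report`, a list with
#'   `dropped_shallow`, `outlier_scores`, `flagged_outliers`,
#'   `removed_outliers`, `removed_for_balance`,
#'   `final_replicates_per_condition`.
#' @export
preprocess <- function(table, metadata, depth = 9000, seed_rarefy = NULL,
                       outlier_k = 3, drop_samples = NULL,
                       drop_flagged = FALSE, replicates = "auto",
                       seed_equalize = NULL) {
  r <- rarefy(table, depth = depth, seed = seed_rarefy)
  scores <- flag_outliers(r$table, metadata, k = outlier_k)
  flagged <- scores$sample_id[scores$flagged]
  to_drop <- unique(c(drop_samples, if (drop_flagged) flagged))
  to_drop <- intersect(to_drop, rownames(r$table))
  tab <- r$table[setdiff(rownames(r$table), to_drop), , drop = FALSE]
  eq <- equalize_replicates(tab, metadata, n = replicates,
                            seed = seed_equalize)
  meta_final <- metadata[metadata$sample_id %in% rownames(eq$table), ]
  list(table = eq$table,
       report = list(
         dropped_shallow = r$dropped_shallow,
         outlier_scores = scores,
         flagged_outliers = flagged,
         removed_outliers = to_drop,
         removed_for_balance = eq$removed,
         final_replicates_per_condition =
           as.list(table(meta_final$condition))))
}
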