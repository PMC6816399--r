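# Class-level aggregation, per-condition relative-abundance profiles with
# replicate dispersion, low-abundance collapse, and alpha diversity.

#' Aggregate OTU counts to taxonomic class
#'
#' Sums counts of all member OTUs per class and sample. OTUs without a class
#' rank contribute to the `"Unclassified"` sentinel class. Classes whose
#' total count is zero are not emitted.
#'
#' @param table OTU count matrix (samples x OTUs).
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @return integer matrix, samples x classes; row sums equal those of the
#'   input table.
#' @export
aggregate_to_class <- function(table, taxonomy) {
  assert_join_closure(table, taxonomy)
  cls <- taxonomy$class_label[match(colnames(table), taxonomy$otu_id)]
  ct <- t(rowsum(t(table), group = cls))
  ct <- ct[, colSums(ct) > 0, drop = FALSE]
  storage.mode(ct) <- "integer"
  ct[, order(colnames(ct)), drop = FALSE]
}

#' Per-condition class relative-abundance profiles
#'
#' Converts each sample to relative abundances, then summarizes every
#' (condition, class) cell by the mean and sample standard deviation
#' (n - 1 denominator) across the condition's replicates. These are the A/B
#' and dA/dB inputs of the enrichment statistic.
#'
#' @param class_table class count matrix from [aggregate_to_class()].
#' @param metadata sample metadata.
#' @param allow_single permit conditions with a single replicate (their sd is
#'   reported as `NA`); default `FALSE`, which makes them an error.
#' @return data.frame with columns `condition`, `enzyme`, `temperature_c`,
#'   `class_label`, `mean_rel_abund`, `sd_rel_abund`, `n_replicates`.
#' @export
condition_profiles <- function(class_table, metadata, allow_single = FALSE) {
  assert_join_closure(class_table,
                      data.frame(otu_id = colnames(class_table)), metadata)
  totals <- rowSums(class_table)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(class_table)[totals == 0], collapse = ", "))
  rel <- class_table / totals
  meta <- metadata[match(rownames(class_table), metadata$sample_id), ]
  conds <- unique(meta[, c("condition", "enzyme", "temperature_c")])
  out <- list()
  for (i in seq_len(nrow(conds))) {
    ids <- meta$sample_id[meta$condition == conds$condition[i]]
    if (length(ids) < 2L && !allow_single)
      stop("condition '", conds$condition[i],
           "' has a single replicate; sd undefined (set allow_single = TRUE)")
    sub <- rel[ids, , drop = FALSE]
    out[[i]] <- data.frame(
      condition = conds$condition[i],
      enzyme = conds$enzyme[i],
      temperature_c = conds$temperature_c[i],
      class_label = colnames(rel),
      mean_rel_abund = colMeans(sub),
      sd_rel_abund = if (length(ids) >= 2L) apply(sub, 2L, stats::sd)
                     else NA_real_,
      n_replicates = length(ids),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse low-abundance classes
#'
#' Ranks non-"Unclassified" classes by grand mean relative abundance across
#' conditions and keeps the top `ceiling(top_fraction * K)`; the remainder is
#' merged into a single category whose per-condition mean is the sum of
#' member means and whose sd is the root-sum-square of member sds. Ties at
#' the cutoff are broken by lexicographic class label. `"Unclassified"` is
#' never collapsed.
#'
#' @param profiles data.frame from [condition_profiles()].
#' @param top_fraction fraction of classes to keep (default 0.15).
#' @param label name of the merged category.
#' @return profiles data.frame restricted to kept classes plus the merged
#'   category (and `"Unclassified"` if present).
#' @export
collapse_low_abundance <- function(profiles, top_fraction = 0.15,
                                   label = "Low abundance groups") {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  ranked <- profiles[profiles$class_label != "Unclassified", ]
  grand <- tapply(ranked$mean_rel_abund, ranked$class_label, mean)
  k_all <- length(grand)
  n_keep <- ceiling(top_fraction * k_all)
  ord <- order(-grand, names(grand))
  keep <- names(grand)[ord][seq_len(min(n_keep, k_all))]
  drop <- setdiff(names(grand), keep)
  kept <- profiles[profiles$class_label %in% c(keep, "Unclassified"), ]
  if (!length(drop)) {
    rownames(kept) <- NULL
    return(kept)
  }
  low <- profiles[profiles$class_label %in% drop, ]
  merged <- do.call(rbind, lapply(split(low, low$condition), function(d)
    data.frame(condition = d$condition[1L], enzyme = d$enzyme[1L],
               temperature_c = d$temperature_c[1L], class_label = label,
               mean_rel_abund = sum(d$mean_rel_abund),
               sd_rel_abund = sqrt(sum(d$sd_rel_abund^2)),
               n_replicates = d$n_replicates[1L],
               stringsAsFactors = FALSE)))
  res <- rbind(kept, merged)
  rownames(res) <- NULL
  res
}

#' Per-sample alpha diversity
#'
#' Richness (OTUs with count > 0), Shannon diversity in nats, and Pielou
#' evenness J = H / ln(richness) (reported as `NA` when richness is 1).
#' Intended for rarefied tables; a warning is issued when sample totals are
#' unequal.
#'
#' @param table OTU count matrix.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`.
#' @export
diversity_indices <- function(table) {
  table <- validate_otu_table(table)
  totals <- rowSums(table)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(table)[totals == 0], collapse = ", "))
  if (length(unique(totals)) > 1L)
    warning("sample totals are unequal; indices are depth-sensitive ",
            "(rarefy first)")
  rich <- vegan::specnumber(table)
  h <- vegan::diversity(table, index = "shannon")
  j <- ifelse(rich > 1L, h / log(rich), NA_real_)
  data.frame(sample_id = rownames(table), richness = as.integer(rich),
             shannon = as.numeric(h), pielou = as.numeric(j),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis screen of diversity differences between conditions
#'
#' Convenience report only: one Kruskal-Wallis test per index against the
#' condition factor.
#'
#' @param div data.frame from [diversity_indices()].
#' @param metadata sample metadata.
#' @return data.frame with columns `index`, `statistic`, `df`, `p_value`.
#' @export
diversity_test <- function(div, metadata) {
  cond <- factor(metadata$condition[match(div$sample_id,
                                          metadata$sample_id)])
  do.call(rbind, lapply(c("richness", "shannon", "pielou"), function(idx) {
    x <- div[[idx]]
    ok <- !is.na(x)
    kt <- stats::kruskal.test(x[ok], cond[ok])
    data.frame(index = idx, statistic = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value,
               stringsAsFactors = FALSE)
  }))
}
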