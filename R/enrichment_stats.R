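# The core statistic: normalized between-condition class enrichment
# (A - B)/(A + B), its first-order (delta-method) propagated standard
# deviation, all pairwise condition comparisons, and the per-pair linear
# regression of enrichment on weighted class GC with assumption diagnostics.

#' Normalized class enrichment between two conditions
#'
#' `(a - b) / (a + b)`: 0 when the class is equally proportional in both
#' conditions, 1 when present only in the first, -1 when present only in the
#' second. Undefined (returned as `NA`) when both abundances are zero.
#'
#' @param a,b non-negative mean relative abundances of the class in the two
#'   conditions (vectorized).
#' @return numeric vector in `[-1, 1]`, `NA` where `a + b == 0`.
#' @export
enrichment <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  s <- a + b
  out <- (a - b) / s
  out[s == 0] <- NA_real_
  out
}

#' Propagated standard deviation of the enrichment statistic
#'
#' First-order delta-method propagation of the replicate standard deviations
#' through the enrichment ratio:
#' `2 * sqrt(b^2 * da^2 + a^2 * db^2) / (a + b)^2`.
#'
#' @param a,b non-negative mean relative abundances.
#' @param da,db non-negative standard deviations of `a` and `b`.
#' @return numeric vector of propagated standard deviations, `NA` where
#'   `a + b == 0`.
#' @export
enrichment_sd <- function(a, b, da, db) {
  if (any(c(a, b) < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  if (any(c(da, db) < 0, na.rm = TRUE))
    stop("standard deviations must be non-negative")
  s <- a + b
  out <- 2 * sqrt(b^2 * da^2 + a^2 * db^2) / s^2
  out[s == 0] <- NA_real_
  out
}

# Conditions ordered by enzyme label, then temperature ascending; this fixes
# the orientation (and therefore the sign) of every pairwise comparison.
condition_order <- function(profiles) {
  u <- unique(profiles[, c("condition", "enzyme", "temperature_c")])
  u$condition[order(u$enzyme, u$temperature_c)]
}

#' All pairwise class-enrichment records
#'
#' One record per (class, unordered condition pair), covering all
#' `choose(k, 2)` pairs of the `k` conditions. Orientation is fixed by
#' ordering conditions by enzyme label then temperature, so signs are
#' reproducible. The `"Unclassified"` sentinel is excluded (its GC mixes
#' taxa). A record is flagged `defined = FALSE` when the class is absent from
#' both conditions.
#'
#' @param profiles data.frame from [condition_profiles()].
#' @param dispersion `"sd"` (replicate standard deviation, default) or
#'   `"se"` (standard error, sd / sqrt(n)).
#' @return data.frame with columns `class_label`, `condition_a`,
#'   `condition_b`, `a_mean`, `b_mean`, `a_sd`, `b_sd`, `enrichment`,
#'   `enrichment_sd`, `defined`.
#' @export
pairwise_enrichment <- function(profiles, dispersion = c("sd", "se")) {
  dispersion <- match.arg(dispersion)
  conds <- condition_order(profiles)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  prof <- profiles[profiles$class_label != "Unclassified", ]
  disp <- prof$sd_rel_abund
  if (dispersion == "se") disp <- disp / sqrt(prof$n_replicates)
  key <- paste(prof$condition, prof$class_label, sep = "\r")
  classes <- sort(unique(prof$class_label))
  pairs <- utils::combn(conds, 2L)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    ca <- pairs[1L, j]; cb <- pairs[2L, j]
    ia <- match(paste(ca, classes, sep = "\r"), key)
    ib <- match(paste(cb, classes, sep = "\r"), key)
    a <- ifelse(is.na(ia), 0, prof$mean_rel_abund[ia])
    b <- ifelse(is.na(ib), 0, prof$mean_rel_abund[ib])
    da <- ifelse(is.na(ia), 0, disp[ia])
    db <- ifelse(is.na(ib), 0, disp[ib])
    out[[j]] <- data.frame(
      class_label = classes, condition_a = ca, condition_b = cb,
      a_mean = a, b_mean = b, a_sd = da, b_sd = db,
      enrichment = enrichment(a, b),
      enrichment_sd = enrichment_sd(a, b, da, db),
      defined = (a + b) > 0, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Significance stars for a p-value
#'
#' `***`, `**`, `*` at p < 0.001, 0.01, 0.05; empty string otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Regress class enrichment on weighted GC for one condition pair
#'
#' Ordinary least squares of the enrichment statistic on abundance-weighted
#' class GC. Reports slope, intercept, adjusted R-squared, the slope t value
#' and its two-sided p, significance stars, and assumption diagnostics
#' (Shapiro-Wilk residual normality and Breusch-Pagan homoscedasticity);
#' `assumptions_ok` is `TRUE` when both diagnostic p-values are >= 0.05, and
#' rows failing it carry the caveat flag in pipeline outputs.
#'
#' @param records enrichment records for a single condition pair.
#' @param gc data.frame from [class_weighted_gc()].
#' @return one-row data.frame (`condition_a`, `condition_b`, `n_classes`,
#'   `slope`, `intercept`, `adjusted_r2`, `t_value`, `p_value`,
#'   `significance`, `shapiro_p`, `bp_p`, `assumptions_ok`).
#' @export
fit_gc_regression <- function(records, gc) {
  if (length(unique(paste(records$condition_a, records$condition_b))) != 1L)
    stop("records must belong to a single condition pair")
  d <- merge(records[records$defined & !is.na(records$enrichment), ],
             gc[, c("class_label", "weighted_gc")], by = "class_label")
  if (nrow(d) < 3L)
    stop("need at least 3 classes with defined enrichment and GC")
  if (stats::var(d$weighted_gc) == 0) stop("degenerate covariate: zero GC variance")
  fit <- stats::lm(enrichment ~ weighted_gc, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  # diagnostics are undefined for an (essentially) perfect fit
  shap <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                   error = function(e) NA_real_)
  bp <- tryCatch(lmtest::bptest(fit)$p.value,
                 error = function(e) NA_real_)
  p <- co["weighted_gc", "Pr(>|t|)"]
  data.frame(condition_a = records$condition_a[1L],
             condition_b = records$condition_b[1L],
             n_classes = nrow(d),
             slope = co["weighted_gc", "Estimate"],
             intercept = co["(Intercept)", "Estimate"],
             adjusted_r2 = sm$adj.r.squared,
             t_value = co["weighted_gc", "t value"],
             p_value = p,
             significance = significance_stars(p),
             shapiro_p = shap, bp_p = unname(bp),
             assumptions_ok = !isTRUE(shap < 0.05) && !isTRUE(bp < 0.05),
             stringsAsFactors = FALSE)
}

#' Holm step-down adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, never below the raw values).
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Enrichment records plus GC regressions for all condition pairs
#'
#' Convenience wrapper binding [pairwise_enrichment()] and
#' [fit_gc_regression()] over every pair.
#'
#' @param profiles data.frame from [condition_profiles()].
#' @param gc data.frame from [class_weighted_gc()].
#' @param dispersion passed to [pairwise_enrichment()].
#' @param holm add a Holm-adjusted p-value column (default `FALSE`; the
#'   per-pair tests are reported unadjusted by default).
#' @return list with `records` and `regressions` data.frames.
#' @export
analyze_enrichment <- function(profiles, gc, dispersion = "sd",
                               holm = FALSE) {
  records <- pairwise_enrichment(profiles, dispersion = dispersion)
  pairs <- unique(records[, c("condition_a", "condition_b")])
  regs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
    sub <- records[records$condition_a == pairs$condition_a[j] &
                   records$condition_b == pairs$condition_b[j], ]
    fit_gc_regression(sub, gc)
  }))
  if (holm) regs$p_holm <- holm_adjust(regs$p_value)
  rownames(regs) <- NULL
  list(records = records, regressions = regs)
}
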