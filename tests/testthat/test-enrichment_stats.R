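# random non-negative abundance pairs, bounded away from a + b == 0
random_pairs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(a = runif(n, 0, 1), b = runif(n, 0, 1),
             da = runif(n, 0, 0.2), db = runif(n, 0, 0.2))
}

test_that("enrichment hits its analytic anchor values", {
  expect_identical(enrichment(0.25, 0.25), 0)
  expect_identical(enrichment(0.3, 0), 1)
  expect_identical(enrichment(0, 0.3), -1)
  expect_equal(enrichment(0.3, 0.1), 0.5)
  expect_true(is.na(enrichment(0, 0)))
  expect_error(enrichment(-0.1, 0.2), "non-negative")
})

test_that("enrichment is antisymmetric, bounded and scale invariant", {
  p <- random_pairs(10000)
  e <- enrichment(p$a, p$b)
  expect_equal(e, -enrichment(p$b, p$a))
  expect_true(all(abs(e) <= 1))
  expect_equal(enrichment(3.7 * p$a, 3.7 * p$b), e, tolerance = 1e-12)
  # sign structure
  expect_true(all(sign(e) == sign(p$a - p$b)))
})

test_that("propagated sd matches the delta-method gradient oracle", {
  expect_identical(enrichment_sd(0.4, 0.2, 0, 0), 0)
  expect_equal(enrichment_sd(0.5, 0.5, 0.1, 0.1), 2 * sqrt(0.005))
  p <- random_pairs(1000, seed = 2)
  got <- enrichment_sd(p$a, p$b, p$da, p$db)
  # independent oracle: sqrt((df/dA)^2 dA^2 + (df/dB)^2 dB^2) with the
  # partial derivatives of (A-B)/(A+B)
  dfda <- 2 * p$b / (p$a + p$b)^2
  dfdb <- -2 * p$a / (p$a + p$b)^2
  oracle <- sqrt(dfda^2 * p$da^2 + dfdb^2 * p$db^2)
  expect_equal(got, oracle, tolerance = 1e-13)
  # swap symmetry
  expect_equal(enrichment_sd(p$b, p$a, p$db, p$da), got)
})

test_that("propagated sd agrees with Monte-Carlo perturbation", {
  set.seed(42)
  n <- 20000
  for (ab in list(c(0.5, 0.5), c(0.3, 0.1), c(0.2, 0.6))) {
    noise <- 0.01 * sum(ab)
    A <- rnorm(n, ab[1], noise)
    B <- rnorm(n, ab[2], noise)
    mc <- stats::sd((A - B) / (A + B))
    mc_err <- mc / sqrt(2 * (n - 1))
    expect_lt(abs(enrichment_sd(ab[1], ab[2], noise, noise) - mc),
              3 * mc_err + 1e-4)
  }
})

four_cond_profiles <- function() {
  sim <- simulate_experiment(small_scenario())
  ct <- aggregate_to_class(sim$table, sim$taxonomy)
  list(prof = condition_profiles(ct, sim$metadata), sim = sim)
}

test_that("pairwise enrichment emits all C(k,2) pairs with fixed orientation", {
  x <- four_cond_profiles()
  rec <- pairwise_enrichment(x$prof)
  pairs <- unique(rec[, c("condition_a", "condition_b")])
  expect_equal(nrow(pairs), 6)               # 4 conditions -> 6 pairs
  # orientation: enzyme then temperature ascending
  expect_equal(pairs$condition_a[1], "ImProm-II 42")
  expect_false(any(rec$class_label == "Unclassified"))
  expect_true(all(abs(rec$enrichment[rec$defined]) <= 1))
  # a record per (class, pair)
  n_classes <- length(setdiff(unique(x$prof$class_label), "Unclassified"))
  expect_equal(nrow(rec), 6 * n_classes)
})

test_that("swapping pair orientation negates every enrichment", {
  x <- four_cond_profiles()
  rec <- pairwise_enrichment(x$prof)
  sub <- rec[rec$defined, ]
  expect_equal(enrichment(sub$b_mean, sub$a_mean), -sub$enrichment)
})

test_that("classes absent from both conditions are flagged undefined", {
  prof <- rbind(
    data.frame(condition = "EnzA 50", enzyme = "EnzA", temperature_c = 50,
               class_label = c("C1", "C2"), mean_rel_abund = c(1, 0),
               sd_rel_abund = 0, n_replicates = 4),
    data.frame(condition = "EnzB 50", enzyme = "EnzB", temperature_c = 50,
               class_label = c("C1", "C2"), mean_rel_abund = c(1, 0),
               sd_rel_abund = 0, n_replicates = 4))
  rec <- pairwise_enrichment(prof)
  expect_false(rec$defined[rec$class_label == "C2"])
  expect_true(is.na(rec$enrichment[rec$class_label == "C2"]))
})

test_that("exactly collinear data give adjusted R2 of 1 and p near 0", {
  gc <- data.frame(class_label = sprintf("C%02d", 1:10),
                   weighted_gc = seq(0.3, 0.8, length.out = 10))
  rec <- data.frame(class_label = gc$class_label,
                    condition_a = "A 1", condition_b = "B 2",
                    a_mean = 0.1, b_mean = 0.1, a_sd = 0, b_sd = 0,
                    enrichment = 2 * gc$weighted_gc - 1,
                    enrichment_sd = 0, defined = TRUE)
  # lm itself warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_gc_regression(rec, gc))
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$significance, "***")
  expect_equal(fit$slope, 2, tolerance = 1e-9)
})

test_that("regression guards degenerate inputs", {
  gc <- data.frame(class_label = c("C1", "C2", "C3"),
                   weighted_gc = c(0.5, 0.5, 0.5))
  rec <- data.frame(class_label = gc$class_label,
                    condition_a = "A 1", condition_b = "B 2",
                    a_mean = 0.1, b_mean = 0.2, a_sd = 0, b_sd = 0,
                    enrichment = c(0.1, 0.2, 0.3), enrichment_sd = 0,
                    defined = TRUE)
  expect_error(fit_gc_regression(rec, gc), "degenerate covariate")
  expect_error(fit_gc_regression(rec[1:2, ], gc), "at least 3")
})

test_that("significance stars follow the 0.05 / 0.01 / 0.001 thresholds", {
  expect_equal(significance_stars(c(0.0009, 0.0099, 0.02, 0.05, 0.2)),
               c("***", "**", "*", "", ""))
})

test_that("the slope test attains its nominal level under permutation", {
  set.seed(303)
  n_cls <- 12
  gc <- data.frame(class_label = sprintf("C%02d", 1:n_cls),
                   weighted_gc = runif(n_cls, 0.3, 0.8))
  reps <- 500
  p <- vapply(seq_len(reps), function(i) {
    rec <- data.frame(class_label = gc$class_label,
                      condition_a = "A 1", condition_b = "B 2",
                      a_mean = 0.1, b_mean = 0.1, a_sd = 0, b_sd = 0,
                      enrichment = sample(rnorm(n_cls)), enrichment_sd = 0,
                      defined = TRUE)
    fit_gc_regression(rec, gc)$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("Holm adjustment is monotone and never below raw p", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  set.seed(5)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(sort(adj)) >= 0))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("analyze_enrichment binds regressions for every pair with optional Holm", {
  x <- four_cond_profiles()
  gc <- class_weighted_gc(x$sim$taxonomy, x$sim$seqs,
                          otu_weights(x$sim$table))
  res <- analyze_enrichment(x$prof, gc, holm = TRUE)
  expect_equal(nrow(res$regressions), 6)
  expect_true(all(res$regressions$p_holm >= res$regressions$p_value))
  expect_equal(res$regressions$significance,
               significance_stars(res$regressions$p_value))
})
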