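test_that("class aggregation is additive and routes Unclassified", {
  m <- matrix(c(3L, 4L, 5L), nrow = 1,
              dimnames = list("S1", c("a", "b", "c")))
  tax <- data.frame(otu_id = c("a", "b", "c"),
                    lineage = c("B;P;Bacilli", "B;P;Bacilli", "B;P"),
                    class_label = c("Bacilli", "Bacilli", "Unclassified"),
                    stringsAsFactors = FALSE)
  ct <- aggregate_to_class(m, tax)
  expect_equal(ct["S1", "Bacilli"], 7L)
  expect_equal(ct["S1", "Unclassified"], 5L)
})

test_that("aggregation conserves reads exactly and drops all-zero classes", {
  sim <- simulate_experiment(small_scenario())
  ct <- aggregate_to_class(sim$table, sim$taxonomy)
  expect_identical(unname(rowSums(ct)), unname(rowSums(sim$table)))
  expect_true(all(colSums(ct) > 0))

  # a class whose only OTU has zero counts everywhere is not emitted
  m <- cbind(toy_table(), OTUz = 0L)
  tax <- rbind(toy_taxonomy(),
               data.frame(otu_id = "OTUz", lineage = "B;P;Ghost",
                          class_label = "Ghost"))
  expect_false("Ghost" %in% colnames(aggregate_to_class(m, tax)))
})

test_that("single-class tables aggregate to the row totals", {
  m <- toy_table()
  tax <- toy_taxonomy()
  tax$class_label <- "OnlyClass"
  ct <- aggregate_to_class(m, tax)
  expect_equal(dim(ct), c(4L, 1L))
  expect_equal(unname(ct[, 1]), unname(rowSums(m)))
})

test_that("condition profiles use the n-1 standard deviation and sum to one", {
  # two replicates with class fractions 0.2 and 0.4 -> mean 0.3, sd 0.1414
  m <- rbind(S1 = c(20L, 80L), S2 = c(40L, 60L),
             S3 = c(50L, 50L), S4 = c(50L, 50L))
  colnames(m) <- c("ClassA", "ClassB")
  md <- make_metadata(rownames(m), c("X", "X", "Y", "Y"))
  prof <- condition_profiles(m, md)
  a <- prof[prof$class_label == "ClassA" & prof$enzyme == "EnzX", ]
  expect_equal(a$mean_rel_abund, 0.3)
  expect_equal(a$sd_rel_abund, stats::sd(c(0.2, 0.4)))
  sums <- tapply(prof$mean_rel_abund, prof$condition, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-9)
})

test_that("profiles are scale-free in per-sample sequencing effort", {
  m <- toy_table()
  md <- toy_metadata()
  m2 <- m
  m2["S1", ] <- m2["S1", ] * 7L
  expect_equal(condition_profiles(m, md), condition_profiles(m2, md))
})

test_that("single-replicate conditions error unless explicitly allowed", {
  m <- toy_table()[1:3, ]
  md <- toy_metadata()[1:3, ]
  expect_error(condition_profiles(m, md), "single replicate")
  prof <- condition_profiles(m, md, allow_single = TRUE)
  expect_true(all(is.na(prof$sd_rel_abund[prof$condition == "EnzB 55"])))
})

# profiles fixture: K classes + Unclassified over 2 conditions, geometric
# abundances
profile_fixture <- function(K = 20) {
  cls <- sprintf("C%02d", 1:K)
  mk <- function(cond, enz) {
    w <- 0.8^(1:K)
    w <- w / sum(w) * 0.98
    data.frame(condition = cond, enzyme = enz, temperature_c = 50,
               class_label = c(cls, "Unclassified"),
               mean_rel_abund = c(w, 0.02),
               sd_rel_abund = 0.01, n_replicates = 4,
               stringsAsFactors = FALSE)
  }
  rbind(mk("EnzA 50", "EnzA"), mk("EnzB 50", "EnzB"))
}

test_that("low-abundance collapse keeps ceil(0.15 K) classes and conserves mass", {
  prof <- profile_fixture(20)
  col <- collapse_low_abundance(prof, top_fraction = 0.15)
  kept <- setdiff(unique(col$class_label),
                  c("Low abundance groups", "Unclassified"))
  expect_length(kept, 3)           # ceiling(0.15 * 20)
  expect_setequal(kept, c("C01", "C02", "C03"))
  # mass conservation per condition
  before <- tapply(prof$mean_rel_abund, prof$condition, sum)
  after <- tapply(col$mean_rel_abund, col$condition, sum)
  expect_equal(after, before, tolerance = 1e-12)
  # merged sd is root-sum-square of member sds (17 members at 0.01)
  low <- col[col$class_label == "Low abundance groups", ]
  expect_equal(low$sd_rel_abund, rep(sqrt(17 * 0.01^2), 2))
})

test_that("collapse at top_fraction 1 is the identity", {
  prof <- profile_fixture(10)
  col <- collapse_low_abundance(prof, top_fraction = 1)
  expect_setequal(col$class_label, prof$class_label)
  expect_false("Low abundance groups" %in% col$class_label)
})

test_that("diversity indices match closed forms", {
  m <- rbind(uniform = c(25L, 25L, 25L, 25L),
             single = c(100L, 0L, 0L, 0L),
             mixed = c(1L, 1L, 2L, 0L))
  colnames(m) <- paste0("OTU", 1:4)
  suppressWarnings(d <- diversity_indices(m))
  expect_equal(d$richness, c(4L, 1L, 3L))
  expect_equal(d$shannon[1], log(4))
  expect_equal(d$pielou[1], 1)
  expect_equal(d$shannon[2], 0)
  expect_true(is.na(d$pielou[2]))
  expect_equal(d$shannon[3],
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_true(all(d$pielou >= 0 & d$pielou <= 1, na.rm = TRUE))

  m0 <- rbind(S1 = c(0L, 0L))
  colnames(m0) <- c("OTU1", "OTU2")
  expect_error(diversity_indices(m0), "zero-total")
})

test_that("diversity Kruskal-Wallis screen reports one valid p per index", {
  sim <- simulate_experiment(small_scenario())
  d <- diversity_indices(sim$table)
  kt <- diversity_test(d, sim$metadata)
  expect_equal(kt$index, c("richness", "shannon", "pielou"))
  expect_true(all(kt$p_value >= 0 & kt$p_value <= 1))
})
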