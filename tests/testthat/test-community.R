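make_table <- function(m, periods = NULL) {
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))), paste0("t", seq_len(ncol(m))))
  meta <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(periods)) meta$period <- periods
  community_table(m, meta)
}

test_that("low-count filter applies the dataset-wide threshold", {
  tab <- make_table(rbind(c(4, 5, 6), c(5, 5, 5)))  # totals 9, 10, 11
  f <- filter_low_count_taxa(tab, min_total = 10)
  expect_equal(ncol(f$counts), 2)
  expect_equal(colnames(f$counts), c("t2", "t3"))
  expect_equal(nrow(f$counts), 2)
  expect_equal(ncol(filter_low_count_taxa(tab, 0)$counts), 3)
  tab0 <- make_table(matrix(0, 2, 2))
  expect_warning(f0 <- filter_low_count_taxa(tab0, 10), "no taxa")
  expect_equal(ncol(f0$counts), 0)
})

test_that("rarefaction hits the target depth deterministically", {
  tab <- random_table(n = 6, p = 10, lambda = 50, seed = 2)
  r1 <- rarefy_table(tab, depth = 100, seed = 9)
  r2 <- rarefy_table(tab, depth = 100, seed = 9)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(rowSums(r1$counts) == 100))
  # identity when depth equals the sample sum
  one <- make_table(matrix(c(30, 20), 1, 2))
  expect_equal(rarefy_table(one, depth = 50, seed = 1)$counts, one$counts)
  # single-taxon mass stays on that taxon
  two <- make_table(matrix(c(100, 0), 1, 2))
  expect_equal(as.vector(rarefy_table(two, depth = 50, seed = 1)$counts), c(50, 0))
  expect_error(rarefy_table(tab, depth = 0), "positive")
  expect_warning(rarefy_table(tab, depth = max(rowSums(tab$counts)), seed = 1), "dropping")
})

test_that("rarefaction preserves expected relative abundance", {
  tab <- make_table(matrix(c(600, 300, 100), 1, 3))
  mean_rel <- Reduce(`+`, lapply(1:1000, function(s) {
    relative_abundance(rarefy_table(tab, depth = 50, seed = s))
  })) / 1000
  expect_equal(as.vector(mean_rel), c(0.6, 0.3, 0.1), tolerance = 0.02)
})

test_that("occupancy classes follow the 75/50 rule with strict satellite bound", {
  n <- 34
  m <- matrix(0, n, 4)
  m[1:26, 1] <- 5   # 26/34 = 0.765 -> core
  m[1:17, 2] <- 5   # 17/34 = 0.50  -> intermediate (not satellite)
  m[1:16, 3] <- 5   # 16/34 < 0.50  -> satellite
  m[, 4] <- 1       # filler keeps every sample non-empty
  part <- partition_taxa(make_table(m))
  expect_equal(as.character(part$occupancy_class[1:3]), c("core", "intermediate", "satellite"))
  expect_equal(part$occurrence_frequency[1], 26 / 34)
})

test_that("abundance categories are assigned by the six-way rule", {
  # columns engineered on 4 samples with depth 1000:
  # t1 always >= 1%; t2 moderate everywhere; t3 always < 0.01% (absent);
  # t4 sometimes abundant never rare; t5 never abundant sometimes rare;
  # t6 spans rare to abundant
  m <- rbind(
    c(100, 5, 0, 20, 5, 0),
    c(100, 5, 0, 20, 5, 200),
    c(100, 5, 0, 5, 5, 200),
    c(100, 5, 0, 20, 0, 200)
  )
  m <- cbind(m, 1000 - rowSums(m))  # filler taxon keeps sums at 1000
  part <- partition_taxa(make_table(m))
  expect_equal(as.character(part$abundance_class[1:6]),
               c("AAT", "MT", "ART", "CAT", "CRT", "CRAT"))
})

test_that("abundance categories are mutually exclusive and exhaustive", {
  withr::with_seed(13, {
    for (i in 1:25) {
      m <- matrix(rpois(8 * 30, lambda = sample(c(1, 5, 100), 1)), 8, 30)
      if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1
      part <- partition_taxa(make_table(m))
      expect_false(any(is.na(part$abundance_class)))
    }
  })
  expect_error(partition_taxa(random_table(), rare_thr = 0.5, abundant_thr = 0.1), "rare_thr")
})

test_that("partitioning is invariant to sample and taxon order", {
  tab <- random_table(n = 12, p = 15, lambda = 3, seed = 4)
  part <- partition_taxa(tab)
  perm <- withr::with_seed(1, list(s = sample(1:12), t = sample(1:15)))
  tab2 <- community_table(tab$counts[perm$s, perm$t],
                          tab$sample_meta[perm$s, , drop = FALSE])
  part2 <- partition_taxa(tab2)
  part2 <- part2[match(part$taxon_id, part2$taxon_id), ]
  expect_equal(as.character(part$occupancy_class), as.character(part2$occupancy_class))
  expect_equal(as.character(part$abundance_class), as.character(part2$abundance_class))
})

test_that("absolute abundance scales relative abundance by the qPCR total", {
  m <- rbind(c(50, 50), c(10, 90))
  tab <- make_table(m)
  part <- partition_taxa(tab)
  ab <- absolute_abundance(tab, c(s1 = 1e6, s2 = 2e6), part)
  expect_equal(ab$per_taxon["s1", "t1"], 5e5)
  # conservation: per-sample sums equal the qPCR totals
  expect_equal(unname(rowSums(ab$per_taxon)), c(1e6, 2e6))
  expect_equal(ab$group_sums$entire, c(1e6, 2e6))
  # compositional invariance: doubling counts changes nothing
  ab2 <- absolute_abundance(make_table(2 * m), c(s1 = 1e6, s2 = 2e6), part)
  expect_equal(ab2$per_taxon, ab$per_taxon)
  expect_error(absolute_abundance(tab, c(s1 = 1e6), part), "s2")
})

test_that("core taxa are more abundant than satellite taxa in default scenarios", {
  ds <- generate_scenario(scenario_config(seed = 21))
  for (d in c("surface", "bottom")) {
    part <- partition_taxa(rarefy_table(filter_low_count_taxa(ds$community[[d]]), seed = 21))
    core_mean <- mean(part$mean_relative_abundance[part$occupancy_class == "core"])
    sat_mean <- mean(part$mean_relative_abundance[part$occupancy_class == "satellite"])
    expect_gt(core_mean, sat_mean)
  }
})

test_that("Kruskal-Wallis letters separate clear groups and merge identical ones", {
  vals <- c(1, 2, 3, 101, 102, 103, 201, 202, 203)
  lab <- rep(c("a", "b", "c"), each = 3)
  # exact permutation oracle confirms the global separation is significant
  expect_lt(kw_exact_p(vals, lab), 0.05)
  res <- compare_groups_kw(vals, lab)
  expect_equal(length(unique(res$letters)), 3)
  # identical distributions share one letter
  same <- compare_groups_kw(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$letters == "a"))
  # constant input: p = 1 by convention
  const <- compare_groups_kw(rep(2, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(const$p, 1)
  expect_true(all(const$letters == "a"))
  expect_error(compare_groups_kw(1:3, c("a", "a", "b")), ">= 2")
})

test_that("two-group H equals the squared normal rank-sum statistic", {
  withr::with_seed(31, {
    x <- rnorm(30)
    g <- rep(c("a", "b"), each = 15)
    H <- compare_groups_kw(x, g)$H
    w <- wilcox.test(x[g == "a"], x[g == "b"], exact = FALSE, correct = FALSE)
    n1 <- 15; n2 <- 15
    z <- (w$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    expect_equal(H, unname(z^2), tolerance = 1e-10)
  })
})
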