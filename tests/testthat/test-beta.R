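test_that("Bray-Curtis matches the direct formula and its 2W identity", {
  m <- rbind(x = c(1, 2), y = c(2, 1))
  colnames(m) <- c("t1", "t2")
  d <- bray_curtis(m)
  expect_equal(as.vector(d), 1 / 3)
  # identical samples -> 0; disjoint supports -> 1
  expect_equal(as.vector(bray_curtis(rbind(c(3, 1), c(3, 1)))), 0)
  expect_equal(as.vector(bray_curtis(rbind(c(5, 0), c(0, 7)))), 1)
  # algebraic identity d = 1 - 2W/(A+B) on random tables
  withr::with_seed(3, {
    for (i in 1:20) {
      y <- matrix(rpois(4 * 8, 10) + 0.0, 4, 8)
      if (any(rowSums(y) == 0)) y[rowSums(y) == 0, 1] <- 1
      d <- as.matrix(bray_curtis(y))
      for (j in 1:3) {
        for (k in (j + 1):4) {
          w <- sum(pmin(y[j, ], y[k, ]))
          expect_equal(d[j, k], 1 - 2 * w / (sum(y[j, ]) + sum(y[k, ])), tolerance = 1e-12)
        }
      }
    }
  })
  m0 <- rbind(c(0, 0), c(1, 1))
  rownames(m0) <- c("bad", "ok")
  expect_error(bray_curtis(m0), "bad")
})

test_that("NMDS embeds Euclidean configurations and is seed-deterministic", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  d <- dist(pts)
  o1 <- nmds(d, seed = 2)
  expect_lt(o1$stress, 0.01)
  o2 <- nmds(d, seed = 2)
  expect_identical(o1$points, o2$points)
  # monotone transform of the input distances preserves the rank order of
  # the recovered configuration distances
  withr::with_seed(5, {
    y <- matrix(runif(10 * 2), 10, 2)
    d1 <- dist(y)
    d2 <- d1^1.7
    c1 <- nmds(d1, seed = 3)
    c2 <- nmds(d2, seed = 3)
    expect_gt(cor(dist(c1$points), dist(c2$points), method = "spearman"), 0.95)
  })
})

test_that("ANOSIM matches its definition, vegan, and exact enumeration", {
  # complete separation between two tight clusters -> R = 1
  m <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  d <- dist(m)
  g <- rep(c("a", "b"), each = 4)
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  # cross-check R against the independent oracle and vegan on random data
  withr::with_seed(9, {
    for (i in 1:5) {
      y <- matrix(rpois(6 * 5, 10), 6, 5)
      if (any(rowSums(y) == 0)) y[rowSums(y) == 0, 1] <- 1
      dm <- bray_curtis(y)
      gg <- rep(c("a", "b"), each = 3)
      mine <- anosim_test(dm, gg, n_perm = 99, seed = i)
      expect_equal(mine$R, anosim_R_oracle(dm, gg), tolerance = 1e-12)
      veg <- vegan::anosim(dm, gg, permutations = 9)
      expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-12)
    }
  })
  expect_error(anosim_test(d, rep("a", 8)), ">= 2")
  expect_error(anosim_test(d, c("a", rep("b", 7))), ">= 2 members")
})

test_that("SIMPER decomposes the mean between-group dissimilarity", {
  # single taxon: 100% contribution
  y <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("s", 1:4), "t1"))
  s <- simper_contributions(y, rep(c("a", "b"), each = 2))
  expect_equal(s$a_vs_b$contribution_pct, 100)
  # two-taxon toy equals brute-force enumeration over pairs
  y2 <- rbind(c(5, 5), c(8, 2), c(1, 9), c(6, 4))
  rownames(y2) <- paste0("s", 1:4); colnames(y2) <- c("t1", "t2")
  g <- c("a", "a", "b", "b")
  rel <- y2 / rowSums(y2)
  pair_terms <- matrix(0, 2, 2)
  for (j in 1:2) for (k in 3:4) {
    pair_terms[j, ] <- pair_terms[j, ] +
      abs(rel[j, ] - rel[k, ]) / (sum(rel[j, ]) + sum(rel[k, ]))
  }
  brute <- colSums(pair_terms) / 4
  s2 <- simper_contributions(y2, g)$a_vs_b
  expect_equal(sort(s2$average), sort(unname(brute)), tolerance = 1e-12)
  mean_d <- mean(as.matrix(bray_curtis(y2))[1:2, 3:4])
  expect_equal(attr(s2, "mean_dissimilarity"), mean_d, tolerance = 1e-12)
  expect_equal(sum(s2$contribution_pct), 100, tolerance = 1e-12)
})

test_that("time-lag analysis uses 30.44-day months and recovers trends", {
  d2 <- as.dist(matrix(c(0, .5, .5, 0), 2))
  tl <- time_lag(d2, as.Date("2020-01-01") + c(0, 30.44))
  expect_equal(tl$pairs$lag_months, 1.0)
  # constant dissimilarity -> zero slope
  dc <- as.dist(matrix(0.4, 5, 5) - diag(0.4, 5))
  # constant response: lm warns about a perfect fit, which is the point
  tlc <- suppressWarnings(time_lag(dc, as.Date("2020-01-01") + seq(0, 120, by = 30)))
  expect_equal(tlc$slope, 0, tolerance = 1e-12)
  # divergence recovery: dissimilarity = 0.01 * lag + noise
  withr::with_seed(17, {
    n <- 20
    dates <- as.Date("2015-07-01") + seq(0, by = 10, length.out = n)
    lagm <- abs(outer(as.numeric(dates), as.numeric(dates), "-")) / 30.44
    dd <- as.dist(0.01 * lagm + matrix(runif(n * n, 0, 0.02), n, n))
    tlr <- time_lag(dd, dates)
    expect_lt(abs(tlr$slope - 0.01), 0.004)
    expect_lt(tlr$p, 0.01)
  })
})

test_that("period-pair bins have the right combinatorial sizes", {
  periods <- rep(c("before", "mixing", "after"), c(14, 11, 9))
  withr::with_seed(23, {
    y <- matrix(rpois(34 * 10, 20), 34, 10)
    pp <- period_pair_dissimilarity(bray_curtis(y), periods)
  })
  expect_equal(
    as.vector(pp$bin_sizes[c("B-B", "M-M", "A-A", "B-M", "B-A", "M-A")]),
    c(choose(14, 2), choose(11, 2), choose(9, 2), 14 * 11, 14 * 9, 11 * 9)
  )
  expect_equal(sum(pp$bin_sizes), choose(34, 2))
  # surface recovery scenario: before-vs-after pairs closer than before-vs-mixing
  ds <- generate_scenario(scenario_config(seed = 29))
  tab <- rarefy_table(filter_low_count_taxa(ds$community$surface), seed = 29)
  part <- partition_taxa(tab)
  core_tab <- coresat:::subset_community(tab, taxa = part$taxon_id[part$occupancy_class == "core"])
  pp2 <- period_pair_dissimilarity(bray_curtis(core_tab), tab$sample_meta$period)
  med <- tapply(pp2$pairs$dissimilarity, pp2$pairs$bin, median)
  expect_lt(med[["B-A"]], med[["B-M"]])
})

test_that("ANOSIM R stays within [-1, 1] on random instances", {
  withr::with_seed(41, {
    for (i in 1:200) {
      n <- sample(6:10, 1)
      y <- matrix(runif(n * 4), n, 4)
      g <- sample(rep(c("a", "b"), c(floor(n / 2), ceiling(n / 2))))
      R <- anosim_test(dist(y), g, n_perm = 9, seed = i)$R
      expect_gte(R, -1)
      expect_lte(R, 1)
    }
  })
})
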