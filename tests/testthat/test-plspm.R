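test_that("single-indicator blocks reduce exactly to OLS path analysis", {
  withr::with_seed(11, {
    n <- 200
    x <- rnorm(n); z <- 0.5 * x + rnorm(n); y <- 0.4 * x - 0.3 * z + rnorm(n)
    d <- data.frame(x = x, z = z, y = y)
  })
  blocks <- list(X = "x", Z = "z", Y = "y")
  inner <- matrix(0, 3, 3, dimnames = list(names(blocks), names(blocks)))
  inner["Z", "X"] <- 1
  inner["Y", c("X", "Z")] <- 1
  fit <- fit_plspm(d, blocks, inner)
  sx <- scale(d)
  ols_z <- coef(lm(sx[, "z"] ~ sx[, "x"] - 1))
  ols_y <- coef(lm(sx[, "y"] ~ sx[, c("x", "z")] - 1))
  expect_equal(fit$path_matrix["Z", "X"], unname(ols_z), tolerance = 1e-10)
  expect_equal(unname(fit$path_matrix["Y", c("X", "Z")]), unname(ols_y), tolerance = 1e-10)
  # R^2 equals the OLS R^2 and communalities are 1
  expect_equal(unname(fit$r_squared["Y"]),
               summary(lm(sx[, "y"] ~ sx[, c("x", "z")]))$r.squared, tolerance = 1e-10)
  expect_equal(unname(fit$communality), rep(1, 3))
  expect_true(fit$gof >= 0 && fit$gof <= 1)
})

test_that("a two-LV single-indicator path is recovered without bias", {
  est <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 10000
      x <- rnorm(n)
      y <- 0.6 * x + rnorm(n, 0, sqrt(1 - 0.36))
      d <- data.frame(x = x, y = y)
    })
    inner <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
                    dimnames = list(c("X", "Y"), c("X", "Y")))
    fit_plspm(d, list(X = "x", Y = "y"), inner)$path_matrix["Y", "X"]
  }, 1)
  expect_lt(abs(mean(est) - 0.6), 0.02)
})

test_that("loadings and paths of a three-block chain are recovered", {
  fits <- lapply(1:8, function(s) {
    fit_plspm(sim_chain_composite(5000, seed = s), chain_blocks3, chain_inner3())
  })
  loadings <- rowMeans(sapply(fits, function(f) f$loadings$loading))
  expect_lt(max(abs(loadings - rep(c(0.9, 0.8, 0.85), 3))), 0.05)
  paths <- rowMeans(sapply(fits, function(f) f$paths$coefficient))
  expect_lt(max(abs(paths - c(0.5, 0.3))), 0.05)
  gofs <- vapply(fits, function(f) f$gof, 1)
  expect_true(all(gofs >= 0 & gofs <= 1))
})

test_that("weak indicators are pruned iteratively at the 0.7 rule", {
  d <- sim_chain_composite(2000, seed = 3)
  withr::with_seed(4, d$x2_junk <- rnorm(2000))  # unrelated indicator in block 2
  blocks <- chain_blocks3
  blocks$LV2 <- c(blocks$LV2, "x2_junk")
  fit <- fit_plspm(d, blocks, chain_inner3())
  expect_true("x2_junk" %in% fit$pruned)
  expect_false("x2_junk" %in% fit$blocks$LV2)
  expect_true(all(abs(fit$loadings$loading) >= 0.7))
  # a block whose indicators are mutually orthogonal all load near
  # 1/sqrt(3) < 0.7 on the composite, so pruning empties it and errors
  withr::with_seed(5, {
    q <- qr.Q(qr(matrix(rnorm(500 * 4), 500, 4)))
    bad <- data.frame(
      a = q[, 1],
      b = q[, 2] + 0.05 * q[, 1],
      c = q[, 3] + 0.05 * q[, 1],
      e = q[, 4] + 0.05 * q[, 1]
    )
  })
  blocks2 <- list(A = "a", B = c("b", "c", "e"))
  inner2 <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(fit_plspm(bad, blocks2, inner2), "every indicator")
})

test_that("the model spec is validated", {
  d <- data.frame(x = rnorm(20), y = rnorm(20))
  inner <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_error(fit_plspm(d, list(X = "x", Y = "nope"), inner), "absent")
  bad_inner <- matrix(1, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_error(fit_plspm(d, list(X = "x", Y = "y"), bad_inner), "lower-triangular")
})

test_that("bootstrap intervals are seed-stable and detect strong paths", {
  withr::with_seed(21, {
    n <- 200
    x <- rnorm(n)
    y <- 0.7 * x + rnorm(n, 0, sqrt(1 - 0.49))
    d <- data.frame(x = x, y = y)
  })
  inner <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE, dimnames = list(c("X", "Y"), c("X", "Y")))
  fit <- fit_plspm(d, list(X = "x", Y = "y"), inner)
  b1 <- bootstrap_paths(fit, n_boot = 199, seed = 7)
  b2 <- bootstrap_paths(fit, n_boot = 199, seed = 7)
  expect_identical(b1, b2)
  expect_lt(b1$p, 0.1)
  expect_true(b1$lower > 0.4 && b1$upper < 1)
})
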