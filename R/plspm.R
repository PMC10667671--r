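# Partial least squares path modelling (PLS-PM): Lohmoeller's alternating
# outer/inner estimation with reflective (mode A) measurement, centroid
# inner weighting by default, OLS inner path coefficients, and iterative
# pruning of weak indicators.

#' Fit a PLS path model
#'
#' Estimates latent variable (LV) scores by Lohmoeller's alternating
#' algorithm: indicators are standardized; outer approximation builds each
#' LV as a weighted sum of its block's indicators (mode A: weights
#' proportional to the covariance between indicator and the inner proxy);
#' inner approximation builds each proxy from the LV's structural
#' neighbours (centroid scheme: signs of inter-LV correlations; factorial:
#' the correlations themselves; path: regression weights on predecessors,
#' correlations with successors). Iteration stops when the largest absolute
#' weight change falls below `tol`. Path coefficients are then OLS
#' regressions of each endogenous LV on its predecessors; R^2 per
#' endogenous LV; block communality is the mean squared loading; and
#' GoF = sqrt(mean communality x mean R^2). Each LV's sign is aligned to
#' correlate positively with its first indicator.
#'
#' When `prune = TRUE` (the default), indicators with |loading| below
#' `loading_min` are removed and the model refitted until none remain, the
#' usual reflective-measurement pruning rule.
#'
#' @param data data.frame or matrix of indicators (samples in rows).
#' @param blocks named list mapping each LV name to a character vector of
#'   indicator column names.
#' @param inner_matrix square 0/1 matrix, LV names on both dimensions,
#'   lower-triangular in the LV order given: `inner_matrix[i, j] = 1` means
#'   LV j -> LV i.
#' @param scheme inner weighting scheme: `"centroid"` (default),
#'   `"factorial"` or `"path"`.
#' @param tol convergence tolerance on outer weights.
#' @param max_iter maximum number of alternating iterations.
#' @param prune iteratively drop indicators with |loading| < `loading_min`.
#' @param loading_min pruning threshold (default 0.7).
#' @return object of class `pls_path_model`: list with `blocks`, `weights`,
#'   `loadings` (data.frame), `scores` (n x LV matrix, unit variance),
#'   `paths` (data.frame: from, to, coefficient), `path_matrix`,
#'   `r_squared`, `communality`, `gof`, `inner_matrix`, `scheme`,
#'   `iterations`, `pruned` (dropped indicators), and the standardized
#'   `data` actually used.
#' @export
fit_plspm <- function(data, blocks, inner_matrix,
                      scheme = c("centroid", "factorial", "path"),
                      tol = 1e-6, max_iter = 100,
                      prune = TRUE, loading_min = 0.7) {
  scheme <- match.arg(scheme)
  check_plspm_spec(data, blocks, inner_matrix)
  pruned <- character(0)
  repeat {
    fit <- plspm_core(data, blocks, inner_matrix, scheme, tol, max_iter)
    if (!prune) break
    weak <- fit$loadings[abs(fit$loadings$loading) < loading_min, , drop = FALSE]
    if (nrow(weak) == 0) break
    for (b in unique(weak$block)) {
      drop_ind <- weak$indicator[weak$block == b]
      remaining <- setdiff(blocks[[b]], drop_ind)
      if (length(remaining) == 0) {
        stop_input(
          "pruning removed every indicator of block '", b,
          "' (all loadings < ", loading_min, ")"
        )
      }
      blocks[[b]] <- remaining
      pruned <- c(pruned, drop_ind)
    }
  }
  fit$pruned <- pruned
  fit
}

check_plspm_spec <- function(data, blocks, inner_matrix) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop_input("blocks must be a named list")
  }
  lv <- names(blocks)
  if (!is.matrix(inner_matrix) ||
      !identical(rownames(inner_matrix), lv) ||
      !identical(colnames(inner_matrix), lv)) {
    stop_input("inner_matrix must be square with dimnames equal to the block names")
  }
  if (any(inner_matrix[upper.tri(inner_matrix, diag = TRUE)] != 0)) {
    stop_input("inner_matrix must be lower-triangular (acyclic) in block order")
  }
  missing_ind <- setdiff(unlist(blocks), colnames(data))
  if (length(missing_ind) > 0) {
    stop_input("indicator(s) absent from data: ", paste(missing_ind, collapse = ", "))
  }
  if (any(lengths(blocks) == 0)) stop_input("every block needs >= 1 indicator")
  invisible(TRUE)
}

plspm_core <- function(data, blocks, inner_matrix, scheme, tol, max_iter) {
  lv <- names(blocks)
  X <- lapply(blocks, function(cols) {
    m <- scale(as.matrix(data[, cols, drop = FALSE]))
    if (any(!is.finite(m))) stop_input("constant or non-finite indicator in data")
    m
  })
  n <- nrow(X[[1]])
  neighbours <- (inner_matrix + t(inner_matrix)) > 0

  norm_w <- function(Xb, w) w / sd(as.vector(Xb %*% w))
  w <- lapply(X, function(Xb) norm_w(Xb, rep(1, ncol(Xb))))
  scores <- function(w) {
    Y <- vapply(lv, function(b) as.vector(X[[b]] %*% w[[b]]), numeric(n))
    scale(Y, scale = FALSE)
  }

  iter <- 0
  repeat {
    iter <- iter + 1
    Y <- scores(w)
    R <- cor(Y)
    Z <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
    for (b in seq_along(lv)) {
      nb <- which(neighbours[b, ])
      if (length(nb) == 0) stop_input("block '", lv[b], "' is structurally isolated")
      e <- switch(scheme,
        centroid = sign(R[b, nb]),
        factorial = R[b, nb],
        path = {
          pred <- which(inner_matrix[b, ] == 1)
          succ <- setdiff(nb, pred)
          ev <- numeric(length(nb))
          if (length(pred) > 0) {
            bcoef <- solve(R[pred, pred, drop = FALSE], R[pred, b])
            ev[match(pred, nb)] <- bcoef
          }
          ev[match(succ, nb)] <- R[b, succ]
          ev
        }
      )
      Z[, b] <- Y[, nb, drop = FALSE] %*% e
    }
    w_new <- lapply(seq_along(lv), function(b) {
      wb <- as.vector(crossprod(X[[lv[b]]], Z[, b])) / (n - 1)  # mode A
      wb <- norm_w(X[[lv[b]]], wb)
      # sign alignment: LV correlates positively with its first indicator
      if (sum(wb * cov(X[[lv[b]]])[, 1]) < 0) wb <- -wb
      wb
    })
    names(w_new) <- lv
    delta <- max(unlist(Map(function(a, b) max(abs(a - b)), w_new, w)))
    w <- w_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop_input(
        "PLS-PM did not converge in ", max_iter,
        " iterations (last max weight change ", signif(delta, 3), ")"
      )
    }
  }

  Y <- scores(w)
  loadings <- do.call(rbind, lapply(lv, function(b) {
    data.frame(
      block = b, indicator = blocks[[b]],
      loading = as.vector(cor(X[[b]], Y[, b])),
      stringsAsFactors = FALSE
    )
  }))
  rownames(loadings) <- NULL
  communality <- vapply(lv, function(b) {
    mean(loadings$loading[loadings$block == b]^2)
  }, 1)

  endo <- lv[rowSums(inner_matrix) > 0]
  path_matrix <- inner_matrix * 0
  r_squared <- setNames(rep(NA_real_, length(lv)), lv)
  paths <- data.frame(from = character(0), to = character(0), coefficient = numeric(0))
  Ys <- scale(Y)  # unit-variance LV scores for standardized coefficients
  for (b in endo) {
    pred <- lv[inner_matrix[b, ] == 1]
    fit <- lm(Ys[, b] ~ Ys[, pred, drop = FALSE] - 1)
    cf <- coef(fit)
    if (any(!is.finite(cf))) stop_input("singular inner regression for LV '", b, "'")
    path_matrix[b, pred] <- cf
    r_squared[b] <- sum(cf * cor(Ys[, pred, drop = FALSE], Ys[, b]))
    paths <- rbind(paths, data.frame(
      from = pred, to = b, coefficient = unname(cf), stringsAsFactors = FALSE
    ))
  }
  gof <- sqrt(mean(communality) * mean(r_squared[endo]))

  structure(
    list(
      blocks = blocks, weights = w, loadings = loadings,
      scores = Ys, paths = paths, path_matrix = path_matrix,
      r_squared = r_squared[endo], communality = communality, gof = gof,
      inner_matrix = inner_matrix, scheme = scheme, iterations = iter,
      data = data
    ),
    class = "pls_path_model"
  )
}

#' @export
print.pls_path_model <- function(x, ...) {
  cat("pls_path_model:", length(x$blocks), "blocks,", nrow(x$paths), "paths;",
      "GoF =", round(x$gof, 3), "\n")
  for (i in seq_len(nrow(x$paths))) {
    cat(sprintf("  %s -> %s: %.3f\n", x$paths$from[i], x$paths$to[i], x$paths$coefficient[i]))
  }
  invisible(x)
}

#' Bootstrap confidence intervals and p-values for path coefficients
#'
#' Case-resampling bootstrap of the fitted model (no pruning inside
#' resamples; the pruned block structure is kept fixed). Percentile
#' intervals at level `conf`; two-sided p by CI inversion,
#' p = 2 min(P(b* <= 0), P(b* >= 0)) with the add-one convention.
#' Resamples in which an indicator is constant are redrawn (counted,
#' capped).
#'
#' @param model a fitted [fit_plspm()] object.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level for the percentile intervals (default 0.90,
#'   matching a p < 0.1 display rule).
#' @return data.frame: `from`, `to`, `estimate`, `lower`, `upper`, `p`,
#'   plus attribute `n_redrawn`.
#' @export
bootstrap_paths <- function(model, n_boot = 999, seed = 1, conf = 0.90) {
  stopifnot(inherits(model, "pls_path_model"))
  data <- model$data
  n <- nrow(data)
  cols <- unlist(model$blocks)
  boot <- matrix(NA_real_, n_boot, nrow(model$paths))
  redrawn <- 0
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(100)) {
        idx <- sample.int(n, replace = TRUE)
        d <- data[idx, , drop = FALSE]
        if (all(apply(as.matrix(d[, cols, drop = FALSE]), 2, sd) > 0)) break
        redrawn <- redrawn + 1
        if (try == 100) stop_input("could not draw a non-degenerate bootstrap resample")
      }
      fit <- fit_plspm(
        d, model$blocks, model$inner_matrix, scheme = model$scheme,
        prune = FALSE
      )
      boot[b, ] <- fit$paths$coefficient
    }
  })
  a <- (1 - conf) / 2
  out <- model$paths
  out$estimate <- out$coefficient
  out$coefficient <- NULL
  out$lower <- apply(boot, 2, quantile, probs = a)
  out$upper <- apply(boot, 2, quantile, probs = 1 - a)
  out$p <- vapply(seq_len(ncol(boot)), function(j) {
    lo <- (1 + sum(boot[, j] <= 0)) / (1 + n_boot)
    hi <- (1 + sum(boot[, j] >= 0)) / (1 + n_boot)
    min(1, 2 * min(lo, hi))
  }, 1)
  attr(out, "n_redrawn") <- redrawn
  out
}
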