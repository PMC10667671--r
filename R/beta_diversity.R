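# Beta-diversity analytics: Bray-Curtis dissimilarity, NMDS ordination,
# ANOSIM, SIMPER decomposition, time-lag analysis and period-pair bins.

#' Bray-Curtis dissimilarity matrix
#'
#' d(j,k) = sum_t |y_tj - y_tk| / sum_t (y_tj + y_tk), computed on per-sample
#' relative abundances (tables are rarefied to even depth, so proportions and
#' counts give the same dissimilarities).
#'
#' @param table a [community_table()], or a non-negative numeric matrix with
#'   samples in rows.
#' @return a `dist` object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis <- function(table) {
  y <- if (inherits(table, "community_table")) relative_abundance(table) else as.matrix(table)
  if (any(y < 0)) stop_input("abundances must be non-negative")
  tot <- rowSums(y)
  if (any(tot == 0)) {
    stop_input("all-zero sample(s): ", paste(rownames(y)[tot == 0], collapse = ", "))
  }
  vegan::vegdist(y, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (via [vegan::metaMDS()] on the supplied
#' dissimilarities): best of `n_starts` random starts, axes centred and
#' principal-axis rotated, deterministic under `seed`.
#'
#' @param dm a `dist` of dissimilarities.
#' @param k number of ordination axes (default 2).
#' @param n_starts number of random starts.
#' @param seed integer seed.
#' @return list with `points` (samples x k coordinate matrix) and `stress`.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, seed = 1) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  if (n < k + 1) stop_input("need at least k + 1 samples")
  fit <- withr::with_seed(seed, suppressWarnings(vegan::metaMDS(
    dm, k = k, try = n_starts, trymax = n_starts, trace = 0,
    autotransform = FALSE, wascores = FALSE
  )))
  pts <- fit$points
  colnames(pts) <- paste0("NMDS", seq_len(k))
  list(points = pts, stress = fit$stress)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's R statistic on the ranked dissimilarities,
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4),
#' with mid-ranks for ties. The p-value permutes group labels; by default
#' `n_perm` random permutations with the add-one convention
#' p = (1 + #\{R* >= R\}) / (1 + n_perm). With `exact = TRUE` all distinct
#' label arrangements are enumerated (feasible for small n) and the p-value
#' is the exact proportion of arrangements with R* >= R.
#'
#' @param dm a `dist` of dissimilarities.
#' @param groups group label per sample.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exact enumerate all label permutations instead (n <= 10).
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = 1, exact = FALSE) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  groups <- factor(groups)
  if (length(groups) != n) stop_input("one group label per sample required")
  if (nlevels(groups) < 2) stop_input("need >= 2 groups")
  if (any(table(groups) < 2)) stop_input("every group needs >= 2 members")
  r <- rank(as.vector(dm))  # mid-ranks for ties
  denom <- n * (n - 1) / 4
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  R_obs <- stat(as.integer(groups))
  if (exact) {
    if (n > 10) stop_input("exact enumeration limited to n <= 10")
    perms <- all_permutations(n)
    Rs <- apply(perms, 1, function(p) stat(as.integer(groups)[p]))
    p <- mean(Rs >= R_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    Rs <- withr::with_seed(seed, replicate(n_perm, stat(as.integer(groups)[sample.int(n)])))
    p <- (1 + sum(Rs >= R_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(R = R_obs, p = p, n_perm = n_used)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For every pair of groups, decomposes the mean between-group Bray-Curtis
#' dissimilarity into additive per-taxon contributions
#' |y_tj - y_tk| / sum_t (y_tj + y_tk), averaged over all between-group
#' sample pairs, and expresses them as percentages of the mean dissimilarity.
#'
#' @param table a [community_table()] (or relative-abundance matrix).
#' @param groups group label per sample.
#' @return named list, one data.frame per group pair with columns `taxon_id`,
#'   `average` (mean per-pair contribution), `contribution_pct` and
#'   `cumulative_pct`, sorted by decreasing contribution. Each element
#'   carries the mean between-group dissimilarity as attribute
#'   `mean_dissimilarity`.
#' @export
simper_contributions <- function(table, groups) {
  y <- if (inherits(table, "community_table")) relative_abundance(table) else as.matrix(table)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_input("need >= 2 groups")
  tot <- rowSums(y)
  if (any(tot == 0)) stop_input("all-zero sample(s) present")
  out <- list()
  lv <- levels(groups)
  for (a in seq_len(length(lv) - 1)) {
    for (b in seq(a + 1, length(lv))) {
      ia <- which(groups == lv[a])
      ib <- which(groups == lv[b])
      contrib <- numeric(ncol(y))
      for (j in ia) {
        for (k in ib) {
          contrib <- contrib + abs(y[j, ] - y[k, ]) / (tot[j] + tot[k])
        }
      }
      contrib <- contrib / (length(ia) * length(ib))
      mean_d <- sum(contrib)
      df <- data.frame(
        taxon_id = colnames(y),
        average = contrib,
        contribution_pct = 100 * contrib / mean_d,
        stringsAsFactors = FALSE
      )
      df <- df[order(-df$average), ]
      df$cumulative_pct <- cumsum(df$contribution_pct)
      rownames(df) <- NULL
      attr(df, "mean_dissimilarity") <- mean_d
      out[[paste(lv[a], lv[b], sep = "_vs_")]] <- df
    }
  }
  out
}

#' Time-lag analysis of community dissimilarity
#'
#' Plots-ready table of time difference (in months of 30.44 days) against
#' dissimilarity for every unordered sample pair, with an OLS trend.
#'
#' @param dm a `dist` of dissimilarities.
#' @param dates `Date` vector aligned to the samples.
#' @return list with `pairs` (data.frame: lag_months, dissimilarity),
#'   `slope`, `intercept`, `p` (slope t-test).
#' @export
time_lag <- function(dm, dates) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  dates <- as.Date(dates)
  if (length(dates) != n) stop_input("one date per sample required")
  idx <- combn(n, 2)
  lag <- abs(as.numeric(dates[idx[2, ]] - dates[idx[1, ]])) / 30.44
  d <- as.vector(dm)
  fit <- lm(d ~ lag)
  sm <- summary(fit)
  list(
    pairs = data.frame(lag_months = lag, dissimilarity = d),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  )
}

#' Dissimilarities binned by period pair
#'
#' Assigns every unordered sample pair to one of the six period bins
#' (B-B, B-M, B-A, M-M, M-A, A-A) and compares the bins with
#' [compare_groups_kw()].
#'
#' @param dm a `dist` of dissimilarities.
#' @param periods period label per sample (`before`/`mixing`/`after`).
#' @return list with `pairs` (data.frame: bin, dissimilarity), `bin_sizes`
#'   and `kw` (the Kruskal-Wallis + letters result).
#' @export
period_pair_dissimilarity <- function(dm, periods) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  periods <- as_period(periods)
  if (length(periods) != n) stop_input("one period label per sample required")
  if (nlevels(droplevels(periods)) < 3) stop_input("all three periods must be present")
  key <- c(before = "B", mixing = "M", after = "A")
  idx <- combn(n, 2)
  lab <- apply(idx, 2, function(jk) {
    pr <- sort(factor(key[as.character(periods[jk])], levels = c("B", "M", "A")))
    paste(pr, collapse = "-")
  })
  bins <- c("B-B", "B-M", "B-A", "M-M", "M-A", "A-A")
  pairs <- data.frame(
    bin = factor(lab, levels = bins),
    dissimilarity = as.vector(dm)
  )
  list(
    pairs = pairs,
    bin_sizes = table(pairs$bin),
    kw = compare_groups_kw(pairs$dissimilarity, pairs$bin)
  )
}
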