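# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive quantities from first principles,
# separately from the package implementation.

# Random community table: n samples x p taxa of Poisson counts.
random_table <- function(n = 10, p = 6, lambda = 20, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * p, lambda), n, p)
    m[m < 0] <- 0
    if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(p)))
    community_table(m)
  })
}

# Brute-force Bray-Curtis between two vectors.
bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Benjamini-Hochberg step-up from the definition: find the largest k with
# p_(k) <= k/m * alpha is the rejection rule; the adjusted value is
# min over j >= k of (m/j) p_(j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(pmin(sorted, 1))))
  adj
}

# Exact Kruskal-Wallis permutation p: all distinct assignments of the values
# to groups of the given sizes, P(H >= H_obs). H computed directly from the
# joint ranks; the tie-correction factor depends only on the value multiset,
# so it cancels and is omitted.
kw_exact_p <- function(values, labels) {
  labels <- factor(labels)
  sizes <- table(labels)
  r <- rank(values)
  n <- length(values)
  h_of <- function(groups) {  # groups: list of index vectors
    12 / (n * (n + 1)) *
      sum(vapply(groups, function(ix) length(ix) * mean(r[ix])^2, 1)) -
      3 * (n + 1)
  }
  h_obs <- h_of(split(seq_len(n), labels))
  assignments <- list()
  recurse <- function(remaining, acc) {
    if (length(acc) == length(sizes) - 1) {
      assignments[[length(assignments) + 1]] <<- c(acc, list(remaining))
      return(invisible())
    }
    g <- length(acc) + 1
    picks <- combn(remaining, sizes[g], simplify = FALSE)
    for (p in picks) recurse(setdiff(remaining, p), c(acc, list(p)))
  }
  recurse(seq_len(n), list())
  hs <- vapply(assignments, h_of, 1)
  mean(hs >= h_obs - 1e-12)
}

coresat_all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- coresat_all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# Exhaustive maximum-modularity partition search over all set partitions of
# the vertices of a small igraph graph; returns the maximal modularity.
max_modularity_exhaustive <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 7)
  parts <- set_partitions(n)
  max(vapply(parts, function(m) igraph::modularity(graph, m), 1))
}

# All set partitions of n elements as membership vectors (restricted growth
# strings).
set_partitions <- function(n) {
  out <- list()
  grow <- function(member) {
    if (length(member) == n) {
      out[[length(out) + 1]] <<- member
      return(invisible())
    }
    k <- if (length(member) == 0) 0 else max(member)
    for (g in seq_len(k + 1)) grow(c(member, g))
  }
  grow(integer(0))
  out
}

# ANOSIM R from the raw definition (no shared code with the package).
anosim_R_oracle <- function(dm, groups) {
  m <- as.matrix(dm)
  n <- nrow(m)
  v <- m[lower.tri(m)]
  r <- rank(v)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  within <- groups[idx[, 1]] == groups[idx[, 2]]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# Composite-model data generator for path-model recovery tests: three
# blocks of three indicators whose composites carry all between-block
# covariance. cor(indicator, composite) = loadings; composite correlations
# follow the chain paths. PLS-PM (mode A) is consistent for exactly this
# data-generating model, so recovery can be asserted tightly.
sim_chain_composite <- function(n, paths = c(0.5, 0.3),
                                loadings = c(0.9, 0.8, 0.85), seed = 1) {
  lam <- loadings
  mu <- sum(lam^2)
  M <- rbind(c(lam[2], lam[3], 0),
             c(lam[1], 0, lam[3]),
             c(0, lam[1], lam[2]))
  a <- solve(M, (mu - 1) * lam)
  Sb <- diag(3)
  Sb[1, 2] <- Sb[2, 1] <- a[1]
  Sb[1, 3] <- Sb[3, 1] <- a[2]
  Sb[2, 3] <- Sb[3, 2] <- a[3]
  S <- matrix(0, 9, 9)
  for (b in 1:3) S[(3 * b - 2):(3 * b), (3 * b - 2):(3 * b)] <- Sb
  cross <- function(rr) rr * outer(lam, lam)
  S[1:3, 4:6] <- cross(paths[1]); S[4:6, 1:3] <- t(S[1:3, 4:6])
  S[4:6, 7:9] <- cross(paths[2]); S[7:9, 4:6] <- t(S[4:6, 7:9])
  S[1:3, 7:9] <- cross(paths[1] * paths[2]); S[7:9, 1:3] <- t(S[1:3, 7:9])
  L <- chol(S)
  d <- withr::with_seed(seed, as.data.frame(matrix(rnorm(n * 9), n, 9) %*% L))
  colnames(d) <- paste0("x", rep(1:3, each = 3), "_", rep(1:3, 3))
  d
}

chain_blocks3 <- list(LV1 = paste0("x1_", 1:3), LV2 = paste0("x2_", 1:3),
                      LV3 = paste0("x3_", 1:3))

chain_inner3 <- function() {
  lv <- names(chain_blocks3)
  m <- matrix(0, 3, 3, dimnames = list(lv, lv))
  m[2, 1] <- 1
  m[3, 2] <- 1
  m
}
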