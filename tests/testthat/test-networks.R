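test_that("node filter requires period sharing and the abundance floor", {
  n <- 12
  periods <- rep(c("before", "mixing", "after"), each = 4)
  total <- 10000
  m <- matrix(0, n, 4)
  m[, 1] <- 100                      # shared, abundant
  m[periods != "mixing", 2] <- 100   # absent in mixing -> excluded
  m[, 3] <- c(rep(4, 6), rep(6, 6))  # shared, mean rel = 0.0005 -> included
  m[, 4] <- c(rep(3, 6), rep(5, 6))  # shared, mean rel = 0.0004 -> excluded
  m[, 1] <- m[, 1] + (total - rowSums(m))  # pad sums to 10000
  dimnames(m) <- list(paste0("s", 1:n), paste0("t", 1:4))
  tab <- community_table(m)
  keep <- network_node_filter(tab, periods)
  expect_true(all(c("t1", "t3") %in% keep))
  expect_false("t2" %in% keep)
  expect_false("t4" %in% keep)
  # brute-force equivalence on random tables
  withr::with_seed(7, {
    for (i in 1:10) {
      y <- matrix(rpois(12 * 20, 3), 12, 20)
      y[, 1] <- y[, 1] + 5  # keep samples non-empty
      dimnames(y) <- list(paste0("s", 1:12), paste0("t", 1:20))
      tabr <- community_table(y)
      keep <- suppressWarnings(network_node_filter(tabr, periods, 0.01))
      rel <- y / rowSums(y)
      brute <- colnames(y)[
        sapply(colnames(y), function(t) {
          all(tapply(y[, t] > 0, periods, any)) && mean(rel[, t]) >= 0.01
        })
      ]
      expect_setequal(keep, brute)
    }
  })
})

test_that("network edges require strong rank correlation at FDR control", {
  withr::with_seed(11, {
    n <- 10
    base <- round(sort(rlnorm(n, 3, 1)) * 10)
    m <- cbind(
      t1 = base, t2 = base + 1,            # same ranks as t1
      t3 = round(rlnorm(n, 3, 1) * 10), t4 = round(rlnorm(n, 3, 1) * 10),
      t5 = rep(5, n)                       # constant taxon
    )
    # filler pads every sample to the same total, so relative abundances
    # keep the engineered rank structure
    m <- cbind(m, filler = max(rowSums(m)) + 50 - rowSums(m))
    rownames(m) <- paste0("s", 1:n)
    tab <- community_table(m)
    expect_warning(net <- build_network(tab), "constant")
    e <- net$edges
    expect_true(any(e$node1 == "t1" & e$node2 == "t2"))
    expect_equal(e$rho[e$node1 == "t1" & e$node2 == "t2"], 1)
    expect_equal(igraph::vcount(net$graph), 6)  # constant node retained
    expect_equal(sum(e$node1 == "t5" | e$node2 == "t5"), 0)
  })
  expect_error(build_network(random_table(n = 4)), ">= 5 samples")
})

test_that("FDR control keeps independent taxa nearly edge-free", {
  false_edges <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      m <- matrix(rlnorm(34 * 30, 3, 0.5), 34, 30)
      dimnames(m) <- list(paste0("s", 1:34), paste0("t", 1:30))
      igraph::ecount(build_network(community_table(round(m * 10) + 1))$graph)
    })
  }, 1)
  expect_lte(mean(false_edges), 0.05)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  withr::with_seed(13, {
    p <- runif(20)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    p2 <- round(runif(20), 2)  # with ties
    expect_equal(p.adjust(p2, "BH"), bh_oracle(p2), tolerance = 1e-12)
  })
})

test_that("induced subnetworks equal brute-force construction", {
  withr::with_seed(17, {
    n <- 12
    f <- rlnorm(n)
    m <- vapply(1:8, function(j) round(100 * f * rlnorm(n, 0, 0.05)) + 1, numeric(n))
    dimnames(m) <- list(paste0("s", 1:n), paste0("t", 1:8))
    tab <- community_table(m)
    net <- build_network(tab, rho_min = 0.5, fdr_max = 0.2)
    # whole-sample subnetwork is the whole network
    full <- sample_subnetwork(net, setNames(rep(1, 8), paste0("t", 1:8)))
    expect_equal(igraph::ecount(full), igraph::ecount(net$graph))
    # empty sample -> empty graph
    empty <- sample_subnetwork(net, setNames(rep(0, 8), paste0("t", 1:8)))
    expect_equal(igraph::vcount(empty), 0)
    # random masks match brute-force edge filtering
    for (i in 1:10) {
      mask <- setNames(rbinom(8, 1, 0.6), paste0("t", 1:8))
      sg <- sample_subnetwork(net, mask)
      present <- names(mask)[mask > 0]
      brute <- net$edges[net$edges$node1 %in% present & net$edges$node2 %in% present, ]
      expect_equal(igraph::ecount(sg), nrow(brute))
      expect_setequal(igraph::V(sg)$name, intersect(igraph::V(net$graph)$name, present))
    }
  })
})

test_that("topological metrics match closed forms on canonical graphs", {
  star <- igraph::make_star(5, mode = "undirected")  # K1,4
  ms <- topological_metrics(star)
  expect_equal(ms$density, 0.4)
  expect_equal(ms$avg_path_length, 1.6)
  expect_equal(ms$betweenness_centralization, 1.0)
  k5 <- igraph::make_full_graph(5)
  mk <- topological_metrics(k5)
  expect_equal(mk$density, 1)
  expect_equal(mk$avg_path_length, 1)
  expect_equal(mk$betweenness_centralization, 0)
  expect_equal(mk$modularity, 0)
  # degenerate sizes
  expect_true(is.na(topological_metrics(igraph::make_empty_graph(1, directed = FALSE))$density))
  expect_true(is.na(topological_metrics(igraph::make_full_graph(2))$betweenness_centralization))
})

test_that("greedy modularity attains the exhaustive optimum on small graphs", {
  two_triangles <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE
  )
  graphs <- list(
    two_triangles = two_triangles,
    k5 = igraph::make_full_graph(5),
    star = igraph::make_star(5, mode = "undirected"),
    path4 = igraph::make_ring(4, circular = FALSE),
    ring6 = igraph::make_ring(6)
  )
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    expect_equal(
      topological_metrics(g)$modularity,
      max_modularity_exhaustive(g),
      tolerance = 1e-12
    )
  }
  expect_equal(topological_metrics(two_triangles)$modularity, 0.5)
})

test_that("metrics and edges are invariant to taxon order and monotone transforms", {
  withr::with_seed(19, {
    n <- 12
    f <- rlnorm(n)
    m <- vapply(1:6, function(j) round(100 * f * rlnorm(n, 0, 0.1)) + 1, numeric(n))
    dimnames(m) <- list(paste0("s", 1:n), paste0("t", 1:6))
    net <- build_network(community_table(m), rho_min = 0.5, fdr_max = 0.2)
    # taxon permutation
    perm <- sample(1:6)
    net2 <- build_network(community_table(m[, perm]), rho_min = 0.5, fdr_max = 0.2)
    key <- function(e) sort(paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2)))
    expect_equal(key(net$edges), key(net2$edges))
    # strictly monotone transform of abundances preserves Spearman edges
    net3 <- build_network(community_table(m^2), rho_min = 0.5, fdr_max = 0.2)
    expect_equal(key(net$edges), key(net3$edges))
  })
})

test_that("period comparison of metrics flags disturbance-driven differences", {
  # before and after share the exact same values, so their mean ranks tie
  metrics <- data.frame(
    sample_id = paste0("s", 1:12),
    density = c(0.2, 0.21, 0.22, 0.23, 0.8, 0.81, 0.82, 0.83, 0.2, 0.21, 0.22, 0.23)
  )
  periods <- rep(c("before", "mixing", "after"), each = 4)
  res <- compare_metrics_by_period(metrics, periods)
  expect_lt(res$density$p, 0.05)
  lt <- res$density$letters
  expect_false(lt[["before"]] == lt[["mixing"]])
  expect_equal(lt[["before"]], lt[["after"]])
})
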