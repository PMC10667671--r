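# Thresholded Spearman co-occurrence networks, per-sample induced
# subnetworks and their topological properties.

#' Select taxa eligible for network construction
#'
#' Keeps taxa that occur (count > 0) in at least one sample of every period
#' and whose mean relative abundance over all samples is at least
#' `min_rel_abund` (default 0.05%).
#'
#' @param table a [community_table()].
#' @param periods period label per sample.
#' @param min_rel_abund inclusive mean relative-abundance threshold.
#' @return character vector of retained taxon ids.
#' @export
network_node_filter <- function(table, periods, min_rel_abund = 0.0005) {
  stopifnot(inherits(table, "community_table"))
  periods <- as_period(periods)
  if (nlevels(droplevels(periods)) < 3) stop_input("all three periods must be present")
  rel <- relative_abundance(table)
  shared <- Reduce(`&`, lapply(period_levels(), function(p) {
    colSums(table$counts[periods == p, , drop = FALSE] > 0) > 0
  }))
  keep <- shared & colMeans(rel) >= min_rel_abund
  if (!any(keep)) warning("no taxa pass the network node filter", call. = FALSE)
  colnames(table$counts)[keep]
}

# Spearman correlation p-values: t approximation (default) or exact
# enumeration of rank permutations for very small n.
spearman_p <- function(rho, n, method = c("t", "exact"), x = NULL, y = NULL) {
  method <- match.arg(method)
  if (method == "t") {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(-abs(tstat), df = n - 2))
  }
  if (n > 8) stop_input("exact Spearman p limited to n <= 8")
  perms <- all_permutations(n)
  ry <- rank(y)
  rx <- rank(x)
  obs <- abs(cor(rx, ry))
  stats <- abs(apply(perms, 1, function(p) cor(rx, ry[p])))
  mean(stats >= obs - 1e-12)
}

#' Build a thresholded Spearman co-occurrence network
#'
#' All-pairs Spearman correlations (mid-ranks for ties) of the supplied
#' taxa's abundances across samples (rank-based, so counts of a table
#' rarefied to even depth and relative abundances are equivalent);
#' two-sided p-values from
#' the t approximation (or exact rank-permutation enumeration for n <= 8),
#' Benjamini-Hochberg corrected across all pairs. A pair becomes an edge iff
#' |rho| >= `rho_min` and adjusted p < `fdr_max`.
#'
#' @param table a [community_table()] restricted (or restrictable via
#'   `taxa`) to the eligible node set.
#' @param taxa optional character vector of taxon ids to use.
#' @param rho_min correlation magnitude threshold (default 0.8).
#' @param fdr_max adjusted-p threshold (default 0.01).
#' @param p_method `"t"` or `"exact"`.
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph, all eligible taxa as vertices), `edges` (data.frame: node1,
#'   node2, rho, p, p_adj) and `params`.
#' @export
build_network <- function(table, taxa = NULL, rho_min = 0.8, fdr_max = 0.01,
                          p_method = c("t", "exact")) {
  stopifnot(inherits(table, "community_table"))
  p_method <- match.arg(p_method)
  if (!is.null(taxa)) table <- subset_community(table, taxa = taxa)
  n <- nrow(table$counts)
  if (n < 5) stop_input("need >= 5 samples to estimate correlations")
  # Spearman is rank-based per taxon, so on a table rarefied to even depth
  # counts and relative abundances give identical correlations; counts are
  # used directly, which also keeps samples with no reads in the taxon
  # subset well-defined.
  rel <- table$counts
  p_taxa <- ncol(rel)
  const <- apply(rel, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    warning(
      "constant taxa retained without edges: ",
      paste(colnames(rel)[const], collapse = ", "),
      call. = FALSE
    )
  }
  rho <- suppressWarnings(cor(rel, method = "spearman"))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(
    node1 = colnames(rel)[idx[, 1]],
    node2 = colnames(rel)[idx[, 2]],
    rho = rho[idx],
    stringsAsFactors = FALSE
  )
  ok <- is.finite(edges$rho)
  edges$p <- NA_real_
  edges$p[ok] <- vapply(which(ok), function(e) {
    spearman_p(edges$rho[e], n, p_method,
      x = rel[, idx[e, 1]], y = rel[, idx[e, 2]]
    )
  }, 1)
  edges$p_adj <- NA_real_
  edges$p_adj[ok] <- p.adjust(edges$p[ok], method = "BH")
  keep <- ok & abs(edges$rho) >= rho_min & edges$p_adj < fdr_max
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("node1", "node2")],
    directed = FALSE,
    vertices = data.frame(name = colnames(rel))
  )
  igraph::E(g)$rho <- edges$rho
  structure(
    list(
      graph = g, edges = edges,
      params = list(
        rho_min = rho_min, fdr_max = fdr_max, n_samples = n,
        p_method = p_method, n_taxa = p_taxa
      )
    ),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(
    "cooccurrence_network:", igraph::vcount(x$graph), "nodes,",
    igraph::ecount(x$graph), "edges (|rho| >=", x$params$rho_min,
    ", FDR p <", x$params$fdr_max, ")\n"
  )
  invisible(x)
}

#' Induced subnetwork for one sample
#'
#' Induces the subgraph of the whole network on the taxa present (count > 0)
#' in one sample; every edge whose endpoints are both present is retained.
#'
#' @param net a [build_network()] result.
#' @param sample_counts named numeric vector of that sample's counts (names =
#'   taxon ids), or logical presence vector over the network's vertices.
#' @return igraph graph.
#' @export
sample_subnetwork <- function(net, sample_counts) {
  stopifnot(inherits(net, "cooccurrence_network"))
  vn <- igraph::V(net$graph)$name
  if (is.logical(sample_counts)) {
    present <- vn[sample_counts[seq_along(vn)]]
  } else {
    if (is.null(names(sample_counts))) stop_input("sample counts must be named by taxon")
    present <- vn[vn %in% names(sample_counts)[sample_counts > 0]]
  }
  igraph::induced_subgraph(net$graph, present)
}

#' Topological properties of a simple undirected graph
#'
#' Node and edge counts; average path length over connected vertex pairs
#' only; Freeman betweenness centralization
#' sum_i (b_max - b_i) / ((N-1)^2 (N-2) / 2) on raw betweenness; density
#' 2E / (N(N-1)); and the modularity of the partition found by deterministic
#' greedy modularity maximisation (unweighted). Undefined metrics (e.g.
#' centralization for N < 3, density for N < 2, modularity without edges)
#' are returned as `NA`.
#'
#' @param graph an igraph graph (undirected, simple).
#' @return one-row data.frame: `nodes`, `edges`, `avg_path_length`,
#'   `betweenness_centralization`, `density`, `modularity`.
#' @export
topological_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  apl <- if (n >= 2 && e >= 1) {
    igraph::mean_distance(graph, directed = FALSE, unconnected = TRUE)
  } else {
    NA_real_
  }
  dens <- if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_
  centr <- if (n >= 3) {
    b <- igraph::betweenness(graph, directed = FALSE)
    sum(max(b) - b) / ((n - 1)^2 * (n - 2) / 2)
  } else {
    NA_real_
  }
  mod <- if (e >= 1) {
    igraph::modularity(graph, greedy_modularity(graph))
  } else {
    NA_real_
  }
  data.frame(
    nodes = n, edges = e, avg_path_length = apl,
    betweenness_centralization = centr, density = dens, modularity = mod
  )
}

#' Deterministic greedy modularity maximisation
#'
#' Clauset-Newman-Moore style agglomeration: starting from singleton
#' communities, repeatedly merge the pair of connected communities with the
#' largest modularity gain (ties broken lexicographically by the smallest
#' vertex contained in each community), and return the partition with the
#' highest modularity seen anywhere along the merge sequence. Unweighted;
#' fully deterministic, so repeated runs give identical partitions.
#'
#' @param graph an undirected igraph graph with at least one edge.
#' @return integer membership vector named by vertex.
#' @export
greedy_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (m < 1) stop_input("graph has no edges")
  vn <- igraph::V(graph)$name
  if (is.null(vn)) vn <- as.character(seq_len(n))
  ord <- order(vn)  # lexicographic vertex order for deterministic ties
  comm <- as.list(ord)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)[ord, ord, drop = FALSE]
  B <- adj                      # B[i, j], i != j: edges between communities
  diag(B) <- diag(adj) / 2      # diag: edges within (0 for simple graphs)
  d <- rowSums(adj) + diag(adj) # community degree sums
  q_of <- function(B, d) sum(diag(B)) / m - sum((d / (2 * m))^2)
  best_q <- q_of(B, d)
  best_comm <- comm
  while (length(comm) > 1) {
    k <- length(comm)
    best_gain <- -Inf; bi <- bj <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (B[i, j] == 0) next  # only merge connected communities
        gain <- B[i, j] / m - d[i] * d[j] / (2 * m^2)
        if (gain > best_gain + 1e-15) {
          best_gain <- gain; bi <- i; bj <- j
        }
      }
    }
    if (bi == 0) break  # disconnected at community level: stop merging
    B[bi, bi] <- B[bi, bi] + B[bj, bj] + B[bi, bj]
    keep <- setdiff(seq_len(k), c(bi, bj))
    B[bi, keep] <- B[bi, keep] + B[bj, keep]
    B[keep, bi] <- B[bi, keep]
    d[bi] <- d[bi] + d[bj]
    B <- B[-bj, -bj, drop = FALSE]
    d <- d[-bj]
    comm[[bi]] <- sort(c(comm[[bi]], comm[[bj]]))
    comm[[bj]] <- NULL
    q <- q_of(B, d)
    if (q > best_q + 1e-15) {
      best_q <- q
      best_comm <- comm
    }
  }
  membership <- integer(n)
  for (ci in seq_along(best_comm)) membership[best_comm[[ci]]] <- ci
  names(membership) <- vn
  membership
}

#' Per-sample subnetwork metrics for a whole table
#'
#' @param net a [build_network()] result.
#' @param table the [community_table()] the network was built from (samples
#'   define the subnetworks).
#' @return data.frame with one row per sample (`sample_id` + the
#'   [topological_metrics()] columns).
#' @export
subnetwork_metrics <- function(net, table) {
  stopifnot(inherits(table, "community_table"))
  out <- do.call(rbind, lapply(rownames(table$counts), function(s) {
    g <- sample_subnetwork(net, table$counts[s, ])
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE), topological_metrics(g))
  }))
  rownames(out) <- NULL
  out
}

#' Compare topological metrics across periods
#'
#' One Kruskal-Wallis + compact-letter result per metric column, with `NA`
#' metric values excluded pairwise.
#'
#' @param metrics output of [subnetwork_metrics()].
#' @param periods period label per sample (aligned to `metrics$sample_id`).
#' @return named list of [compare_groups_kw()] results.
#' @export
compare_metrics_by_period <- function(metrics, periods) {
  periods <- as_period(periods)
  cols <- setdiff(names(metrics), "sample_id")
  out <- lapply(cols, function(cl) {
    ok <- is.finite(metrics[[cl]])
    if (sum(ok) < 4 || nlevels(droplevels(periods[ok])) < 2) return(NULL)
    compare_groups_kw(metrics[[cl]][ok], periods[ok])
  })
  setNames(out, cols)
}
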