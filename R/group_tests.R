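# Kruskal-Wallis comparison across disturbance periods with a compact
# letter display, the workhorse behind every "different lowercase letters"
# style panel in the pipeline.

#' Kruskal-Wallis comparison with post-hoc letters
#'
#' Global tie-corrected Kruskal-Wallis H test, followed by Conover-Iman
#' rank-based pairwise t comparisons with Benjamini-Hochberg correction and
#' an insert-and-absorb compact letter display: groups sharing a letter are
#' not significantly different at `alpha`.
#'
#' @param values numeric vector of observations.
#' @param labels group label per observation (coerced to factor).
#' @param alpha significance level for the letter display.
#' @return list with `H`, `p`, `letters` (named character vector, one entry
#'   per group in label-level order), `pairwise` (data.frame of adjusted
#'   pairwise p-values) and `group_medians`.
#' @export
compare_groups_kw <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]
  labels <- droplevels(labels[ok])
  g <- levels(labels)
  k <- length(g)
  if (k < 2 || any(table(labels) < 2)) {
    stop_input("need >= 2 groups with >= 2 members each")
  }
  n <- length(values)

  if (length(unique(values)) == 1) {
    # Constant input: no evidence of any difference, by convention.
    return(list(
      H = 0, p = 1,
      letters = setNames(rep("a", k), g),
      pairwise = pairwise_frame(g, rep(1, k * (k - 1) / 2)),
      group_medians = tapply(values, labels, median)
    ))
  }

  kw <- kruskal.test(values, labels)
  H <- unname(kw$statistic)

  # Conover-Iman pairwise comparisons on the joint ranks.
  r <- rank(values)
  mean_r <- tapply(r, labels, mean)
  n_g <- tabulate(labels)
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)  # rank variance, tie-safe
  scale2 <- s2 * (n - 1 - H) / (n - k)
  pairs <- combn(k, 2)
  praw <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- scale2 * (1 / n_g[i] + 1 / n_g[j])
    if (se2 <= 0) return(1)  # degenerate: ranks fully explained
    tstat <- (mean_r[i] - mean_r[j]) / sqrt(se2)
    2 * pt(-abs(tstat), df = n - k)
  })
  padj <- p.adjust(praw, method = "BH")
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    sig[i, j] <- sig[j, i] <- padj[c] < alpha
  }
  list(
    H = H, p = unname(kw$p.value),
    letters = letter_display(sig, order(-unname(mean_r))),
    pairwise = pairwise_frame(g, padj),
    group_medians = tapply(values, labels, median)
  )
}

pairwise_frame <- function(groups, padj) {
  pr <- combn(groups, 2)
  data.frame(
    group1 = pr[1, ], group2 = pr[2, ], p_adj = as.numeric(padj),
    stringsAsFactors = FALSE
  )
}

# Insert-and-absorb compact letter display (Piepho-style). `sig` is a
# symmetric logical matrix of significant pairs; `pref_order` orders groups
# (e.g. by decreasing mean rank) for stable letter assignment.
letter_display <- function(sig, pref_order = seq_len(nrow(sig))) {
  k <- nrow(sig)
  g <- rownames(sig)
  cols <- list(rep(TRUE, k))  # start: one column containing every group
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          new_cols <- c(new_cols, list(a, b))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[b] &&
              all(new_cols[[b]] | !new_cols[[a]]) &&
              !identical(new_cols[[a]], new_cols[[b]])) {
            keep[a] <- FALSE
            break
          }
        }
      }
      # drop exact duplicates
      cols <- unique(new_cols[keep])
    }
  }
  # order columns so letters read in preference order
  first_member <- vapply(cols, function(col) min(match(which(col), pref_order)), 1)
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  setNames(out, g)
}
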