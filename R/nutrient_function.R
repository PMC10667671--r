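# Multi-nutrient cycling index and the collinearity pre-filter used before
# path modelling.

#' Multi-nutrient cycling (MNC) index
#'
#' Each nutrient is log(x + 1)-transformed, Z-scored over samples, and the
#' standardized variables are averaged per sample. With the canonical eight
#' constituents (TC, TOC, TN, NH4+, NO3-, NO2-, TP, PO43-) the index is a
#' dimensionless per-sample proxy for multi-nutrient cycling, centred at 0.
#'
#' @param nutrients data.frame or matrix of non-negative nutrient
#'   concentrations, samples in rows, one column per nutrient.
#' @return numeric vector of MNC values (named by row names when present),
#'   with the standardized matrix attached as attribute `z`.
#' @export
mnc_index <- function(nutrients) {
  x <- as.matrix(nutrients)
  if (!is.numeric(x)) stop_input("nutrients must be numeric")
  if (any(!is.finite(x))) stop_input("nutrients must be finite")
  if (any(x < 0)) stop_input("nutrients must be non-negative")
  lx <- log(x + 1)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0)) {
    stop_input(
      "zero-variance nutrient(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    )
  }
  z <- scale(lx)
  mnc <- rowMeans(z)
  attr(mnc, "z") <- z
  mnc
}

#' Greedy collinearity filter on squared Spearman correlations
#'
#' Scans variables in input order; whenever a later variable has a squared
#' Spearman correlation >= `threshold_sq_rho` with an already retained one,
#' the later variable is dropped. Deterministic by construction. The
#' conventional thresholds are 0.5 for environmental variables and 0.6 for
#' network topological properties.
#'
#' @param variables data.frame or matrix, samples in rows.
#' @param threshold_sq_rho squared-correlation cutoff.
#' @return character vector of retained column names.
#' @export
collinearity_filter <- function(variables, threshold_sq_rho = 0.5) {
  x <- as.matrix(variables)
  if (ncol(x) < 2) stop_input("need >= 2 variables")
  rho2 <- suppressWarnings(cor(x, method = "spearman"))^2
  kept <- 1L
  for (j in seq(2, ncol(x))) {
    r2 <- rho2[kept, j]
    if (all(is.na(r2)) || all(r2 < threshold_sq_rho, na.rm = TRUE)) {
      kept <- c(kept, j)
    }
  }
  colnames(x)[kept]
}
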