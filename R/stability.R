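# Moving-window community stability: inverse coefficient of variation of
# group-summed absolute abundance, window grouping around the disturbance,
# and subcommunity-vs-entire stability relationships.

#' Overlapping moving windows over a time series
#'
#' @param n_samples number of chronologically ordered samples.
#' @param w window length (default 5 samples).
#' @return data.frame with `window_index` (1-based), `start`, `end`; window
#'   i covers samples i..i+w-1, giving n - w + 1 windows.
#' @examples
#' nrow(moving_windows(34, 5))  # 30
#' @export
moving_windows <- function(n_samples, w = 5) {
  if (w < 2) stop_input("window length must be >= 2")
  if (n_samples < w) stop_input("need at least w samples")
  i <- seq_len(n_samples - w + 1)
  data.frame(window_index = i, start = i, end = i + w - 1)
}

#' Windowed 1/CV stability of an abundance series
#'
#' Stability of each window is mean/SD (SD with the n-1 denominator) of the
#' absolute abundances in the window: the inverse coefficient of variation.
#' A constant window (SD = 0) is reported as `Inf`.
#'
#' @param abundance_series positive numeric vector, chronological order.
#' @param windows output of [moving_windows()] for `length(abundance_series)`.
#' @return data.frame: `window_index`, `stability`.
#' @export
window_stability <- function(abundance_series, windows) {
  if (any(!is.finite(abundance_series)) || any(abundance_series <= 0)) {
    stop_input("abundances must be positive and finite")
  }
  stab <- vapply(seq_len(nrow(windows)), function(i) {
    x <- abundance_series[windows$start[i]:windows$end[i]]
    s <- sd(x)
    if (s == 0) Inf else mean(x) / s
  }, 1)
  data.frame(window_index = windows$window_index, stability = stab)
}

#' Assign disturbance groups to moving windows
#'
#' Group 1: windows containing only before-mixing samples. Group 2: windows
#' containing at least one complete-mixing sample. Group 3: windows
#' containing only after-mixing samples. In the 14/11/9 design with w = 5
#' this yields groups of 10, 15 and 5 windows, the mixing-containing windows
#' being 11 through 25.
#'
#' @param windows output of [moving_windows()].
#' @param periods period label per sample.
#' @return factor (`group1`/`group2`/`group3`), one entry per window.
#' @export
assign_window_groups <- function(windows, periods) {
  periods <- as_period(periods)
  grp <- vapply(seq_len(nrow(windows)), function(i) {
    p <- periods[windows$start[i]:windows$end[i]]
    if (any(p == "mixing")) return("group2")
    if (all(p == "before")) return("group1")
    if (all(p == "after")) return("group3")
    stop_input(
      "window ", windows$window_index[i],
      " mixes before and after samples without a mixing sample; ",
      "periods must be contiguous"
    )
  }, "")
  factor(grp, levels = c("group1", "group2", "group3"))
}

#' Build the full stability series for one subcommunity
#'
#' Convenience wrapper combining [moving_windows()], [window_stability()] and
#' [assign_window_groups()].
#'
#' @param abundance_series positive numeric vector (copies/mL per sample).
#' @param periods period label per sample.
#' @param w window length.
#' @param subcommunity label stored in the output (`entire`, `core`,
#'   `satellite`).
#' @return data.frame: `window_index`, `subcommunity`, `stability`,
#'   `window_group`.
#' @export
stability_series <- function(abundance_series, periods, w = 5,
                             subcommunity = "entire") {
  win <- moving_windows(length(abundance_series), w)
  st <- window_stability(abundance_series, win)
  st$subcommunity <- subcommunity
  st$window_group <- assign_window_groups(win, periods)
  st[, c("window_index", "subcommunity", "stability", "window_group")]
}

#' Relationship between subcommunity and entire-community stability
#'
#' OLS fit and Pearson correlation of a subcommunity's windowed stability
#' against the entire community's, excluding (pairwise) windows with an
#' infinite 1/CV.
#'
#' @param sub,entire stability data.frames from [stability_series()] (or
#'   [window_stability()]) on aligned windows.
#' @return list: `slope`, `intercept`, `r`, `p`, `n` (finite pairs used).
#' @export
stability_relation <- function(sub, entire) {
  m <- merge(
    sub[, c("window_index", "stability")],
    entire[, c("window_index", "stability")],
    by = "window_index", suffixes = c("_sub", "_entire")
  )
  ok <- is.finite(m$stability_sub) & is.finite(m$stability_entire)
  m <- m[ok, ]
  if (nrow(m) < 3) stop_input("fewer than 3 finite stability pairs")
  fit <- lm(stability_sub ~ stability_entire, data = m)
  ct <- suppressWarnings(cor.test(m$stability_sub, m$stability_entire))
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r = unname(ct$estimate),
    p = ct$p.value,
    n = nrow(m)
  )
}
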