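# Thermocline detection and mixing-period labelling from temperature profiles.

#' Detect the thermocline depth of a temperature profile
#'
#' The thermocline is taken as the shallowest depth at which the magnitude of
#' the vertical temperature gradient between successive measurement depths
#' exceeds `gradient_threshold` (the classical 0.2 degC/m criterion for lakes
#' and reservoirs). The gradient of each successive pair is assigned to the
#' deeper endpoint, so the returned value is the depth at which stratified
#' water is first encountered.
#'
#' @param depths numeric, measurement depths in metres, strictly increasing.
#' @param temperatures numeric, water temperature in degC, same length.
#' @param gradient_threshold gradient criterion in degC per metre; a pair must
#'   exceed it strictly for a thermocline to be declared.
#' @return The thermocline depth in metres, or `NA_real_` when no successive
#'   pair exceeds the threshold (a fully mixed water column).
#' @examples
#' thermocline_depth(c(1, 2, 3, 4), c(25, 25, 24, 23.9))  # 3
#' thermocline_depth(c(1, 5, 10), c(20, 20, 20))          # NA: mixed
#' @export
thermocline_depth <- function(depths, temperatures, gradient_threshold = 0.2) {
  if (length(depths) < 2 || length(depths) != length(temperatures)) {
    stop_input("profile needs >= 2 paired depth/temperature points")
  }
  if (any(!is.finite(depths)) || any(!is.finite(temperatures))) {
    stop_input("profile contains non-finite values")
  }
  if (any(diff(depths) <= 0)) {
    stop_input("depths must be strictly increasing")
  }
  if (any(depths <= 0)) stop_input("depths must be positive")
  grad <- abs(diff(temperatures)) / diff(depths)
  hit <- which(grad > gradient_threshold)
  if (length(hit) == 0) return(NA_real_)
  depths[hit[1] + 1]  # deeper endpoint of the first exceeding pair
}

#' Label chronologically ordered visits with disturbance periods
#'
#' Given the presence/absence of a thermocline at each sampling visit, assigns
#' the run-length encoded period labels used by the whole pipeline: the
#' leading run of stratified visits is `before`, the single maximal run of
#' mixed visits is `mixing`, and the trailing stratified visits are `after`.
#'
#' @param thermocline_present logical vector, one entry per visit in
#'   chronological order (`TRUE` = thermocline detected).
#' @return factor of labels `before`/`mixing`/`after`, one per visit.
#' @examples
#' label_periods(rep(c(TRUE, FALSE, TRUE), c(14, 11, 9)))
#' @export
label_periods <- function(thermocline_present) {
  if (length(thermocline_present) == 0) return(as_period(character(0)))
  if (any(is.na(thermocline_present))) stop_input("presence flags must not be NA")
  r <- rle(as.logical(thermocline_present))
  absent_runs <- which(!r$values)
  if (length(absent_runs) > 1) {
    stop_input(
      "ambiguous period structure: ", length(absent_runs),
      " separate runs without a thermocline (run lengths ",
      paste(r$lengths[absent_runs], collapse = ", "), ")"
    )
  }
  if (length(absent_runs) == 0) {
    return(as_period(rep("before", length(thermocline_present))))
  }
  n_before <- sum(r$lengths[seq_len(absent_runs - 1)])
  n_mixing <- r$lengths[absent_runs]
  n_after <- length(thermocline_present) - n_before - n_mixing
  as_period(rep(c("before", "mixing", "after"), c(n_before, n_mixing, n_after)))
}
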