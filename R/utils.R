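#' @importFrom stats cor cor.test coef cov dist kruskal.test lm median p.adjust
#'   pchisq pnorm pt quantile rbinom rlnorm rmultinom rnorm runif sd setNames
#'   var complete.cases
#' @importFrom utils combn head write.csv read.csv read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Derive a stage-specific seed from a master seed so that independent stages
# of a pipeline run do not share random streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}

# Ordered period levels used throughout.
period_levels <- function() c("before", "mixing", "after")

as_period <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), period_levels())
  if (length(bad) > 0) {
    stop_input("unknown period label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = period_levels())
}
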