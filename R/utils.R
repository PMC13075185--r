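#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats coef cor lm median pnorm pt qnorm rbeta rbinom rnorm runif
#'   sd setNames var plogis predict
#' @importFrom utils head packageVersion
#' @importFrom Rcpp evalCpp
#' @useDynLib ricesalt, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# clamp numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# paper-style label for a trait's stress tolerance index (GP -> GSTI, RL -> RLSTI)
sti_label <- function(trait) {
  ifelse(trait == "GP", "GSTI", paste0(trait, "STI"))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(lo), format(hi)))
  }
  invisible(x)
}

# ordinal tolerance scale, susceptible to tolerant
tolerance_levels <- function() c("HS", "S", "MT", "T", "HT")

tolerance_factor <- function(x) {
  factor(as.character(x), levels = tolerance_levels(), ordered = TRUE)
}
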