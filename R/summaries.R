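#' Relative expression by the comparative cycle threshold method
#'
#' Classic qPCR quantification assuming perfect doubling per cycle:
#' returns `2^-ddCt` where `ddCt = (target - control)_sample -
#' (target - control)_calibrator`, with the control Ct taken from an
#' internal-control gene measured in the same cDNA.
#'
#' @param sample,calibrator lists (or 2-element numeric vectors) with
#'   elements `target_ct` and `control_ct`, finite positive cycle values.
#' @return Relative expression of the sample versus the calibrator.
#' @export
relative_expression_ddct <- function(sample, calibrator) {
  get_ct <- function(x, who) {
    if (is.numeric(x) && length(x) == 2 && is.null(names(x)))
      x <- list(target_ct = x[1], control_ct = x[2])
    t <- x$target_ct %||% x["target_ct"]
    c <- x$control_ct %||% x["control_ct"]
    t <- as.numeric(t); c <- as.numeric(c)
    if (!is.finite(t) || !is.finite(c) || t <= 0 || c <= 0)
      stopf("%s Ct values must be finite and positive", who)
    c(t, c)
  }
  s <- get_ct(sample, "sample")
  k <- get_ct(calibrator, "calibrator")
  ddct <- (s[1] - s[2]) - (k[1] - k[2])
  2^(-ddct)
}

#' Uncorrected (population-form) sample standard deviation
#'
#' `sqrt(sum((x - mean)^2) / n)` — divisor n, not n - 1. This is the
#' spread statistic quoted alongside means in the figure summaries.
#'
#' @param values non-empty numeric vector.
#' @return The uncorrected standard deviation.
#' @export
uncorrected_sd <- function(values) {
  if (!length(values)) stopf("uncorrected_sd requires at least one value")
  if (any(!is.finite(values))) stopf("values must be finite")
  sqrt(mean((values - mean(values))^2))
}

#' Integrated density of a stained region
#'
#' `IntDen = Area x Mean Gray Value`, the ImageJ-style proxy for total
#' signal (e.g., nuclear DNA amount under Feulgen staining) in a
#' segmented circular region.
#'
#' @param area region area in pixels; must be positive.
#' @param mean_gray mean gray value of the region.
#' @return The integrated density.
#' @export
integrated_density <- function(area, mean_gray) {
  if (any(area <= 0)) stopf("area must be positive")
  area * mean_gray
}
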