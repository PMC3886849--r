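# Ordinal necrosis rating and a simulated blinded-observer mechanism.
#
# The scale rates the percentage of white matter with necrosis on H&E:
# 0 = none, 1 = 1-25%, 2 = 26-50%, 3 = 51-75%, 4 = 76-100%. Diffuse gliosis
# without necrosis scores 0 by construction, which is exactly why the scale
# is insensitive to the milder end of the injury spectrum: necrosis only
# appears above a latent-severity threshold.

#' Ordinal necrosis score from percent necrotic white matter
#'
#' Score 0 iff there is no necrosis at all; otherwise half-open 25% bands
#' (0,25] -> 1, (25,50] -> 2, (50,75] -> 3, (75,100] -> 4 (the minimal
#' consistent completion of the integer band definition for fractional
#' percents).
#'
#' @param percent percent of white matter with necrosis, in [0, 100];
#'   vectorized.
#' @return integer score(s) in 0..4.
#' @examples
#' necrosis_to_score(c(0, 30, 100))
#' @export
necrosis_to_score <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0 | percent > 100))
    stopf("necrosis percent must be in [0, 100]")
  as.integer(ifelse(percent == 0, 0L, pmin(4L, ceiling(percent / 25))))
}

#' Simulate percent necrosis from latent injury severity
#'
#' Rectified-linear link with additive pre-threshold noise:
#' `percent = clamp(gain * max(0, severity - threshold + noise), 0, 100)`.
#' Below threshold there is no necrosis (diffuse gliosis only); above it
#' necrotic burden grows linearly. The default threshold is calibrated so
#' that with standard-normal severity about 12 of 17 injured animals score 0.
#'
#' @param severity latent severity (unitless, ~N(0,1) under the default
#'   cohort model); vectorized.
#' @param threshold severity above which necrosis appears.
#' @param gain percent necrosis per severity unit above threshold; > 0.
#' @param noise_sd SD of the observer/biology noise on the threshold scale.
#' @param seed optional seed; if `NULL` draws from the current RNG stream.
#' @return percent necrosis in [0, 100], same length as `severity`.
#' @export
simulate_necrosis_percent <- function(severity, threshold = 0.5944, gain = 30,
                                      noise_sd = 0.45, seed = NULL) {
  stopifnot(gain > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  noise <- rnorm(length(severity), 0, noise_sd)
  clamp(gain * pmax(0, severity - threshold + noise), 0, 100)
}
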