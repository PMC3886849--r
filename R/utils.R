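#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rlnorm runif sd var cor lm coef resid pt pf anova
#'   setNames complete.cases qnorm pnorm median quantile
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage child seed from a top-level seed
#'
#' One top-level seed fans out to per-stage seeds by fixed offsets, so stages
#' are reproducible independently of how many random draws earlier stages
#' consumed. Result always fits a 32-bit integer.
#'
#' @param seed integer top-level seed.
#' @param offset integer stage offset (each pipeline stage uses its own).
#' @return an integer seed.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 1009 + as.double(offset) * 99991) %% 2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
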