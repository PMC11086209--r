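#' Approximate entropy
#'
#' Regularity statistic ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r) of a time
#' series: the negative mean log conditional probability that runs of
#' length `m` that match within tolerance `r` (Chebyshev distance,
#' self-matches included) still match at length `m + 1`. Predictable
#' signals score near zero; irregular signals score high. ApEn is the
#' featurization applied to every sensor channel before non-time-series
#' classification.
#'
#' @param series numeric vector, length at least `m + 2`.
#' @param m template length (default 2, the standard convention).
#' @param r matching tolerance; defaults to `0.2 * sd(series)`, making the
#'   statistic invariant to shifting and scaling of the input. A constant
#'   series (sd 0) short-circuits to 0: it produces no information.
#' @return A single non-negative scalar (up to estimator noise).
#' @export
approx_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series must not contain missing values")
  if (length(series) < m + 2)
    stop(sprintf("series too short for ApEn: length %d, need >= %d",
                 length(series), m + 2))
  if (stats::sd(series) == 0) return(0)
  if (!is.finite(r) || r <= 0) stop("`r` must be positive")
  .apen_cpp(series, as.integer(m), r)
}
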