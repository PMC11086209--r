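#' RR-interval series
#'
#' Construct a validated RR-interval series: one timestamped inter-beat
#' interval per detected heartbeat, the substrate of all heart-rate
#' variability computations in this package.
#'
#' @param t numeric vector of UNIX epoch seconds, one per beat, strictly
#'   increasing.
#' @param rr_ms numeric vector of inter-beat (RR) intervals in milliseconds,
#'   all positive, same length as `t`.
#' @return An object of class `rr_series`: a data.frame with columns
#'   `t` and `rr_ms`.
#' @examples
#' rr <- rr_series(t = cumsum(rep(0.8, 5)), rr_ms = rep(800, 5))
#' @export
rr_series <- function(t, rr_ms) {
  t <- as.numeric(t)
  rr_ms <- as.numeric(rr_ms)
  if (length(t) != length(rr_ms))
    stop("`t` and `rr_ms` must have the same length")
  if (length(t) == 0L)
    stop("RR series contains no beats")
  if (anyNA(t) || anyNA(rr_ms) || any(!is.finite(rr_ms)))
    stop("RR series must be finite and free of missing values")
  if (any(rr_ms <= 0))
    stop("all RR intervals must be positive")
  if (any(diff(t) <= 0))
    stop("beat timestamps must be strictly increasing")
  structure(data.frame(t = t, rr_ms = rr_ms), class = c("rr_series", "data.frame"))
}

#' Read an RR-interval series from CSV
#'
#' Expects a header `t_unix,rr_ms` with one row per beat.
#'
#' @param path path to the CSV file.
#' @return An [rr_series()].
#' @export
read_rr_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_unix", "rr_ms") %in% names(d)))
    stop("RR CSV must have columns `t_unix` and `rr_ms`")
  rr_series(d$t_unix, d$rr_ms)
}

#' Round RR intervals to a fixed bin width
#'
#' Replaces each RR interval by the nearest multiple of `bin_width_ms`,
#' the noise-reduction step applied before computing histogram statistics
#' such as the Baevsky Stress Index. Exact midpoints round away from zero
#' (so 825 ms with 50 ms bins becomes 850 ms). Timestamps are untouched.
#'
#' @param rr an [rr_series()].
#' @param bin_width_ms positive bin width in milliseconds (default 50).
#' @return An `rr_series` with binned `rr_ms`.
#' @export
bin_rr <- function(rr, bin_width_ms = 50) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(bin_width_ms) != 1L || !is.finite(bin_width_ms) || bin_width_ms <= 0)
    stop("`bin_width_ms` must be a single positive number")
  if (nrow(rr) == 0L) stop("RR series contains no beats")
  # floor(x/w + 0.5) rounds halves up; rr_ms > 0 so "up" is away from zero
  binned <- floor(rr$rr_ms / bin_width_ms + 0.5) * bin_width_ms
  rr_series(rr$t, binned)
}

#' Mode statistics of a binned RR series
#'
#' Returns the mode Mo (most frequent binned RR value, in seconds) and its
#' amplitude AMo (the mode's share of all beats, in percent). On a
#' multimodal tie the smallest RR value wins, keeping the statistic
#' deterministic.
#'
#' @param binned an [rr_series()] whose intervals have been passed through
#'   [bin_rr()].
#' @return A list with `mo_s` (seconds) and `amo_pct` (percent).
#' @export
mode_stats <- function(binned) {
  stopifnot(inherits(binned, "rr_series"))
  if (nrow(binned) == 0L) stop("RR series contains no beats")
  counts <- table(binned$rr_ms)
  vals <- as.numeric(names(counts))
  best <- which(counts == max(counts))
  mo_ms <- min(vals[best])  # tie-break: smallest RR value
  list(
    mo_s = mo_ms / 1000,
    amo_pct = 100 * max(counts) / nrow(binned)
  )
}

#' Range of a binned RR series
#'
#' MxDMn: difference between the longest and the shortest RR interval of
#' the (binned) series, in seconds.
#'
#' @inheritParams mode_stats
#' @return Range in seconds (>= 0).
#' @export
mxdmn <- function(binned) {
  stopifnot(inherits(binned, "rr_series"))
  if (nrow(binned) == 0L) stop("RR series contains no beats")
  (max(binned$rr_ms) - min(binned$rr_ms)) / 1000
}

#' Baevsky Stress Index
#'
#' Computes the Baevsky Stress Index SI = AMo / (2 * Mo * MxDMn) from an
#' RR-interval series, after rounding the intervals to 50 ms bins. AMo is
#' expressed in percent and Mo and MxDMn in seconds — the unit convention
#' under which published SI magnitudes (tens to hundreds in healthy adults,
#' higher under sympathetic stress) arise. Low beat-to-beat variability
#' concentrates the RR histogram (high AMo, small MxDMn) and therefore
#' yields a high index.
#'
#' @param rr an [rr_series()].
#' @param bin_width_ms histogram bin width in milliseconds (default 50).
#' @return An object of class `bsi_result`: a list with fields `mo_s`,
#'   `amo_pct`, `mxdmn_s` and `si`.
#' @examples
#' baevsky_si(rr_series(1:4, c(800, 800, 800, 850)))  # si = 937.5
#' @export
baevsky_si <- function(rr, bin_width_ms = 50) {
  binned <- bin_rr(rr, bin_width_ms)
  ms <- mode_stats(binned)
  rng <- mxdmn(binned)
  if (rng <= 0)
    stop("degenerate variability: MxDMn is zero after binning (constant heart rate), SI undefined")
  structure(
    list(mo_s = ms$mo_s, amo_pct = ms$amo_pct, mxdmn_s = rng,
         si = ms$amo_pct / (2 * ms$mo_s * rng)),
    class = "bsi_result"
  )
}

#' @export
print.bsi_result <- function(x, ...) {
  cat(sprintf("Baevsky Stress Index: %.2f  (Mo = %.3f s, AMo = %.1f %%, MxDMn = %.3f s)\n",
              x$si, x$mo_s, x$amo_pct, x$mxdmn_s))
  invisible(x)
}

#' Baevsky Stress Index over a task window
#'
#' Restricts the series to beats whose timestamps fall in the half-open
#' window `[t_start, t_end)` and computes [baevsky_si()] on them. At least
#' `min_beats` beats are required; mode and range statistics are
#' meaningless on fewer.
#'
#' @param rr an [rr_series()].
#' @param task_window numeric length-2 vector `c(t_start, t_end)` in UNIX
#'   seconds.
#' @param min_beats minimum number of in-window beats (default 10).
#' @param bin_width_ms histogram bin width in milliseconds (default 50).
#' @return A `bsi_result` for the windowed beats.
#' @export
per_task_bsi <- function(rr, task_window, min_beats = 10, bin_width_ms = 50) {
  stopifnot(inherits(rr, "rr_series"), length(task_window) == 2L)
  if (task_window[2] <= task_window[1]) stop("task window must be well-ordered")
  keep <- rr$t >= task_window[1] & rr$t < task_window[2]
  if (sum(keep) < min_beats)
    stop(sprintf("insufficient data: %d beats in window, need at least %d",
                 sum(keep), min_beats))
  baevsky_si(rr_series(rr$t[keep], rr$rr_ms[keep]), bin_width_ms)
}
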