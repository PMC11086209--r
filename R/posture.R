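#' Pose landmark series
#'
#' Validates a long-format table of 2D pose-landmark detections. Landmark
#' ids follow the common 33-point whole-body numbering, in which id 12 is
#' the right shoulder and id 14 the right elbow — the two points reliably
#' visible from a camera placed on the subject's right side at the console.
#'
#' @param df data.frame with columns `t`, `landmark_id`, `x`, `y`
#'   (image coordinates, pixels or normalised; the metrics are covariant
#'   with the unit, so it only needs to be consistent).
#' @return The validated data.frame with class `landmark_series`.
#' @export
landmark_series <- function(df) {
  need <- c("t", "landmark_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark series needs columns: ", paste(need, collapse = ", "))
  if (any(df$landmark_id < 0 | df$landmark_id > 32))
    stop("landmark ids must lie in 0..32")
  ord <- order(df$landmark_id, df$t)
  df <- df[ord, , drop = FALSE]
  if (any(stats::ave(df$t, df$landmark_id, FUN = function(v) c(1, diff(v))) < 0))
    stop("timestamps must be non-decreasing within each landmark")
  class(df) <- c("landmark_series", "data.frame")
  df
}

#' Read a landmark series from CSV
#'
#' Expects a header `t_unix,landmark_id,x,y`.
#'
#' @param path path to the CSV file.
#' @return A [landmark_series()].
#' @export
read_landmark_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d)[names(d) == "t_unix"] <- "t"
  landmark_series(d)
}

#' Shift a landmark series clock
#'
#' Posture videos are recorded on a separate device without a shared clock,
#' so each trial carries a manually determined offset that aligns the
#' posture stream with the UNIX-stamped sensor streams.
#'
#' @param series a [landmark_series()].
#' @param offset_s finite clock offset in seconds, added to all timestamps.
#' @return The shifted [landmark_series()].
#' @export
align_posture_clock <- function(series, offset_s) {
  stopifnot(inherits(series, "landmark_series"))
  if (length(offset_s) != 1L || !is.finite(offset_s))
    stop("`offset_s` must be a single finite number")
  series$t <- series$t + offset_s
  series
}

#' Posture metrics over a task window
#'
#' Reduces the tracked right-shoulder and right-elbow landmark series to
#' vertical-displacement metrics. The primary metric per landmark is the
#' time-averaged absolute vertical velocity: mean |first difference of y|
#' divided by the mean sampling interval. Because absolute differences are
#' used, the metric does not depend on whether image y grows up or down.
#' The peak-to-peak vertical range over the window is returned alongside as
#' a secondary descriptor.
#'
#' @param series a [landmark_series()] (already clock-aligned).
#' @param task_window numeric `c(t_start, t_end)`, half-open `[start, end)`.
#' @param shoulder_id,elbow_id landmark ids of the tracked points
#'   (defaults 12 and 14, the right shoulder and right elbow).
#' @return An object of class `posture_summary`: list with `elbow_vy`,
#'   `shoulder_vy` (coordinate units per second) and `elbow_range`,
#'   `shoulder_range` (coordinate units).
#' @export
posture_summary <- function(series, task_window, shoulder_id = 12, elbow_id = 14) {
  stopifnot(inherits(series, "landmark_series"), length(task_window) == 2L)
  one <- function(id, label) {
    d <- series[series$landmark_id == id &
                  series$t >= task_window[1] & series$t < task_window[2], ,
                drop = FALSE]
    if (nrow(d) < 2L)
      stop(sprintf("missing landmark in window: %s (id %d) has %d samples, need >= 2",
                   label, id, nrow(d)))
    d <- d[order(d$t), , drop = FALSE]
    list(vy = mean(abs(diff(d$y))) / mean(diff(d$t)),
         rng = max(d$y) - min(d$y))
  }
  sh <- one(shoulder_id, "right shoulder")
  el <- one(elbow_id, "right elbow")
  structure(list(elbow_vy = el$vy, shoulder_vy = sh$vy,
                 elbow_range = el$rng, shoulder_range = sh$rng),
            class = "posture_summary")
}
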