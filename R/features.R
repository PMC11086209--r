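# order and names of the eleven per-trial feature channels
.feature_channels <- c("hr", "right_x", "right_y", "right_z",
                       "left_x", "left_y", "left_z",
                       "shoulder_x", "shoulder_y", "elbow_x", "elbow_y")

#' Build the approximate-entropy feature matrix
#'
#' Converts each trial's time-series channels into the eleven-scalar
#' feature vector used for skill classification: the ApEn of the
#' instantaneous heart-rate series (60000 / RR, linearly resampled onto the
#' common grid), of the six hand-position coordinates (right- and left-hand
#' x, y, z in the reference-marker frame), and of the four posture
#' coordinates (right shoulder and right elbow x, y). Trials missing any
#' channel are dropped with a message and listed in the `dropped`
#' attribute.
#'
#' @param trials list of [trial_record()] objects.
#' @param grid_hz synchronization grid rate (default 10).
#' @param m,r_factor ApEn hyperparameters: template length and tolerance
#'   factor (`r = r_factor * sd(channel)`); defaults 2 and 0.2, the
#'   standard convention.
#' @param shoulder_id,elbow_id tracked landmark ids (defaults 12, 14).
#' @return Numeric matrix, one row per retained trial, columns `hr`,
#'   `right_x` ... `elbow_y`; attribute `dropped` holds indices of dropped
#'   trials and `trial` the retained ones.
#' @export
build_feature_matrix <- function(trials, grid_hz = 10, m = 2, r_factor = 0.2,
                                 shoulder_id = 12, elbow_id = 14) {
  one <- function(tr) {
    syn <- synchronize(tr, grid_hz)
    grid <- syn$grid_t
    if (is.null(syn$left) || is.null(syn$right) || is.null(syn$posture) ||
        is.null(tr$rr))
      stop("missing channel")
    hr_t <- tr$rr$t
    keep <- hr_t >= tr$task_window[1] & hr_t < tr$task_window[2]
    if (sum(keep) < 2L) stop("missing channel: heart rate")
    hr_grid <- grid[grid >= min(hr_t[keep]) & grid <= max(hr_t[keep])]
    hr <- stats::approx(hr_t[keep], 60000 / tr$rr$rr_ms[keep], xout = hr_grid)$y
    lm <- function(id, cl) {
      d <- syn$posture[syn$posture$landmark_id == id, , drop = FALSE]
      if (nrow(d) < m + 2) stop("missing channel: landmark ", id)
      d[[cl]]
    }
    chans <- list(hr = hr,
                  right_x = syn$right$x, right_y = syn$right$y,
                  right_z = syn$right$z,
                  left_x = syn$left$x, left_y = syn$left$y,
                  left_z = syn$left$z,
                  shoulder_x = lm(shoulder_id, "x"),
                  shoulder_y = lm(shoulder_id, "y"),
                  elbow_x = lm(elbow_id, "x"), elbow_y = lm(elbow_id, "y"))
    vapply(chans, function(v) approx_entropy(v, m = m,
                                             r = r_factor * stats::sd(v)),
           numeric(1))
  }
  rows <- vector("list", length(trials))
  dropped <- integer(0)
  for (i in seq_along(trials)) {
    rows[[i]] <- tryCatch(one(trials[[i]]), error = function(e) {
      message(sprintf("trial %d dropped from feature matrix: %s",
                      i, conditionMessage(e)))
      NULL
    })
    if (is.null(rows[[i]])) dropped <- c(dropped, i)
  }
  keep <- setdiff(seq_along(trials), dropped)
  out <- do.call(rbind, rows[keep])
  colnames(out) <- .feature_channels
  attr(out, "dropped") <- dropped
  attr(out, "trial") <- keep
  out
}
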