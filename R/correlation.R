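# Table column order of the per-trial metric battery: 10 hand-movement
# metrics, 2 bimanuality ratios, 2 posture metrics, 6 workload-questionnaire
# scores, 5 manually recorded scores.
.metric_columns <- c(
  "Lefthand_std", "Lefthand_range", "Lefthand_total_dist", "Lefthand_avg_speed",
  "Left_jerk", "Righthand_std", "Righthand_range", "Righthand_total_dist",
  "Righthand_avg_speed", "Right_jerk", "Total_dist_rate", "Range_rate",
  "Elbow_vy", "Shoulder_vy",
  "Mental_fatigue", "Physical_fatigue", "Temporal_demands", "Complexity",
  "Situational_stress", "Distractions",
  "Collisions_phantom", "Collision_robot_arms", "Rings_placed", "Ring_drops",
  "Spike_color_missed"
)

#' Metric battery column names
#'
#' Names and order of the 25 per-trial metrics correlated against the
#' Baevsky Stress Index.
#' @return Character vector of length 25.
#' @export
metric_columns <- function() .metric_columns

#' Workload questionnaire responses
#'
#' Six-dimension surgical task-load responses, each an integer score from
#' 1 to 20.
#'
#' @param mental,physical,temporal,complexity,situational_stress,distractions
#'   integer scores in 1..20.
#' @return A named list with class `surg_tlx`.
#' @export
surg_tlx <- function(mental, physical, temporal, complexity,
                     situational_stress, distractions) {
  v <- c(mental = mental, physical = physical, temporal = temporal,
         complexity = complexity, situational_stress = situational_stress,
         distractions = distractions)
  if (any(v != round(v)) || any(v < 1) || any(v > 20))
    stop("workload scores must be integers in 1..20")
  structure(as.list(v), class = "surg_tlx")
}

#' One subject-task trial record
#'
#' Bundles all streams and scores of one trial. Hand movement may be given
#' either as raw camera-frame marker observations (`markers`; the normal
#' path, exercised through [build_trajectory()]) or as ready reference-frame
#' trajectories (`left`, `right`).
#'
#' @param subject_id subject identifier.
#' @param group one of `"novice"`, `"resident"`, `"surgeon"`.
#' @param task_id task number 1..4.
#' @param task_window numeric `c(t_start, t_end)`, UNIX seconds.
#' @param rr an [rr_series()].
#' @param markers a [marker_obs()] table, or NULL.
#' @param left,right [trajectory()] objects, or NULL if `markers` given.
#' @param posture a [landmark_series()].
#' @param posture_offset_s manual clock offset applied to the posture
#'   stream before analysis (default 0).
#' @param tlx a [surg_tlx()].
#' @param manual named list of non-negative integer scores:
#'   `collisions_phantom`, `collision_robot_arms`, `rings_placed`,
#'   `ring_drops`, `spike_color_missed`.
#' @return A list with class `trial_record`.
#' @export
trial_record <- function(subject_id, group, task_id, task_window, rr,
                         markers = NULL, left = NULL, right = NULL,
                         posture = NULL, posture_offset_s = 0,
                         tlx = NULL, manual = NULL) {
  group <- match.arg(group, c("novice", "resident", "surgeon"))
  stopifnot(length(task_window) == 2L, task_window[1] < task_window[2])
  if (!is.null(manual)) {
    need <- c("collisions_phantom", "collision_robot_arms", "rings_placed",
              "ring_drops", "spike_color_missed")
    if (!all(need %in% names(manual)) || any(unlist(manual[need]) < 0))
      stop("`manual` must contain non-negative counts: ",
           paste(need, collapse = ", "))
  }
  structure(list(subject_id = subject_id, group = group, task_id = task_id,
                 task_window = as.numeric(task_window), rr = rr,
                 markers = markers, left = left, right = right,
                 posture = posture, posture_offset_s = posture_offset_s,
                 tlx = tlx, manual = manual),
            class = "trial_record")
}

#' Synchronize the streams of a trial onto a common grid
#'
#' Hand trajectories (built from raw markers if needed) and the
#' clock-aligned posture stream are resampled by linear interpolation onto
#' a common regular grid over the task window. RR intervals are an event
#' series and are left untouched; they are consumed per-window by
#' [per_task_bsi()].
#'
#' @param trial a [trial_record()].
#' @param grid_hz grid rate in Hz (default 10, the marker-tracking rate).
#' @return The trial with gridded `left`, `right` and `posture` streams and
#'   a `grid_t` element holding the grid timestamps.
#' @export
synchronize <- function(trial, grid_hz = 10) {
  stopifnot(inherits(trial, "trial_record"))
  w <- trial$task_window
  n <- floor((w[2] - w[1]) * grid_hz - 1e-9) + 1L
  grid <- w[1] + (seq_len(n) - 1L) / grid_hz
  if (is.null(trial$left) && !is.null(trial$markers)) {
    trial$left <- build_trajectory(trial$markers, "left")
    trial$right <- build_trajectory(trial$markers, "right")
  }
  eps <- 1e-6  # timestamp round-trip jitter tolerance (seconds)
  regrid_traj <- function(traj, label) {
    if (is.null(traj)) return(NULL)
    if (nrow(traj) < 2L || min(traj$t) > grid[n] || max(traj$t) < grid[1])
      stop(sprintf("stream `%s` does not overlap the task window", label))
    g <- grid[grid >= min(traj$t) - eps & grid <= max(traj$t) + eps]
    pos <- vapply(c("x", "y", "z"),
                  function(cl) stats::approx(traj$t, traj[[cl]], xout = g,
                                             rule = 2)$y,
                  numeric(length(g)))
    trajectory(g, pos, attr(traj, "hand"), attr(traj, "n_dropped"))
  }
  trial$left <- regrid_traj(trial$left, "left trajectory")
  trial$right <- regrid_traj(trial$right, "right trajectory")
  if (!is.null(trial$posture)) {
    p <- align_posture_clock(trial$posture, trial$posture_offset_s)
    out <- lapply(unique(p$landmark_id), function(id) {
      d <- p[p$landmark_id == id, , drop = FALSE]
      if (nrow(d) < 2L || min(d$t) > grid[n] || max(d$t) < grid[1])
        stop("stream `posture` does not overlap the task window")
      g <- grid[grid >= min(d$t) - eps & grid <= max(d$t) + eps]
      data.frame(t = g, landmark_id = id,
                 x = stats::approx(d$t, d$x, xout = g, rule = 2)$y,
                 y = stats::approx(d$t, d$y, xout = g, rule = 2)$y)
    })
    trial$posture <- landmark_series(do.call(rbind, out))
    trial$posture_offset_s <- 0
  }
  trial$grid_t <- grid
  trial
}

#' Assemble the per-trial metric table
#'
#' Runs every trial through stream synchronization and the per-module
#' summaries, producing one row per trial: the Baevsky Stress Index plus
#' the 25 metrics of [metric_columns()]. A metric whose computation fails
#' on a trial (degenerate variability, missing stream, zero ratio
#' denominator, ...) is recorded as NA — flagged, never zero-filled — and
#' is later excluded pairwise from that metric's correlation.
#'
#' @param trials list of [trial_record()] objects, length >= 3.
#' @param grid_hz synchronization grid rate (default 10).
#' @return A data.frame with class `metric_table`: identification columns,
#'   `BSI`, and the 25 metric columns.
#' @export
build_metric_table <- function(trials, grid_hz = 10) {
  if (length(trials) < 3L) stop("need at least 3 trials")
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    stopifnot(inherits(tr, "trial_record"))
    syn <- tryCatch(synchronize(tr, grid_hz), error = function(e) tr)
    row <- stats::setNames(as.list(rep(NA_real_, 26L)), c("BSI", .metric_columns))
    row$BSI <- safe(per_task_bsi(tr$rr, tr$task_window)$si)
    kl <- tryCatch(kinematic_summary(syn$left, grid_hz), error = function(e) NULL)
    kr <- tryCatch(kinematic_summary(syn$right, grid_hz), error = function(e) NULL)
    if (!is.null(kl)) {
      row$Lefthand_std <- kl$std3d_m; row$Lefthand_range <- kl$range_m
      row$Lefthand_total_dist <- kl$total_dist_m
      row$Lefthand_avg_speed <- kl$avg_speed_mps; row$Left_jerk <- kl$jerk_mps3
    }
    if (!is.null(kr)) {
      row$Righthand_std <- kr$std3d_m; row$Righthand_range <- kr$range_m
      row$Righthand_total_dist <- kr$total_dist_m
      row$Righthand_avg_speed <- kr$avg_speed_mps; row$Right_jerk <- kr$jerk_mps3
    }
    if (!is.null(kl) && !is.null(kr)) {
      rates <- tryCatch(bimanuality_ratios(kr, kl), error = function(e) NULL)
      if (!is.null(rates)) {
        row$Total_dist_rate <- rates$total_dist_rate
        row$Range_rate <- rates$range_rate
      }
    }
    if (!is.null(syn$posture)) {
      ps <- tryCatch(posture_summary(syn$posture, tr$task_window),
                     error = function(e) NULL)
      if (!is.null(ps)) {
        row$Elbow_vy <- ps$elbow_vy; row$Shoulder_vy <- ps$shoulder_vy
      }
    }
    if (!is.null(tr$tlx)) {
      row$Mental_fatigue <- tr$tlx$mental
      row$Physical_fatigue <- tr$tlx$physical
      row$Temporal_demands <- tr$tlx$temporal
      row$Complexity <- tr$tlx$complexity
      row$Situational_stress <- tr$tlx$situational_stress
      row$Distractions <- tr$tlx$distractions
    }
    if (!is.null(tr$manual)) {
      row$Collisions_phantom <- tr$manual$collisions_phantom
      row$Collision_robot_arms <- tr$manual$collision_robot_arms
      row$Rings_placed <- tr$manual$rings_placed
      row$Ring_drops <- tr$manual$ring_drops
      row$Spike_color_missed <- tr$manual$spike_color_missed
    }
    cbind(data.frame(trial = i, subject_id = tr$subject_id, group = tr$group,
                     task_id = tr$task_id, stringsAsFactors = FALSE),
          as.data.frame(row))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson coefficient between two vectors after pairwise deletion
#' of missing entries, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (computed via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length; NAs deleted pairwise.
#' @return A list with `r`, `p` and `n` (pairs used).
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Significance tier of a correlation p-value
#'
#' p below 0.05 counts as a strong, statistically significant correlation;
#' p in the closed interval 0.05 to 0.08 as a weak or possible correlation
#' worth examining on larger datasets; anything above as none.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector: `"strong"`, `"weak"` or `"none"`.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.05, "strong", ifelse(p <= 0.08, "weak", "none"))
}

#' Correlation report against the stress index
#'
#' Correlates every metric column of a [build_metric_table()] result with
#' the Baevsky Stress Index column: Pearson r, two-sided p, pairs used,
#' significance tier and correlation sign, one row per metric in the fixed
#' battery order. Metrics with fewer than 3 valid pairs or zero variance
#' are reported with tier `"insufficient data"`.
#'
#' @param table a `metric_table`.
#' @return A data.frame with class `correlation_report`: columns `metric`,
#'   `r`, `p`, `n_pairs`, `tier`, `sign`.
#' @export
correlation_report <- function(table) {
  stopifnot(inherits(table, "metric_table"))
  if (sum(is.finite(table$BSI)) < 3L)
    stop("BSI column has fewer than 3 valid entries")
  rows <- lapply(.metric_columns, function(m) {
    res <- tryCatch(pearson_with_p(table[[m]], table$BSI),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(metric = m, r = NA_real_, p = NA_real_,
                        n_pairs = sum(is.finite(table[[m]]) & is.finite(table$BSI)),
                        tier = "insufficient data", sign = "",
                        stringsAsFactors = FALSE))
    data.frame(metric = m, r = res$r, p = res$p, n_pairs = res$n,
               tier = significance_tier(res$p),
               sign = if (res$r >= 0) "+" else "-",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_report", "data.frame")
  out
}
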