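# Synthetic cohort generator: complete trials with planted stress/skill
# structure so every pipeline stage can be exercised without access to the
# restricted clinical recordings. Each trial carries a latent stress level
# s ~ Uniform(0,1) that drives heart-rate variability (hence the stress
# index), the left hand's movement envelope, posture oscillation amplitude
# and two questionnaire dimensions; group membership carries a skill level
# that drives the manually recorded error counts. Calibration constants
# below were fixed once, by simulation, so that the cohort reproduces the
# dominant/non-dominant path-length ratio of about 1.7 and bounding-box
# ratio of about 6.2 at the calibration point s = 0.5.

.cohort_const <- list(
  # left hand: a fixed-shape AR(1) walk (phi constant) scaled by the planted
  # envelope 0.05 + 0.06 s (bounding-box diagonal, metres), so every
  # left-hand metric is exactly scale-covariant in the envelope
  left_diag = function(s) 0.05 + 0.06 * s,
  left_stat_per_diag = 0.0946,     # sigma_stat per unit of target diagonal
  left_phi = 0.90,                # fixed AR(1) coefficient at 10 Hz
  # right hand: fixed stationary spread, per-step volatility decreasing in
  # stress (path shortens under stress); both calibrated to the 1.7 / 6.2
  # ratio anchors at s = 0.5
  right_stat = 0.1100,
  right_vol = function(s) 0.00699 * (1 - 0.35 * s),
  skill_vol_factor = function(skill) 1.05 - 0.1 * skill,
  hand_centres = list(left = c(-0.15, 0.00, 0.40), right = c(0.15, 0.00, 0.40)),
  marker_rvec = list(left = c(0.30, -0.20, 0.10), right = c(-0.25, 0.15, 0.20)),
  ref_rvec_world = c(0.10, 0.20, -0.15),
  ref_tvec_world = c(0.05, 0.20, 1.20),
  cam_rvec_base = c(0.20, -0.10, 0.05),
  cam_tvec_base = c(0.10, -0.30, -1.00),
  cam_wobble_rot_sd = 0.02,       # rad, AR(1) stationary sd
  cam_wobble_trans_sd = 0.005,    # m
  cam_wobble_phi = 0.98,
  tvec_z_noise_sd = 0.004,        # m; the RGB-D depth channel is exact
  posture_y0 = c(shoulder = 0.35, elbow = 0.55),
  posture_amp = function(s) 0.01 + 0.04 * s,
  posture_noise_sd = 0.002
)

#' Specification of a synthetic cohort
#'
#' Defaults mirror the study conditions: three groups (novice medical
#' students, resident surgeons, board-eligible laparoscopic surgeons) of
#' five subjects each, four tasks per subject, with the trial list
#' truncated to 58 trials; two-minute tasks; RR intervals Gaussian with
#' mean `900 - 150 s` ms and sd `90 (1 - 0.7 s)` ms, truncated at 300 ms,
#' so higher latent stress s means a faster, more rigid heart rate and a
#' higher stress index.
#'
#' @param n_per_group subjects per group (default 5).
#' @param tasks_per_subject tasks per subject (default 4).
#' @param n_trials total trials kept (default 58).
#' @param duration_s task duration in seconds (default 120).
#' @param seed master seed; everything downstream is deterministic in it.
#' @param base_epoch UNIX epoch of the first trial (default 1714600000).
#' @param mean_rr_ms,sd_rr_ms functions of latent stress s giving the RR
#'   model.
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 5, tasks_per_subject = 4, n_trials = 58,
                        duration_s = 120, seed = 20240502,
                        base_epoch = 1714600000,
                        mean_rr_ms = function(s) 900 - 150 * s,
                        sd_rr_ms = function(s) 90 * (1 - 0.7 * s)) {
  structure(list(n_per_group = n_per_group,
                 tasks_per_subject = tasks_per_subject,
                 n_trials = n_trials, duration_s = duration_s, seed = seed,
                 base_epoch = base_epoch, mean_rr_ms = mean_rr_ms,
                 sd_rr_ms = sd_rr_ms),
            class = "cohort_spec")
}

# stationary AR(1) series of length n
.ar1 <- function(n, phi, sd_stat) {
  x0 <- stats::rnorm(1, 0, sd_stat)
  e <- stats::rnorm(n, 0, sd_stat * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
}

#' Generate an RR-interval series
#'
#' Beats are drawn with Gaussian RR intervals (mean and sd from the cohort
#' spec at latent stress `s`, truncated below at 300 ms) and cumulative
#' timestamps, emulating a chest-strap heart-rate recording.
#'
#' @param duration_s recording length in seconds (> 10).
#' @param spec a [cohort_spec()].
#' @param s latent stress in `[0, 1]`.
#' @param seed optional seed; if NULL the current RNG stream is used.
#' @param t0 UNIX epoch of recording start.
#' @return An [rr_series()] covering `[t0, t0 + duration_s]`.
#' @export
generate_rr <- function(duration_s, spec = cohort_spec(), s = 0.5,
                        seed = NULL, t0 = spec$base_epoch) {
  if (duration_s <= 10) stop("duration must exceed 10 s")
  gen <- function() {
    mu <- spec$mean_rr_ms(s); sg <- spec$sd_rr_ms(s)
    n_max <- ceiling(duration_s * 1000 / max(mu - 3 * sg, 300)) + 10L
    rr <- pmax(stats::rnorm(n_max, mu, sg), 300)
    t <- t0 + cumsum(rr) / 1000
    keep <- t <= t0 + duration_s
    rr_series(t[keep], rr[keep])
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Generate hand trajectories and their camera-frame marker observations
#'
#' Hands follow smoothed mean-reverting (Ornstein-Uhlenbeck style) walks
#' confined to per-hand envelopes: the left hand is a fixed-shape walk
#' scaled by an envelope that grows with latent stress (so all its metrics
#' scale together), and the right-hand envelope is fixed while its
#' per-step volatility falls with stress. The planted
#' reference-frame trajectories are also emitted as raw camera-frame marker
#' observations of the reference marker and the two hand markers, composed
#' through a wobbling camera pose, so that trajectory reconstruction has to
#' perform real rebasing to recover them. The z component of each emitted
#' translation carries measurement noise while the depth channel is exact,
#' so depth substitution is material to exact recovery.
#'
#' @inheritParams generate_rr
#' @param skill skill level in `[0, 1]` (mild overall efficiency factor,
#'   cancels in bimanuality ratios).
#' @param grid_hz sampling rate (default 10).
#' @return A list with `left` and `right` [trajectory()] objects and
#'   `markers`, a [marker_obs()] table.
#' @export
generate_hand_trajectories <- function(duration_s, spec = cohort_spec(),
                                       s = 0.5, skill = 0.5, seed = NULL,
                                       t0 = spec$base_epoch, grid_hz = 10) {
  cc <- .cohort_const
  gen <- function() {
    n <- as.integer(round(duration_s * grid_hz))
    t <- t0 + (seq_len(n) - 1L) / grid_hz
    sf <- cc$skill_vol_factor(skill)
    walk <- function(sd_stat, phi, centre) {
      sweep(vapply(1:3, function(j) .ar1(n, phi, sd_stat), numeric(n)),
            2, centre, "+")
    }
    sdL <- cc$left_stat_per_diag * cc$left_diag(s) * sf
    left_pos <- walk(sdL, cc$left_phi, cc$hand_centres$left)
    volR <- min(cc$right_vol(s) * sf, 0.99 * cc$right_stat)
    right_pos <- walk(cc$right_stat, sqrt(1 - (volR / cc$right_stat)^2),
                      cc$hand_centres$right)
    # camera pose wobble in the world frame
    wob <- vapply(1:6, function(j) .ar1(n, cc$cam_wobble_phi,
                                        if (j <= 3) cc$cam_wobble_rot_sd
                                        else cc$cam_wobble_trans_sd),
                  numeric(n))
    R_cam <- rodrigues_many(sweep(wob[, 1:3, drop = FALSE], 2,
                                  cc$cam_rvec_base, "+"))
    p_cam <- sweep(wob[, 4:6, drop = FALSE], 2, cc$cam_tvec_base, "+")
    R_cam_t <- rot_transpose_many(R_cam)
    R1w <- rodrigues(cc$ref_rvec_world)
    p1w <- cc$ref_tvec_world
    obs_rows <- function(marker_id, R_w9, p_w) {
      # pose of marker in camera frame: R = R_cam' R_w, p = R_cam'(p_w - p_cam)
      Rk <- rot_compose_many(R_cam_t, R_w9)
      pk <- rotate_points_many(R_cam_t, p_w - p_cam)
      rv <- rvec_many(Rk)
      data.frame(t = t, marker_id = marker_id,
                 rx = rv[, 1], ry = rv[, 2], rz = rv[, 3],
                 tx = pk[, 1], ty = pk[, 2],
                 tz = pk[, 3] + stats::rnorm(n, 0, cc$tvec_z_noise_sd),
                 depth_m = pk[, 3])
    }
    R1w9 <- matrix(rep(as.numeric(R1w), each = n), n)
    world_pos <- function(pos_ref) {
      sweep(rotate_points_many(R1w9, pos_ref), 2, p1w, "+")
    }
    RLw9 <- matrix(rep(as.numeric(R1w %*% rodrigues(cc$marker_rvec$left)),
                       each = n), n)
    RRw9 <- matrix(rep(as.numeric(R1w %*% rodrigues(cc$marker_rvec$right)),
                       each = n), n)
    markers <- rbind(
      obs_rows(1L, R1w9, matrix(rep(p1w, each = n), n)),
      obs_rows(2L, RLw9, world_pos(left_pos)),
      obs_rows(3L, RRw9, world_pos(right_pos)))
    list(left = trajectory(t, left_pos, "left"),
         right = trajectory(t, right_pos, "right"),
         markers = marker_obs(markers[order(markers$t, markers$marker_id), ]))
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Generate a posture landmark series
#'
#' Right-shoulder and right-elbow image coordinates as baseline plus slow
#' drift plus an oscillation whose amplitude grows with latent stress,
#' with small detection noise. Coordinates are normalised image units.
#'
#' @inheritParams generate_rr
#' @param grid_hz sampling rate (default 10).
#' @param amplitude oscillation amplitude; defaults to the planted
#'   stress-dependent value.
#' @param drift_sd stationary sd of the slow postural drift (0 disables).
#' @param noise_sd detection noise sd (0 disables).
#' @param shoulder_id,elbow_id emitted landmark ids (defaults 12, 14).
#' @return A [landmark_series()].
#' @export
generate_posture <- function(duration_s, s = 0.5, seed = NULL,
                             t0 = 1714600000, grid_hz = 10,
                             amplitude = .cohort_const$posture_amp(s),
                             drift_sd = 0.01,
                             noise_sd = .cohort_const$posture_noise_sd,
                             shoulder_id = 12, elbow_id = 14) {
  cc <- .cohort_const
  gen <- function() {
    n <- as.integer(round(duration_s * grid_hz))
    t <- t0 + (seq_len(n) - 1L) / grid_hz
    one <- function(id, y0) {
      f <- stats::runif(1, 0.15, 0.4)
      ph <- stats::runif(1, 0, 2 * pi)
      drift <- if (drift_sd > 0) .ar1(n, 0.995, drift_sd) else numeric(n)
      y <- y0 + drift + amplitude * sin(2 * pi * f * (t - t0) + ph) +
        stats::rnorm(n, 0, noise_sd)
      x <- 0.5 + (if (drift_sd > 0) .ar1(n, 0.99, drift_sd) else numeric(n)) +
        stats::rnorm(n, 0, noise_sd)
      data.frame(t = t, landmark_id = id, x = x, y = y)
    }
    landmark_series(rbind(one(shoulder_id, cc$posture_y0[["shoulder"]]),
                          one(elbow_id, cc$posture_y0[["elbow"]])))
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

.clip_score <- function(x) pmin(20L, pmax(1L, as.integer(round(x))))

#' Planted correlation structure of the synthetic cohort
#'
#' Direction and strength class of each metric's planted link with the
#' stress index: `strong` links are calibrated to be detectable at the
#' default cohort size, `induced` links arise mechanically from the
#' generator's couplings (ratios of linked quantities, finite-sample
#' envelope effects) without a calibrated strength, and `null` metrics are
#' driven by skill or pure noise, independent of latent stress.
#'
#' @return data.frame with columns `metric`, `planted_sign`
#'   (`"+"`, `"-"`, `""`) and `class` (`strong`/`induced`/`null`).
#' @export
planted_links <- function() {
  strong_pos <- c("Lefthand_std", "Lefthand_range", "Lefthand_total_dist",
                  "Lefthand_avg_speed", "Left_jerk", "Elbow_vy", "Shoulder_vy",
                  "Physical_fatigue", "Distractions")
  strong_neg <- c("Righthand_total_dist", "Righthand_avg_speed", "Right_jerk")
  induced_neg <- c("Total_dist_rate", "Range_rate", "Righthand_std",
                   "Righthand_range")
  data.frame(
    metric = .metric_columns,
    planted_sign = ifelse(.metric_columns %in% strong_pos, "+",
                   ifelse(.metric_columns %in% c(strong_neg, induced_neg),
                          "-", "")),
    class = ifelse(.metric_columns %in% c(strong_pos, strong_neg), "strong",
            ifelse(.metric_columns %in% induced_neg, "induced", "null")),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Produces full trial records — RR series, camera-frame marker
#' observations, posture landmarks with a random clock offset, workload
#' questionnaire responses and manual error counts — for the configured
#' subjects and tasks, truncated to `spec$n_trials`, together with a
#' ground-truth table of the planted latent stress and skill per trial.
#' Generation is fully deterministic in `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with class `synthetic_cohort`: `trials` (list of
#'   [trial_record()]), `truth` (per-trial data.frame with `s` and
#'   `skill`), `links` (the [planted_links()] table) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("novice", "resident", "surgeon")
  skill_of <- c(novice = 0, resident = 0.5, surgeon = 1)
  plan <- expand.grid(task_id = seq_len(spec$tasks_per_subject),
                      subj = seq_len(spec$n_per_group * 3))
  plan <- plan[order(plan$subj, plan$task_id), , drop = FALSE]
  plan <- plan[seq_len(min(spec$n_trials, nrow(plan))), , drop = FALSE]
  .with_seed(spec$seed, {
    trials <- vector("list", nrow(plan))
    truth <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      subj <- plan$subj[i]
      group <- groups[(subj - 1) %/% spec$n_per_group + 1]
      skill <- skill_of[[group]]
      s <- stats::runif(1)
      t0 <- spec$base_epoch + (i - 1) * (spec$duration_s + 60)
      window <- c(t0, t0 + spec$duration_s)
      rr <- generate_rr(spec$duration_s + 2, spec, s, t0 = t0)
      hands <- generate_hand_trajectories(spec$duration_s, spec, s, skill,
                                          t0 = t0)
      posture <- generate_posture(spec$duration_s, s, t0 = t0)
      offset <- stats::runif(1, -20, 20)
      posture$t <- posture$t - offset   # raw video clock; offset re-aligns
      tlx <- surg_tlx(
        mental = .clip_score(6 + 5 * (1 - skill) + stats::rnorm(1, 0, 2.5)),
        physical = .clip_score(1 + 12 * s + stats::rnorm(1, 0, 1.5)),
        temporal = .clip_score(8 + stats::rnorm(1, 0, 3)),
        complexity = .clip_score(5 + 4 * (1 - skill) + stats::rnorm(1, 0, 2.5)),
        situational_stress = .clip_score(6 + stats::rnorm(1, 0, 3)),
        distractions = .clip_score(1 + 10 * s + stats::rnorm(1, 0, 1.5)))
      manual <- list(
        collisions_phantom = stats::rpois(1, 3 * (1 - 0.6 * skill)),
        collision_robot_arms = stats::rpois(1, 1.5 * (1 - 0.6 * skill)),
        rings_placed = stats::rbinom(1, 10, 0.5 + 0.45 * skill),
        ring_drops = stats::rpois(1, 2 * (1 - 0.6 * skill)),
        spike_color_missed = stats::rpois(1, 1 * (1 - 0.6 * skill)))
      trials[[i]] <- trial_record(
        subject_id = sprintf("S%02d", subj), group = group,
        task_id = plan$task_id[i], task_window = window, rr = rr,
        markers = hands$markers, posture = posture,
        posture_offset_s = offset, tlx = tlx, manual = manual)
      truth[[i]] <- data.frame(trial = i, subject_id = sprintf("S%02d", subj),
                               group = group, task_id = plan$task_id[i],
                               s = s, skill = skill)
    }
    structure(list(trials = trials, truth = do.call(rbind, truth),
                   links = planted_links(), spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d trials, %d subjects, seed %d\n",
              length(x$trials), length(unique(x$truth$subject_id)),
              x$spec$seed))
  invisible(x)
}
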