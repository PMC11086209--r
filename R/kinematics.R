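#' Marker observation table
#'
#' Validates a table of fiducial-marker detections. Each row is one
#' detection of one marker in one video frame: an axis-angle rotation
#' vector, a translation in the camera frame, and optionally the RGB-D
#' depth reading at the marker centre. Marker id 1 is by convention the
#' fixed reference marker on the console armrest; ids 2 and 3 are the
#' markers on the left and right hand controllers.
#'
#' @param df data.frame with columns `t`, `marker_id`, `rx`, `ry`, `rz`,
#'   `tx`, `ty`, `tz` and optionally `depth_m` (NA where no depth reading
#'   is available).
#' @return The validated data.frame with class `marker_obs`.
#' @export
marker_obs <- function(df) {
  need <- c("t", "marker_id", "rx", "ry", "rz", "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    stop("marker observations need columns: ", paste(need, collapse = ", "))
  if (!"depth_m" %in% names(df)) df$depth_m <- NA_real_
  ang <- sqrt(df$rx^2 + df$ry^2 + df$rz^2)
  if (any(ang >= 2 * pi))
    stop("axis-angle norms must be below 2*pi")
  if (any(!is.na(df$depth_m) & df$depth_m <= 0))
    stop("depth readings must be positive")
  class(df) <- c("marker_obs", "data.frame")
  df
}

#' Read marker observations from CSV
#'
#' Expects a header `t_unix,marker_id,rx,ry,rz,tx,ty,tz,depth_m`
#' (axis-angle dialect of ArUco-style detectors; `depth_m` may be empty).
#'
#' @param path path to the CSV file.
#' @return A [marker_obs()] table.
#' @export
read_marker_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d)[names(d) == "t_unix"] <- "t"
  marker_obs(d)
}

#' Substitute RGB-D depth into marker translations
#'
#' The z component of a marker translation estimated from the printed
#' marker size is noisier than the depth channel of an RGB-D camera, so
#' where a depth reading is present it replaces the z component of `tvec`.
#' Rows without a depth reading are left unchanged.
#'
#' @param obs a [marker_obs()] table.
#' @return The table with depth substituted into `tz`.
#' @export
substitute_depth <- function(obs) {
  stopifnot(inherits(obs, "marker_obs"))
  has <- !is.na(obs$depth_m)
  obs$tz[has] <- obs$depth_m[has]
  obs
}

#' Hand trajectory in the reference-marker frame
#'
#' @param t numeric, strictly increasing timestamps (seconds).
#' @param pos n x 3 matrix of positions in metres.
#' @param hand `"left"` or `"right"`.
#' @param n_dropped number of frames dropped because either marker was
#'   missing.
#' @return A data.frame `t,x,y,z` with class `trajectory` and attributes
#'   `hand` and `n_dropped`.
#' @export
trajectory <- function(t, pos, hand = c("left", "right"), n_dropped = 0L) {
  hand <- match.arg(hand)
  pos <- matrix(pos, ncol = 3)
  if (length(t) != nrow(pos)) stop("`t` and `pos` lengths differ")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("trajectory timestamps must be strictly increasing")
  out <- data.frame(t = as.numeric(t), x = pos[, 1], y = pos[, 2], z = pos[, 3])
  structure(out, class = c("trajectory", "data.frame"),
            hand = hand, n_dropped = as.integer(n_dropped))
}

#' Build a hand trajectory from marker observations
#'
#' For every frame in which both the fixed reference marker and the
#' requested hand marker were detected, the hand marker's (depth-substituted)
#' pose is rebased into the reference-marker frame and its translation
#' retained — marker placement on the hand controllers discards orientation
#' by design. Frames missing either marker are dropped and counted in the
#' `n_dropped` attribute. Camera motion cancels in the rebasing, so the
#' returned trajectory lives in a frame rigidly attached to the console.
#'
#' @param obs a [marker_obs()] table covering one trial.
#' @param hand `"left"` or `"right"`.
#' @param reference_id marker id of the fixed reference (default 1).
#' @param hand_ids named ids of the moving markers
#'   (default `c(left = 2, right = 3)`).
#' @return A [trajectory()].
#' @export
build_trajectory <- function(obs, hand = c("left", "right"), reference_id = 1,
                             hand_ids = c(left = 2, right = 3)) {
  hand <- match.arg(hand)
  obs <- substitute_depth(marker_obs(as.data.frame(obs)))
  ref <- obs[obs$marker_id == reference_id, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference marker never observed")
  mov <- obs[obs$marker_id == hand_ids[[hand]], , drop = FALSE]
  frames <- sort(unique(c(ref$t, mov$t)))
  i_ref <- match(frames, ref$t)
  i_mov <- match(frames, mov$t)
  ok <- !is.na(i_ref) & !is.na(i_mov)
  n_dropped <- sum(!ok)
  if (!any(ok))
    return(trajectory(numeric(0), matrix(0, 0, 3), hand, n_dropped))
  ref <- ref[i_ref[ok], , drop = FALSE]
  mov <- mov[i_mov[ok], , drop = FALSE]
  R1 <- rodrigues_many(cbind(ref$rx, ref$ry, ref$rz))
  d <- cbind(mov$tx - ref$tx, mov$ty - ref$ty, mov$tz - ref$tz)
  pos <- rotate_points_many(rot_transpose_many(R1), d)
  trajectory(frames[ok], pos, hand, n_dropped)
}

#' Kinematic summary of a hand trajectory
#'
#' Reduces a trajectory to the hand-movement metrics used in the per-trial
#' metric table:
#' \describe{
#'   \item{std3d_m}{3D spatial standard deviation,
#'     `sqrt(var_x + var_y + var_z)` with population variances.}
#'   \item{range_m}{bounding-box diagonal: Euclidean norm of the per-axis
#'     extents (the extents themselves are returned as `extent_m`).}
#'   \item{total_dist_m}{summed Euclidean step lengths (path length).}
#'   \item{avg_speed_mps}{path length divided by elapsed time.}
#'   \item{jerk_mps3}{mean norm of the third time derivative of position,
#'     estimated by a third-order central finite difference on a regular
#'     grid after gap-aware linear interpolation: the trajectory is split
#'     at detection gaps longer than `max_gap_s`, each segment with at
#'     least five grid samples is differenced on its own, and segment means
#'     are combined weighted by segment duration.}
#' }
#'
#' @param traj a [trajectory()] with at least 2 samples (5 per usable
#'   segment for jerk).
#' @param grid_hz resampling rate for the jerk grid (default 10, the
#'   marker-tracking rate).
#' @param max_gap_s detection gaps longer than this are not interpolated
#'   across (default 0.5 s).
#' @return An object of class `kinematic_summary`: a list with fields
#'   `std3d_m`, `range_m`, `total_dist_m`, `avg_speed_mps`, `jerk_mps3`,
#'   `extent_m`, `n_samples`.
#' @export
kinematic_summary <- function(traj, grid_hz = 10, max_gap_s = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 2L) stop("too few samples for kinematic summary (need >= 2)")
  P <- as.matrix(traj[, c("x", "y", "z")])
  varp <- colMeans(sweep(P, 2, colMeans(P))^2)  # population variances
  ext <- apply(P, 2, function(v) max(v) - min(v))
  steps <- sqrt(rowSums(diff(P)^2))
  total <- sum(steps)
  speed <- total / (traj$t[n] - traj$t[1])
  structure(
    list(std3d_m = sqrt(sum(varp)),
         range_m = sqrt(sum(ext^2)),
         total_dist_m = total,
         avg_speed_mps = speed,
         jerk_mps3 = .mean_jerk(traj$t, P, grid_hz, max_gap_s),
         extent_m = unname(ext),
         n_samples = n),
    class = "kinematic_summary"
  )
}

# duration-weighted mean jerk norm across interpolated gap-free segments
.mean_jerk <- function(t, P, grid_hz, max_gap_s) {
  seg_id <- cumsum(c(0, diff(t) > max_gap_s))
  dt <- 1 / grid_hz
  num <- 0; den <- 0; usable <- FALSE
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 2L) next
    tg <- seq(t[idx[1]], t[idx[length(idx)]], by = dt)
    if (length(tg) < 5L) next
    usable <- TRUE
    G <- vapply(1:3, function(j) stats::approx(t[idx], P[idx, j], xout = tg)$y,
                numeric(length(tg)))
    m <- length(tg)
    i <- 3:(m - 2)
    # third-order central difference: (x[i+2] - 2x[i+1] + 2x[i-1] - x[i-2]) / (2 dt^3)
    D3 <- (G[i + 2, , drop = FALSE] - 2 * G[i + 1, , drop = FALSE] +
             2 * G[i - 1, , drop = FALSE] - G[i - 2, , drop = FALSE]) / (2 * dt^3)
    jnorm <- sqrt(rowSums(D3^2))
    w <- tg[m] - tg[1]
    num <- num + mean(jnorm) * w
    den <- den + w
  }
  if (!usable)
    stop("too few samples for jerk (need >= 5 grid samples in some gap-free segment)")
  num / den
}

#' Bimanuality ratios
#'
#' Dominant-to-non-dominant ratios of path length and bounding-box size.
#' All study subjects were right-handed, so the dominant hand defaults to
#' the right; the argument makes the convention explicit and overridable.
#'
#' @param right,left `kinematic_summary` objects for the two hands.
#' @param dominant which hand is dominant (default `"right"`).
#' @return A list with `total_dist_rate` and `range_rate`.
#' @export
bimanuality_ratios <- function(right, left, dominant = c("right", "left")) {
  dominant <- match.arg(dominant)
  dom <- if (dominant == "right") right else left
  nd  <- if (dominant == "right") left else right
  if (nd$total_dist_m <= 0 || nd$range_m <= 0)
    stop("undefined ratio: non-dominant hand metric is zero")
  list(total_dist_rate = dom$total_dist_m / nd$total_dist_m,
       range_rate = dom$range_m / nd$range_m)
}
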