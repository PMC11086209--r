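test_that("depth substitution replaces only the z component where depth exists", {
  obs <- marker_obs(data.frame(t = c(1, 2, 3), marker_id = 1,
                               rx = 0, ry = 0, rz = 0,
                               tx = 0.1, ty = 0.2, tz = c(0.50, 0.50, 0.48),
                               depth_m = c(0.48, NA, 0.48)))
  out <- substitute_depth(obs)
  expect_equal(out$tz, c(0.48, 0.50, 0.48))
  expect_equal(out$tx, obs$tx)
  expect_equal(out$ty, obs$ty)
})

test_that("axis-angle conversion matches the quaternion oracle", {
  expect_equal(to_homogeneous(c(0, 0, 0), c(1, 2, 3))$R, diag(3))
  R <- to_homogeneous(c(0, 0, pi / 2), c(0, 0, 0))$R
  expect_equal(drop(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    rv <- stats::rnorm(3)
    rv <- rv / sqrt(sum(rv^2)) * stats::runif(1, 0, pi - 1e-3)
    expect_lt(max(abs(rodrigues(rv) - oracle_rotation(rv))), 1e-9)
    # round trip back to axis-angle
    expect_equal(rotation_to_rvec(rodrigues(rv)), rv, tolerance = 1e-9)
  }
  expect_error(to_homogeneous(c(0, 0, Inf), c(0, 0, 0)), "finite")
})

test_that("rebasing inverts the reference pose", {
  set.seed(17)
  h <- random_transform()
  id <- rebase(h, h)
  expect_equal(id$R, diag(3), tolerance = 1e-12)
  expect_equal(id$p, c(0, 0, 0), tolerance = 1e-12)
  ident <- to_homogeneous(c(0, 0, 0), c(0, 0, 0))
  expect_equal(rebase(ident, h)$R, h$R)
  expect_equal(rebase(ident, h)$p, h$p)
  for (i in 1:20) {
    h_ref <- random_transform(); h_k <- random_transform()
    back <- compose_transform(h_ref, rebase(h_ref, h_k))
    expect_lt(max(abs(back$R - h_k$R)), 1e-9)
    expect_lt(max(abs(back$p - h_k$p)), 1e-9)
  }
})

test_that("vectorised rotation helpers agree with the scalar API", {
  set.seed(41)
  rv <- matrix(stats::rnorm(60), ncol = 3) * 0.8
  R9 <- surgstress:::rodrigues_many(rv)
  for (i in seq_len(nrow(rv))) {
    expect_lt(max(abs(matrix(R9[i, ], 3, 3) - rodrigues(rv[i, ]))), 1e-12)
  }
  back <- surgstress:::rvec_many(R9)
  expect_equal(back, rv, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("trajectory reconstruction cancels camera motion", {
  # a moving marker rigidly fixed relative to the reference stays constant
  # in the rebased frame however the camera moves
  set.seed(53)
  n <- 40
  t <- (seq_len(n) - 1) / 10
  rel <- to_homogeneous(c(0.2, -0.1, 0.3), c(0.05, -0.02, 0.1))
  rows <- lapply(seq_len(n), function(i) {
    cam <- random_transform()  # camera pose changes every frame
    h1 <- cam
    h2 <- compose_transform(cam, rel)
    data.frame(t = rep(t[i], 2), marker_id = c(1, 2),
               rx = c(rotation_to_rvec(h1$R)[1], rotation_to_rvec(h2$R)[1]),
               ry = c(rotation_to_rvec(h1$R)[2], rotation_to_rvec(h2$R)[2]),
               rz = c(rotation_to_rvec(h1$R)[3], rotation_to_rvec(h2$R)[3]),
               tx = c(h1$p[1], h2$p[1]), ty = c(h1$p[2], h2$p[2]),
               tz = c(h1$p[3], h2$p[3]), depth_m = NA_real_)
  })
  traj <- build_trajectory(marker_obs(do.call(rbind, rows)), "left")
  expect_equal(nrow(traj), n)
  P <- as.matrix(traj[, c("x", "y", "z")])
  expect_lt(max(abs(sweep(P, 2, rel$p))), 1e-9)
})

test_that("frames missing a marker are dropped and counted", {
  base <- data.frame(t = c(1, 1, 2, 3), marker_id = c(1, 2, 1, 2),
                     rx = 0, ry = 0, rz = 0, tx = 0, ty = 0,
                     tz = c(1, 2, 1, 2), depth_m = NA_real_)
  traj <- build_trajectory(marker_obs(base), "left")
  expect_equal(nrow(traj), 1L)          # only t = 1 has both markers
  expect_equal(attr(traj, "n_dropped"), 2L)
  only_ref <- marker_obs(base[base$marker_id == 1, ])
  empty <- build_trajectory(only_ref, "left")
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_dropped"), 2L)
  expect_error(build_trajectory(marker_obs(base[base$marker_id == 2, ]), "left"),
               "reference marker")
})

test_that("kinematic summary matches closed forms", {
  t <- (0:10) / 10
  stationary <- trajectory(t, matrix(rep(c(1, 2, 3), each = 11), ncol = 3), "left")
  ks <- kinematic_summary(stationary)
  expect_equal(ks$std3d_m, 0)
  expect_equal(ks$range_m, 0)
  expect_equal(ks$total_dist_m, 0)
  expect_equal(ks$avg_speed_mps, 0)
  expect_equal(ks$jerk_mps3, 0)

  line <- trajectory(t, cbind(0.1 * (0:10), 0, 0), "right")
  kl <- kinematic_summary(line)
  expect_equal(kl$total_dist_m, 1)
  expect_equal(kl$avg_speed_mps, 1)
  expect_equal(kl$jerk_mps3, 0, tolerance = 1e-9)

  corners <- trajectory((0:7) / 10,
                        rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                              c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
                        "left")
  expect_equal(kinematic_summary(corners)$range_m, sqrt(3))
  expect_error(kinematic_summary(trajectory(0, cbind(0, 0, 0), "left")),
               "too few samples")
})

test_that("kinematic metrics scale with the trajectory and ignore time order", {
  set.seed(67)
  n <- 50
  P <- apply(matrix(stats::rnorm(3 * n, 0, 0.02), ncol = 3), 2, cumsum)
  t <- (seq_len(n) - 1) / 10
  k1 <- kinematic_summary(trajectory(t, P, "left"))
  k3 <- kinematic_summary(trajectory(t, 3 * P, "left"))
  for (f in c("std3d_m", "range_m", "total_dist_m", "avg_speed_mps", "jerk_mps3")) {
    expect_equal(k3[[f]], 3 * k1[[f]], tolerance = 1e-9)
  }
  krev <- kinematic_summary(trajectory(t, P[n:1, ], "left"))
  expect_equal(krev$total_dist_m, k1$total_dist_m)
  expect_equal(krev$std3d_m, k1$std3d_m)
  expect_equal(krev$range_m, k1$range_m)
})

test_that("bimanuality ratios divide dominant by non-dominant metrics", {
  t <- (0:10) / 10
  mk <- function(step) kinematic_summary(trajectory(t, cbind(step * (0:10), 0, 0), "left"))
  same <- bimanuality_ratios(mk(0.1), mk(0.1))
  expect_equal(same$total_dist_rate, 1)
  expect_equal(same$range_rate, 1)
  r <- bimanuality_ratios(mk(0.17), mk(0.1))
  expect_equal(r$total_dist_rate, 1.7)
  zero <- kinematic_summary(trajectory(t, matrix(0, 11, 3), "left"))
  expect_error(bimanuality_ratios(mk(0.1), zero), "undefined ratio")
})
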