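# Independent oracles, deliberately naive and separate from the package's
# implementation paths.

# literal histogram evaluation of the stress index
oracle_bsi <- function(rr_ms, bin_ms = 50) {
  b <- floor(rr_ms / bin_ms + 0.5) * bin_ms
  tab <- table(b)
  mo <- min(as.numeric(names(tab))[tab == max(tab)]) / 1000
  amo <- 100 * max(tab) / length(b)
  rng <- (max(b) - min(b)) / 1000
  list(mo_s = mo, amo_pct = amo, mxdmn_s = rng, si = amo / (2 * mo * rng))
}

# rotation matrix built from a unit quaternion (axis-angle -> quaternion)
oracle_rotation <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th == 0) return(diag(3))
  ax <- rvec / th
  q <- c(cos(th / 2), sin(th / 2) * ax)  # (w, x, y, z)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# direct-formula Pearson r and two-sided t-distribution p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# O(N^2) template-counting approximate entropy (Chebyshev, self-matches)
oracle_apen <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  phi <- function(m) {
    n <- length(x) - m + 1
    emb <- sapply(seq_len(m), function(k) x[k:(k + n - 1)])
    emb <- matrix(emb, nrow = n)
    cnt <- vapply(seq_len(n), function(i) {
      d <- abs(sweep(emb, 2, emb[i, ]))
      sum(apply(d, 1, max) <= r)
    }, numeric(1))
    mean(log(cnt / n))
  }
  phi(m) - phi(m + 1)
}

# random rigid transform for composition tests
random_transform <- function() {
  rv <- stats::runif(3, -1, 1)
  rv <- rv / sqrt(sum(rv^2)) * stats::runif(1, 0, pi - 0.1)
  to_homogeneous(rv, stats::rnorm(3, 0, 0.5))
}

# small fully hand-checkable trial: straight-line hands, ramping posture
make_simple_trial <- function(n = 120, t0 = 0) {
  t <- t0 + (seq_len(n) - 1) / 10
  line <- function(step, centre) {
    cbind(centre[1] + step * (seq_len(n) - 1), centre[2], centre[3])
  }
  left <- trajectory(t, line(0.01, c(-0.1, 0, 0.4)), "left")
  right <- trajectory(t, line(0.017, c(0.1, 0, 0.4)), "right")
  rr <- rr_series(t0 + cumsum(rep(0.8, 70)) - 0.8 + 0.01,
                  rep(c(800, 850), 35))
  posture <- landmark_series(data.frame(
    t = rep(t, 2), landmark_id = rep(c(12, 14), each = n),
    x = 0.5, y = c(0.3 + 0.001 * (seq_len(n) - 1),
                   0.5 + 0.002 * (seq_len(n) - 1))))
  trial_record(subject_id = "S01", group = "novice", task_id = 1,
               task_window = c(t0, t0 + n / 10), rr = rr,
               left = left, right = right, posture = posture,
               tlx = surg_tlx(5, 6, 7, 8, 9, 10),
               manual = list(collisions_phantom = 1, collision_robot_arms = 0,
                             rings_placed = 8, ring_drops = 2,
                             spike_color_missed = 0))
}
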