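test_that("synchronization leaves already-gridded streams unchanged and interpolates offsets", {
  tr <- make_simple_trial()
  syn <- synchronize(tr)
  expect_equal(syn$left$x, tr$left$x)
  expect_equal(syn$right$z, tr$right$z)
  # stream offset by half a sample interpolates to midpoints
  off <- tr
  off$left <- trajectory(tr$left$t + 0.05,
                         as.matrix(tr$left[, c("x", "y", "z")]), "left")
  syn_off <- synchronize(off)
  keep <- syn_off$left$t
  expected <- stats::approx(off$left$t, off$left$x, xout = keep)$y
  expect_equal(syn_off$left$x, expected)
  mids <- (tr$left$x[-1] + tr$left$x[-nrow(tr$left)]) / 2
  expect_equal(syn_off$left$x, mids[seq_along(syn_off$left$x)])
})

test_that("synchronization names the stream that misses the window", {
  tr <- make_simple_trial()
  tr$posture$t <- tr$posture$t - 1000
  expect_error(synchronize(tr), "posture")
  tr2 <- make_simple_trial()
  tr2$left$t <- tr2$left$t + 1000
  expect_error(synchronize(tr2), "left trajectory")
})

test_that("pearson_with_p matches the direct-formula oracle", {
  expect_equal(pearson_with_p(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  got <- pearson_with_p(x, y)
  want <- oracle_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$n, 5L)
  set.seed(13)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:40, 1)); y <- stats::rnorm(length(x))
    got <- pearson_with_p(x, y); want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_p(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")
})

test_that("pearson is affine-invariant and sign-flips under negation", {
  set.seed(29)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  r0 <- pearson_with_p(x, y)$r
  expect_equal(pearson_with_p(3 * x + 2, y)$r, r0)
  expect_equal(pearson_with_p(x, 0.1 * y - 7)$r, r0)
  expect_equal(pearson_with_p(-x, y)$r, -r0)
})

test_that("significance tiers follow the p-value bands including boundaries", {
  expect_equal(significance_tier(0.006), "strong")
  expect_equal(significance_tier(0.061), "weak")
  expect_equal(significance_tier(0.5), "none")
  expect_equal(significance_tier(c(0.05, 0.08, 0.0801)),
               c("weak", "weak", "none"))
  expect_error(significance_tier(1.2))
})

test_that("the metric table row of a hand-computable trial matches module-level results", {
  tr <- make_simple_trial()
  tab <- build_metric_table(list(tr, make_simple_trial(t0 = 100),
                                 make_simple_trial(t0 = 200)))
  expect_s3_class(tab, "metric_table")
  expect_equal(nrow(tab), 3L)
  expect_setequal(setdiff(colnames(tab),
                          c("trial", "subject_id", "group", "task_id", "BSI")),
                  metric_columns())
  row <- tab[1, ]
  expect_equal(row$BSI, per_task_bsi(tr$rr, tr$task_window)$si)
  kl <- kinematic_summary(tr$left)
  kr <- kinematic_summary(tr$right)
  expect_equal(row$Lefthand_total_dist, kl$total_dist_m)
  expect_equal(row$Righthand_avg_speed, kr$avg_speed_mps)
  expect_equal(row$Total_dist_rate, kr$total_dist_m / kl$total_dist_m,
               tolerance = 1e-12)
  ps <- posture_summary(tr$posture, tr$task_window)
  expect_equal(row$Elbow_vy, ps$elbow_vy)
  expect_equal(row$Shoulder_vy, ps$shoulder_vy)
  expect_equal(row$Physical_fatigue, 6)
  expect_equal(row$Ring_drops, 2)
})

test_that("degenerate metrics are flagged as missing, not zero-filled", {
  trials <- list(make_simple_trial(), make_simple_trial(t0 = 100),
                 make_simple_trial(t0 = 200))
  trials[[2]]$posture <- NULL
  trials[[3]]$rr <- rr_series(trials[[3]]$task_window[1] +
                                cumsum(rep(0.8, 30)),
                              rep(800, 30))  # constant heart rate
  tab <- build_metric_table(trials)
  expect_true(is.na(tab$Elbow_vy[2]))
  expect_false(is.na(tab$Elbow_vy[1]))
  expect_true(is.na(tab$BSI[3]))
  expect_error(build_metric_table(trials[1:2]), "at least 3")
})

test_that("correlation report recovers exact relationships and is deterministic", {
  set.seed(47)
  n <- 30
  tab <- build_metric_table(lapply(seq_len(n) - 1,
                                   function(i) make_simple_trial(t0 = 100 * i)))
  tab$BSI <- stats::rnorm(n, 100, 20)
  for (m in metric_columns()) tab[[m]] <- stats::rnorm(n)
  tab$Lefthand_std <- tab$BSI
  tab$Righthand_std <- -tab$BSI + stats::rnorm(n, 0, 1e-8)
  tab$Elbow_vy <- NA_real_
  rep1 <- correlation_report(tab)
  expect_s3_class(rep1, "correlation_report")
  expect_equal(rep1$metric, metric_columns())
  ls <- rep1[rep1$metric == "Lefthand_std", ]
  expect_equal(ls$r, 1)
  expect_equal(ls$tier, "strong")
  expect_equal(ls$sign, "+")
  rs <- rep1[rep1$metric == "Righthand_std", ]
  expect_lt(rs$r, -0.999)
  expect_equal(rs$tier, "strong")
  expect_equal(rs$sign, "-")
  expect_equal(rep1[rep1$metric == "Elbow_vy", "tier"], "insufficient data")
  expect_identical(rep1, correlation_report(tab))
})
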