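test_that("target binarization uses the mean-threshold rule with ties to expert", {
  expect_equal(binarize_target(c(4, 10, 16)), c(0L, 0L, 1L))
  expect_equal(binarize_target(c(1, 20)), c(0L, 1L))
  expect_warning(out <- binarize_target(c(5, 5, 5)), "degenerate")
  expect_equal(out, c(0L, 0L, 0L))
  expect_error(binarize_target(7), "at least 2")
})

test_that("approximate entropy matches the template-counting oracle", {
  expect_equal(approx_entropy(rep(3.5, 50)), 0)
  set.seed(71)
  for (i in 1:8) {
    x <- stats::rnorm(200)
    expect_equal(approx_entropy(x), oracle_apen(x), tolerance = 1e-10)
  }
  expect_error(approx_entropy(c(1, 2, 3), m = 2), "too short")
})

test_that("approximate entropy ranks periodic below random and is shift-invariant", {
  set.seed(73)
  wins <- sum(sapply(1:25, function(i) {
    per <- rep(c(0, 1), 50) + stats::rnorm(100, 0, 1e-6)
    approx_entropy(per) < approx_entropy(stats::runif(100))
  }))
  expect_gte(wins, 24)
  x <- stats::rnorm(150)
  expect_equal(approx_entropy(x + 100), approx_entropy(x))
})

test_that("approximate entropy agrees with the pracma implementation", {
  skip_if_not_installed("pracma")
  set.seed(79)
  x <- stats::rnorm(150)
  expect_equal(approx_entropy(x),
               pracma::approx_entropy(x, edim = 2, r = 0.2 * stats::sd(x)),
               tolerance = 1e-8)
})

test_that("tuning grids enumerate the protocol parameter lists", {
  dt <- classifier_grid("dt")
  expect_equal(nrow(dt$params), 616L)
  expect_setequal(unique(dt$params$criterion), c("gini", "entropy"))
  expect_equal(length(unique(dt$params$max_depth)), 11L)
  expect_equal(length(unique(dt$params$max_features)), 14L)
  svm <- classifier_grid("svm")
  expect_equal(nrow(svm$params), 396L)
  expect_setequal(unique(svm$params$kernel),
                  c("poly", "rbf", "sigmoid", "linear"))
  expect_equal(length(unique(svm$params$gamma)), 11L)
  lr <- classifier_grid("lr")
  expect_equal(nrow(lr$params), 63L)
  pairs <- unique(lr$params[, c("solver", "penalty")])
  expect_equal(nrow(pairs), 7L)
  expect_setequal(pairs$penalty[pairs$solver == "lbfgs"], "l2")
  expect_setequal(pairs$penalty[pairs$solver == "saga"], c("l1", "l2"))
  knn <- classifier_grid("knn", n_neighbors_max = 9)
  expect_equal(nrow(knn$params), 9L * 2L * 3L)
})

test_that("the decision tree separates separable data and honours max_depth", {
  set.seed(83)
  X <- rbind(matrix(stats::rnorm(40, 0), ncol = 2),
             matrix(stats::rnorm(40, 5), ncol = 2))
  y <- rep(c(0L, 1L), each = 20)
  fit <- fit_dtree(X, y)
  expect_equal(predict(fit, X), y)
  stump <- fit_dtree(X, y, max_depth = 1)
  expect_true(stump$root$leaf == FALSE &&
                stump$root$left$leaf && stump$root$right$leaf)
  # entropy criterion and random splitter still classify separable data
  fit2 <- fit_dtree(X, y, criterion = "entropy", splitter = "random",
                    max_features = "sqrt")
  expect_gt(mean(predict(fit2, X) == y), 0.9)
})

test_that("k-NN prediction respects metric and weighting choices", {
  X <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  y <- c(0L, 0L, 1L, 1L)
  expect_equal(predict_knn(X, y, rbind(c(0.4, 0), c(10.4, 0)), k = 1),
               c(0L, 1L))
  # manhattan penalises the diagonal neighbour that euclidean prefers
  Xt <- rbind(c(1.2, 0), c(0.8, 0.8))
  yt <- c(1L, 0L)
  q <- rbind(c(0, 0))
  expect_equal(predict_knn(Xt, yt, q, k = 1, metric = "euclidean"), 0L)
  expect_equal(predict_knn(Xt, yt, q, k = 1, metric = "manhattan"), 1L)
  expect_equal(predict_knn(Xt, yt, q, k = 1, metric = "minkowski"), 0L)
  # inverse-distance weighting lets one very close neighbour dominate
  Xw <- rbind(c(0, 0), c(3, 0), c(3.2, 0))
  yw <- c(0L, 1L, 1L)
  q2 <- rbind(c(0.2, 0))
  expect_equal(predict_knn(Xw, yw, q2, k = 3, weights = "uniform"), 1L)
  expect_equal(predict_knn(Xw, yw, q2, k = 3, weights = "distance"), 0L)
  expect_error(predict_knn(Xw, yw, q2, k = 5), "exceeds")
})

test_that("fold assignment is stratified, deterministic and seed-sensitive", {
  y <- rep(c(0L, 1L), c(12, 8))
  f <- make_folds(y, 4, seed = 1)
  expect_equal(sort(unique(f)), 1:4)
  expect_true(max(tabulate(f)) - min(tabulate(f)) <= 1)
  for (k in 1:4) expect_equal(sum(y[f == k] == 1), 2)
  expect_identical(f, make_folds(y, 4, seed = 1))
  expect_false(identical(f, make_folds(y, 4, seed = 2)))
  expect_identical(make_folds(y, length(y)), seq_along(y))
  expect_error(make_folds(y, 1), "2..n")
})

test_that("grid search scores LOOCV identically to n-fold CV and finds separable data", {
  set.seed(89)
  X <- rbind(matrix(stats::rnorm(22, 0, 0.3), ncol = 2),
             matrix(stats::rnorm(22, 4, 0.3), ncol = 2))
  y <- rep(c(0L, 1L), each = 11)
  g <- classifier_grid("knn", n_neighbors_max = 5)
  loo <- grid_search(X, y, g, scheme = "loocv")
  nfold <- grid_search(X, y, g, scheme = nrow(X))
  expect_equal(loo$accuracy, nfold$accuracy)
  expect_equal(loo$accuracies, nfold$accuracies)
  expect_equal(loo$accuracy, 1)
  small_dt <- classifier_grid("dt")
  small_dt$params <- small_dt$params[small_dt$params$splitter == "best" &
                                       small_dt$params$max_features == "None", ]
  res <- grid_search(X, y, small_dt, scheme = "loocv")
  expect_equal(res$accuracy, 1)
  expect_error(grid_search(X, rep(0L, 22), g), "single-class")
  expect_error(grid_search(X, y, g, scheme = 23), "exceeds")
})

test_that("all four classifiers run through the grid search deterministically", {
  set.seed(97)
  X <- rbind(matrix(stats::rnorm(36, 0, 1), ncol = 3),
             matrix(stats::rnorm(36, 2.5, 1), ncol = 3))
  y <- rep(c(0L, 1L), each = 12)
  for (cl in c("svm", "lr")) {
    g <- classifier_grid(cl)
    g$params <- g$params[seq(1, nrow(g$params), by = 7), , drop = FALSE]
    r1 <- grid_search(X, y, g, scheme = 6)
    r2 <- grid_search(X, y, g, scheme = 6)
    expect_identical(r1$accuracies, r2$accuracies)
    expect_gte(r1$accuracy, 0.7)
    expect_true(r1$accuracy >= 0 && r1$accuracy <= 1)
  }
})

test_that("skill reports have the accuracy-table shape", {
  set.seed(101)
  n <- 16
  X <- cbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
  tlx <- data.frame(Mental_fatigue = sample(1:20, n, TRUE),
                    Physical_fatigue = sample(1:20, n, TRUE),
                    Temporal_demands = sample(1:20, n, TRUE),
                    Complexity = sample(1:20, n, TRUE),
                    Situational_stress = sample(1:20, n, TRUE),
                    Distractions = sample(1:20, n, TRUE))
  grids <- list(dt = local({
    g <- classifier_grid("dt")
    g$params <- g$params[c(1, 100, 300), ]; g
  }))
  rep <- classify_cohort(X, tlx, classifiers = c("dt", "knn"),
                         schemes = list("loocv", 4), grids = grids)
  expect_s3_class(rep, "skill_report")
  expect_equal(nrow(rep), 12L)
  expect_setequal(unique(rep$question),
                  c("MF", "PF", "TD", "C", "SS", "D"))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  m <- format_accuracy_matrix(rep)
  expect_equal(dim(m), c(6L, 2L))
  expect_match(m[1, 1], "^(LOOCV|cv = \\d+):\\d\\.\\d{6}$")
})
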