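#' Binarize workload responses into skill classes
#'
#' Transforms one questionnaire dimension's responses (integers 1..20)
#' into binary classification targets: a response below the mean of the
#' responses becomes 0 (expert class), above the mean becomes 1 (novice
#' class). A response exactly at the mean is assigned to the expert class,
#' keeping the rule total. All-identical responses produce a single-class
#' target and a warning.
#'
#' @param scores integer vector of responses, length >= 2.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_target <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (length(unique(scores)) == 1L)
    warning("degenerate target: all responses identical, single class")
  as.integer(scores > mean(scores))
}

#' Stratified cross-validation folds
#'
#' Deterministic fold assignment: within each class, indices are shuffled
#' under the given seed and dealt into the folds, so fold sizes differ by
#' at most one and class balance is preserved as far as possible.
#' LOOCV is k-fold with `k = length(y)`.
#'
#' @param y 0/1 label vector.
#' @param k number of folds, 2..`length(y)`.
#' @param seed RNG seed for the shuffle (default 7919).
#' @return Integer vector of fold ids in 1..k.
#' @export
make_folds <- function(y, k, seed = 7919) {
  n <- length(y)
  if (k < 2L || k > n) stop("k must lie in 2..n")
  if (k == n) return(seq_len(n))
  fold <- integer(n)
  .with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Exhaustive grid search under cross-validation
#'
#' Evaluates every parameter combination of a [classifier_grid()] by
#' cross-validation and returns the best one. The score of a combination
#' is the mean over folds of the out-of-fold accuracy (for LOOCV this is
#' the pooled leave-one-out accuracy); `aggregate = "best_fold"` instead
#' scores a combination by its best single fold. Fold assignment and the
#' random-splitter/solver internals are seeded, so results are
#' deterministic. Ties go to the earlier combination in grid order.
#'
#' @param features numeric matrix, one row per trial.
#' @param target integer 0/1 vector.
#' @param grid a `grid_spec` from [classifier_grid()].
#' @param scheme `"loocv"` or an integer number of folds k.
#' @param seed RNG seed (default 7919).
#' @param aggregate `"mean"` (default) or `"best_fold"`.
#' @return An object of class `cv_result`: list with `classifier`,
#'   `scheme`, `k`, `best_params` (one-row data.frame), `accuracy`, and
#'   `accuracies` (per-combination scores).
#' @export
grid_search <- function(features, target, grid, scheme = "loocv",
                        seed = 7919, aggregate = c("mean", "best_fold")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(grid, "grid_spec"))
  X <- as.matrix(features)
  y <- as.integer(target)
  n <- nrow(X)
  if (length(unique(y)) < 2L) stop("single-class target: nothing to classify")
  k <- if (identical(scheme, "loocv")) n else as.integer(scheme)
  if (k > n) stop("k exceeds the number of trials")
  fold <- make_folds(y, k, seed)
  params <- grid$params
  if (grid$classifier == "knn") {
    min_train <- n - max(tabulate(fold, k))
    params <- params[params$n_neighbors <= min_train, , drop = FALSE]
    if (nrow(params) == 0L) stop("no valid kNN neighbour counts for this scheme")
  }
  test_sets <- split(seq_len(n), fold)
  scores <- vapply(seq_len(nrow(params)), function(i) {
    pr <- params[i, , drop = FALSE]
    acc <- vapply(test_sets, function(te) {
      tr <- setdiff(seq_len(n), te)
      pred <- .with_seed(seed + i, tryCatch(
        .fit_predict(grid$classifier, pr, X[tr, , drop = FALSE], y[tr],
                     X[te, , drop = FALSE]),
        error = function(e) rep(.majority(y[tr]), length(te))))
      mean(pred == y[te])
    }, numeric(1))
    if (aggregate == "mean") mean(acc) else max(acc)
  }, numeric(1))
  best <- which.max(scores)
  structure(list(classifier = grid$classifier,
                 scheme = if (k == n) "LOOCV" else sprintf("cv = %d", k),
                 k = k,
                 best_params = params[best, , drop = FALSE],
                 accuracy = scores[best],
                 accuracies = scores),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s  %s: accuracy %.6f\n", x$classifier, x$scheme, x$accuracy))
  cat("best parameters:\n")
  print(x$best_params, row.names = FALSE)
  invisible(x)
}

# question abbreviations in reporting order
.tlx_questions <- c(MF = "Mental_fatigue", PF = "Physical_fatigue",
                    TD = "Temporal_demands", C = "Complexity",
                    SS = "Situational_stress", D = "Distractions")

#' Skill classification over questions, classifiers and CV schemes
#'
#' For each workload-questionnaire dimension, binarizes the responses into
#' expert/novice targets and runs each requested classifier's grid search
#' under each cross-validation scheme, keeping the scheme with the highest
#' best accuracy per (question, classifier) cell — the shape of the study's
#' accuracy table.
#'
#' @param features numeric matrix of per-trial feature vectors
#'   (see [build_feature_matrix()]).
#' @param tlx_scores data.frame or matrix of raw 1..20 responses with the
#'   six columns named as in [metric_columns()] (Mental_fatigue ...
#'   Distractions), one row per trial.
#' @param classifiers subset of `c("dt", "knn", "svm", "lr")`.
#' @param schemes list/vector of schemes: `"loocv"` and/or fold counts.
#' @param grids optional named list of `grid_spec` overrides per
#'   classifier; defaults to the full protocol grids.
#' @param seed RNG seed (default 7919).
#' @param aggregate accuracy aggregation, see [grid_search()].
#' @return A data.frame with class `skill_report`: one row per
#'   question x classifier with `question`, `classifier`, `scheme`, `k`,
#'   `accuracy` and `best_params` (deparsed).
#' @export
classify_cohort <- function(features, tlx_scores,
                            classifiers = c("dt", "knn", "svm", "lr"),
                            schemes = list("loocv", 5, 10),
                            grids = NULL, seed = 7919,
                            aggregate = "mean") {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(nrow(tlx_scores) == n)
  rows <- list()
  for (q in names(.tlx_questions)) {
    target <- binarize_target(tlx_scores[[.tlx_questions[[q]]]])
    if (length(unique(target)) < 2L) next
    for (cl in classifiers) {
      best <- NULL
      for (sc in schemes) {
        k <- if (identical(sc, "loocv")) n else as.integer(sc)
        if (k > n) next
        g <- if (!is.null(grids[[cl]])) grids[[cl]]
             else if (cl == "knn")
               classifier_grid("knn", n_neighbors_max = n - ceiling(n / k))
             else classifier_grid(cl)
        res <- grid_search(X, target, g, scheme = if (k == n) "loocv" else k,
                           seed = seed, aggregate = aggregate)
        if (is.null(best) || res$accuracy > best$accuracy) best <- res
      }
      rows[[length(rows) + 1L]] <- data.frame(
        question = q, classifier = toupper(cl), scheme = best$scheme,
        k = best$k, accuracy = best$accuracy,
        best_params = paste(names(best$best_params),
                            unlist(lapply(best$best_params, as.character)),
                            sep = "=", collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("skill_report", "data.frame")
  out
}

#' Format a skill report as an accuracy matrix
#'
#' Pivots a [classify_cohort()] report into the question x classifier
#' matrix layout, each cell `"cv = k:accuracy"` or `"LOOCV:accuracy"` with
#' six decimals.
#'
#' @param report a `skill_report`.
#' @return A character matrix (questions x classifiers).
#' @export
format_accuracy_matrix <- function(report) {
  stopifnot(inherits(report, "skill_report"))
  qs <- intersect(names(.tlx_questions), unique(report$question))
  cls <- unique(report$classifier)
  m <- matrix("", length(qs), length(cls), dimnames = list(qs, cls))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    m[r$question, r$classifier] <- sprintf("%s:%.6f", r$scheme, r$accuracy)
  }
  m
}
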