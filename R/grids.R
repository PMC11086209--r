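#' Hyperparameter grid for a classifier
#'
#' Builds the exhaustive tuning grid of the study protocol for one of the
#' four classifiers. Values mirror the published enumerations; where an
#' enumeration gives only endpoints ("ranging from 0.1 to 1" for the tree's
#' `max_features`) it is discretized into 11 evenly spaced
#' fractions. The logistic
#' regression grid pairs each solver only with the penalties it can use
#' (liblinear and saga take l1 and l2; newton-cg, lbfgs and sag take l2
#' only), giving 7 solver-penalty pairs. Resulting cardinalities: DT 616,
#' SVM 396, LR 63, kNN `3 * 2 * n_neighbors_max`.
#'
#' @param classifier one of `"dt"`, `"knn"`, `"svm"`, `"lr"`.
#' @param n_neighbors_max for kNN, the largest neighbour count to try;
#'   bounded in practice by the training-set size of the smallest fold.
#' @return An object of class `grid_spec`: list with `classifier` and
#'   `params` (a data.frame with one row per parameter combination).
#' @export
classifier_grid <- function(classifier = c("dt", "knn", "svm", "lr"),
                            n_neighbors_max = NULL) {
  classifier <- match.arg(classifier)
  params <- switch(classifier,
    dt = expand.grid(
      criterion = c("gini", "entropy"),
      max_depth = c("None", as.character(1:10)),
      max_features = c("None", "sqrt", "log2",
                       format(seq(0.1, 1, length.out = 11), trim = TRUE)),
      splitter = c("best", "random"),
      stringsAsFactors = FALSE),
    knn = {
      if (is.null(n_neighbors_max))
        stop("kNN grid needs `n_neighbors_max`")
      expand.grid(
        n_neighbors = seq_len(n_neighbors_max),
        weights = c("uniform", "distance"),
        metric = c("euclidean", "manhattan", "minkowski"),
        stringsAsFactors = FALSE)
    },
    svm = expand.grid(
      C = c(1000, 500, 100, 50, 10, 5, 1, 0.5, 0.1),
      kernel = c("poly", "rbf", "sigmoid", "linear"),
      gamma = c("auto", "scale", "1", "0.5", "0.1", "0.05", "0.01",
                "0.005", "0.001", "0.0005", "0.0001"),
      stringsAsFactors = FALSE),
    lr = {
      pairs <- data.frame(
        solver = c("liblinear", "liblinear", "saga", "saga",
                   "newton-cg", "lbfgs", "sag"),
        penalty = c("l1", "l2", "l1", "l2", "l2", "l2", "l2"),
        stringsAsFactors = FALSE)
      merge(pairs, data.frame(C = c(0.1, 0.5, 1, 5, 10, 50, 100, 500, 1000)))
    }
  )
  structure(list(classifier = classifier, params = params),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s, %d parameter combinations\n",
              x$classifier, nrow(x$params)))
  invisible(x)
}
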