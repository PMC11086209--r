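# Binary classifiers behind the grid search. Classes are coded 0/1
# (0 = expert, 1 = novice). The decision tree and k-NN are implemented
# here because no installed implementation exposes the tuned hyperparameter
# semantics (per-split feature subsampling, random-threshold splitter,
# alternative distance metrics with distance weighting); the SVM rides on
# e1071/libsvm and penalized logistic regression on glmnet.

# run expr with a temporary RNG state so results are deterministic and the
# caller's stream is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.majority <- function(y) if (sum(y == 1) > sum(y == 0)) 1L else 0L

.impurity <- function(n0, n1, criterion) {
  n <- n0 + n1
  p0 <- n0 / n; p1 <- n1 / n
  if (criterion == "gini") return(1 - p0^2 - p1^2)
  h <- 0
  if (n0 > 0) h <- h - p0 * log2(p0)
  if (n1 > 0) h <- h - p1 * log2(p1)
  h
}

# best threshold for one feature; returns c(score, threshold) where score is
# the weighted child impurity (lower is better), or NULL if unsplittable
.best_cut <- function(xv, y, criterion) {
  ord <- order(xv)
  xs <- xv[ord]; ys <- y[ord]
  n <- length(xs)
  cut_after <- which(xs[-n] < xs[-1])
  if (length(cut_after) == 0L) return(NULL)
  c1 <- cumsum(ys)
  nL <- cut_after
  n1L <- c1[cut_after]
  n0L <- nL - n1L
  n1R <- c1[n] - n1L
  n0R <- (n - nL) - n1R
  if (criterion == "gini") {
    iL <- 1 - (n0L / nL)^2 - (n1L / nL)^2
    iR <- 1 - (n0R / (n - nL))^2 - (n1R / (n - nL))^2
  } else {
    ent <- function(a, b) {
      tot <- a + b; pa <- a / tot; pb <- b / tot
      out <- numeric(length(tot))
      out <- out - ifelse(a > 0, pa * log2(pa), 0)
      out - ifelse(b > 0, pb * log2(pb), 0)
    }
    iL <- ent(n0L, n1L)
    iR <- ent(n0R, n1R)
  }
  score <- (nL * iL + (n - nL) * iR) / n
  j <- which.min(score)
  c(score[j], (xs[cut_after[j]] + xs[cut_after[j] + 1]) / 2)
}

# random-threshold cut (extremely-randomized style): uniform threshold
# between the feature's min and max, scored by weighted child impurity
.random_cut <- function(xv, y, criterion) {
  lo <- min(xv); hi <- max(xv)
  if (lo == hi) return(NULL)
  thr <- stats::runif(1, lo, hi)
  left <- xv <= thr
  nL0 <- sum(!y[left]); nL1 <- sum(y[left])
  nR0 <- sum(!y[!left]); nR1 <- sum(y[!left])
  if (nL0 + nL1 == 0L || nR0 + nR1 == 0L) return(NULL)
  n <- length(xv)
  score <- ((nL0 + nL1) * .impurity(nL0, nL1, criterion) +
              (nR0 + nR1) * .impurity(nR0, nR1, criterion)) / n
  c(score, thr)
}

.n_candidate_features <- function(max_features, d) {
  if (is.na(max_features) || max_features == "None") return(d)
  if (max_features == "sqrt") return(max(1L, floor(sqrt(d))))
  if (max_features == "log2") return(max(1L, floor(log2(d))))
  frac <- suppressWarnings(as.numeric(max_features))
  if (is.na(frac) || frac <= 0 || frac > 1)
    stop("invalid max_features: ", max_features)
  max(1L, floor(frac * d))
}

#' Fit a binary classification tree
#'
#' Greedy CART for two classes with the tuning surface of the study
#' protocol: split-quality criterion (`gini` or `entropy`), maximum depth,
#' per-split random feature subsampling (`max_features`: `"None"`,
#' `"sqrt"`, `"log2"` or a fraction of the feature count), and splitter
#' strategy (`"best"` exhausts all thresholds of the candidate features;
#' `"random"` draws one uniform threshold per candidate feature and keeps
#' the best-scoring one).
#'
#' @param X numeric matrix, rows = samples.
#' @param y integer vector of 0/1 labels.
#' @param criterion `"gini"` or `"entropy"`.
#' @param max_depth maximum tree depth, or `"None"`/`NA` for unlimited.
#' @param max_features feature-subsampling rule (see above).
#' @param splitter `"best"` or `"random"`.
#' @return An object of class `surg_dtree`.
#' @export
fit_dtree <- function(X, y, criterion = "gini", max_depth = NA,
                      max_features = NA, splitter = "best") {
  X <- as.matrix(X); y <- as.integer(y)
  criterion <- match.arg(criterion, c("gini", "entropy"))
  splitter <- match.arg(splitter, c("best", "random"))
  d <- ncol(X)
  if (is.character(max_depth) && max_depth == "None") max_depth <- NA
  max_depth <- if (is.na(max_depth)) .Machine$integer.max else as.integer(max_depth)
  mf <- .n_candidate_features(max_features, d)

  grow <- function(idx, depth) {
    yy <- y[idx]
    if (length(idx) < 2L || depth >= max_depth || all(yy == yy[1]))
      return(list(leaf = TRUE, class = .majority(yy)))
    feats <- if (mf < d) sample.int(d, mf) else seq_len(d)
    best <- NULL
    for (f in feats) {
      cut <- if (splitter == "best") .best_cut(X[idx, f], yy, criterion)
             else .random_cut(X[idx, f], yy, criterion)
      if (!is.null(cut) && (is.null(best) || cut[1] < best$score))
        best <- list(score = cut[1], feature = f, threshold = cut[2])
    }
    if (is.null(best)) return(list(leaf = TRUE, class = .majority(yy)))
    left <- idx[X[idx, best$feature] <= best$threshold]
    right <- setdiff(idx, left)
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  structure(list(root = grow(seq_len(nrow(X)), 0L), d = d), class = "surg_dtree")
}

#' Predict with a fitted classification tree
#'
#' @param object a `surg_dtree` from [fit_dtree()].
#' @param newdata numeric matrix of samples to classify.
#' @param ... unused.
#' @return Integer vector of 0/1 labels.
#' @export
predict.surg_dtree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  one <- function(node, row) {
    while (!node$leaf)
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object$root, newdata[i, ]),
         integer(1))
}

#' k-nearest-neighbour prediction
#'
#' Plain k-NN with the tuned metric (`euclidean`, `manhattan`, or
#' `minkowski` with exponent `p`) and neighbour weighting (`uniform`
#' majority vote or inverse-distance weights; a zero-distance neighbour
#' dominates the vote). Vote ties resolve to class 0.
#'
#' @param X_train,y_train training samples and 0/1 labels.
#' @param X_test samples to classify.
#' @param k number of neighbours, at most `nrow(X_train)`.
#' @param weights `"uniform"` or `"distance"`.
#' @param metric `"euclidean"`, `"manhattan"` or `"minkowski"`.
#' @param p Minkowski exponent (default 2).
#' @return Integer vector of 0/1 labels.
#' @export
predict_knn <- function(X_train, y_train, X_test, k, weights = "uniform",
                        metric = "euclidean", p = 2) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y_train <- as.integer(y_train)
  weights <- match.arg(weights, c("uniform", "distance"))
  metric <- match.arg(metric, c("euclidean", "manhattan", "minkowski"))
  if (k > nrow(X_train)) stop("k exceeds training-set size")
  pw <- switch(metric, euclidean = 2, manhattan = 1, minkowski = p)
  vapply(seq_len(nrow(X_test)), function(i) {
    dif <- abs(sweep(X_train, 2, X_test[i, ]))
    dd <- rowSums(dif^pw)^(1 / pw)
    nb <- order(dd)[seq_len(k)]
    dn <- dd[nb]; yn <- y_train[nb]
    if (weights == "uniform") {
      v1 <- sum(yn == 1)
      return(if (v1 > k - v1) 1L else 0L)
    }
    if (any(dn == 0)) {
      yz <- yn[dn == 0]
      return(if (sum(yz == 1) > sum(yz == 0)) 1L else 0L)
    }
    w <- 1 / dn
    if (sum(w[yn == 1]) > sum(w[yn == 0])) 1L else 0L
  }, integer(1))
}

# ---- unified train/predict used by the grid search -----------------------

# params: one-row data.frame of character/numeric hyperparameters.
# Returns predicted 0/1 labels for X_test; degenerate single-class training
# folds fall back to the training majority.
.fit_predict <- function(classifier, params, X_train, y_train, X_test) {
  if (length(unique(y_train)) < 2L)
    return(rep(.majority(y_train), nrow(X_test)))
  switch(classifier,
    dt = {
      fit <- fit_dtree(X_train, y_train,
                       criterion = params$criterion,
                       max_depth = params$max_depth,
                       max_features = params$max_features,
                       splitter = params$splitter)
      predict(fit, X_test)
    },
    knn = predict_knn(X_train, y_train, X_test,
                      k = as.integer(params$n_neighbors),
                      weights = params$weights, metric = params$metric),
    svm = {
      d <- ncol(X_train)
      g <- params$gamma
      gamma <- if (g == "auto") 1 / d
        else if (g == "scale") {
          v <- mean((X_train - mean(X_train))^2)
          if (v > 0) 1 / (d * v) else 1
        } else as.numeric(g)
      kern <- switch(params$kernel, poly = "polynomial", rbf = "radial",
                     sigmoid = "sigmoid", linear = "linear")
      fit <- e1071::svm(x = X_train, y = factor(y_train, levels = c(0, 1)),
                        type = "C-classification", kernel = kern,
                        cost = as.numeric(params$C), gamma = gamma,
                        degree = 3, coef0 = 0, scale = FALSE)
      as.integer(as.character(predict(fit, X_test)))
    },
    lr = {
      alpha <- if (params$penalty == "l1") 1 else 0
      lambda <- 1 / (as.numeric(params$C) * nrow(X_train))
      fit <- suppressWarnings(
        glmnet::glmnet(X_train, y_train, family = "binomial",
                       alpha = alpha, lambda = lambda, standardize = FALSE))
      pr <- stats::predict(fit, X_test, type = "response")
      as.integer(pr[, 1] > 0.5)
    },
    stop("unknown classifier: ", classifier)
  )
}
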