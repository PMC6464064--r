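# Classifiers over cluster-feature matrices. The primary learner is a
# deliberately concrete CART decision tree: axis-aligned binary splits chosen
# by Gini impurity, grown without pruning until every leaf is pure or carries
# no remaining feature variation. Zero-gain splits are taken when a node is
# still impure (ties broken by lowest feature index, then lowest threshold),
# so structure like XOR is fully resolved. Alternate learners (naive Bayes,
# random forest, SVMs) wrap standard implementations for comparison runs.
# Scores for ROC analysis are the positive-class fraction at the leaf.

gini_impurity <- function(n1, n) {
  p <- n1 / n
  1 - p^2 - (1 - p)^2
}

# Best split of one feature: returns c(gain, threshold) or NULL.
best_split_feature <- function(x, y, n1, n) {
  ord <- order(x)
  xs <- unname(x[ord]); ys <- y[ord]
  cum1 <- cumsum(ys)
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  nl <- i
  nr <- n - i
  l1 <- cum1[i]
  r1 <- n1 - l1
  g_parent <- gini_impurity(n1, n)
  gain <- g_parent - (nl * gini_impurity(l1, nl) +
                      nr * gini_impurity(r1, nr)) / n
  gain[!valid] <- -Inf
  k <- which.max(gain)
  c(gain = gain[k], threshold = (xs[k] + xs[k + 1L]) / 2)
}

cart_build <- function(X, y, acc) {
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0L || n1 == n)
    return(list(leaf = TRUE, score = n1 / n, n = n))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    sp <- best_split_feature(X[, j], y, n1, n)
    if (is.null(sp)) next
    if (is.null(best) || sp[["gain"]] > best$gain + 1e-12 ||
        (abs(sp[["gain"]] - best$gain) <= 1e-12 &&
         (j < best$feature ||
          (j == best$feature && sp[["threshold"]] < best$threshold)))) {
      best <- list(gain = sp[["gain"]], feature = j,
                   threshold = sp[["threshold"]])
    }
  }
  if (is.null(best))   # impure but unsplittable (no feature varies)
    return(list(leaf = TRUE, score = n1 / n, n = n))
  acc$importance[best$feature] <- acc$importance[best$feature] +
    n * best$gain
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       n = n,
       left = cart_build(X[left, , drop = FALSE], y[left], acc),
       right = cart_build(X[!left, , drop = FALSE], y[!left], acc))
}

cart_fit <- function(X, y) {
  acc <- new.env()
  acc$importance <- numeric(ncol(X))
  tree <- cart_build(X, y, acc)
  imp <- acc$importance
  names(imp) <- colnames(X)
  list(tree = tree, importance = imp)
}

cart_score_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$score
}

cart_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(cart_depth(node$left), cart_depth(node$right))
}

MODEL_KINDS <- c("decision_tree", "naive_bayes", "random_forest",
                 "svm_linear", "svm_rbf", "svm_poly", "svm_sigmoid")

#' Train a classifier on a feature matrix
#'
#' @param X numeric feature matrix (e.g. from [assemble_matrix()]).
#' @param y labels coercible to 0/1 (positive class = 1).
#' @param kind one of `"decision_tree"` (primary), `"naive_bayes"`,
#'   `"random_forest"`, `"svm_linear"`, `"svm_rbf"`, `"svm_poly"`,
#'   `"svm_sigmoid"`.
#' @param seed RNG seed for stochastic learners (the CART tree itself is
#'   deterministic).
#' @return a `regcl_model` carrying the fit, the column schema and the
#'   training `m_max` (when `X` has one).
#' @export
train_classifier <- function(X, y, kind = "decision_tree", seed = 1L) {
  kind <- match.arg(kind, MODEL_KINDS)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("train_classifier: need both classes in y", call. = FALSE)
  fit <- with_seed(seed, switch(
    kind,
    decision_tree = cart_fit(X, y),
    naive_bayes = {
      keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
      list(nb = e1071::naiveBayes(X[, keep, drop = FALSE], factor(y)),
           keep = keep)
    },
    random_forest = randomForest::randomForest(X, factor(y)),
    {
      kernel <- sub("^svm_", "", kind)
      kernel <- c(linear = "linear", rbf = "radial", poly = "polynomial",
                  sigmoid = "sigmoid")[[kernel]]
      e1071::svm(X, factor(y), kernel = kernel, probability = TRUE)
    }))
  structure(list(kind = kind, fit = fit, schema = colnames(X),
                 m_max = attr(X, "m_max"), seed = seed),
            class = "regcl_model")
}

#' @export
print.regcl_model <- function(x, ...) {
  cat(sprintf("regcl model: %s over %d features\n", x$kind, length(x$schema)))
  invisible(x)
}

#' Positive-class scores from a trained model
#'
#' For the decision tree the score is the positive-class fraction at the leaf
#' a sample falls into; the alternates report their class-1 probability.
#'
#' @param model a `regcl_model`.
#' @param X feature matrix with the training schema.
#' @return numeric scores in \[0, 1\].
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "regcl_model"))
  X <- as.matrix(X)
  if (!is.null(model$schema) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$schema))
    stop("predict_score: feature schema differs from training", call. = FALSE)
  switch(model$kind,
    decision_tree = apply(X, 1L, function(x)
      cart_score_one(model$fit$tree, x)),
    naive_bayes = {
      p <- stats::predict(model$fit$nb,
                          X[, model$fit$keep, drop = FALSE], type = "raw")
      unname(p[, "1"])
    },
    random_forest = unname(stats::predict(model$fit, X,
                                          type = "prob")[, "1"]),
    {
      pr <- stats::predict(model$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    })
}

#' Predicted class labels
#' @inheritParams predict_score
#' @param cutoff score threshold for the positive class (default 0.5).
#' @return integer vector of 0/1 predictions.
#' @export
predict_class <- function(model, X, cutoff = 0.5) {
  as.integer(predict_score(model, X) >= cutoff)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `rounds` rounds of `folds`-fold cross-validation with
#' class-stratified folds re-drawn each round from a seeded stream, and
#' averages sensitivity (`TP/(TP+FN)` on the positive class), specificity and
#' accuracy across rounds.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param rounds,folds cross-validation design (default 10 x 10).
#' @param kind learner, as in [train_classifier()].
#' @param seed RNG seed.
#' @return an `eval_report`: per-round metrics plus their means.
#' @export
cross_validate <- function(X, y, rounds = 10L, folds = 10L,
                           kind = "decision_tree", seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(length(y) >= folds, all(y %in% c(0L, 1L)))
  per_round <- with_seed(seed, {
    res <- vector("list", rounds)
    for (r in seq_len(rounds)) {
      repeat {
        fold <- stratified_folds(y, folds)
        ok <- all(vapply(seq_len(folds), function(k)
          length(unique(y[fold != k])) == 2L, logical(1)))
        if (ok) break
        message("cross_validate: single-class training split, re-drawing folds")
      }
      tp <- fp <- tn <- fn <- 0L
      for (k in seq_len(folds)) {
        tr <- fold != k
        if (!any(!tr)) next
        model <- train_classifier(X[tr, , drop = FALSE], y[tr], kind,
                                  seed = seed + 1000L * r + k)
        pred <- predict_class(model, X[!tr, , drop = FALSE])
        truth <- y[!tr]
        tp <- tp + sum(pred == 1L & truth == 1L)
        fp <- fp + sum(pred == 1L & truth == 0L)
        tn <- tn + sum(pred == 0L & truth == 0L)
        fn <- fn + sum(pred == 0L & truth == 1L)
      }
      res[[r]] <- data.frame(round = r,
                             sensitivity = tp / (tp + fn),
                             specificity = tn / (tn + fp),
                             accuracy = (tp + tn) / (tp + tn + fp + fn))
    }
    do.call(rbind, res)
  })
  structure(list(per_round = per_round,
                 sensitivity = mean(per_round$sensitivity),
                 specificity = mean(per_round$specificity),
                 accuracy = mean(per_round$accuracy),
                 kind = kind, rounds = rounds, folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("%s, %d x %d-fold CV: accuracy %.3f, sensitivity %.3f,",
                     " specificity %.3f\n"),
              x$kind, x$rounds, x$folds, x$accuracy, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' ROC curve and AUC of a model on labeled data
#'
#' Sweeps the score thresholds and integrates the curve (trapezoidal rule, as
#' computed by pROC).
#'
#' @param model a `regcl_model`.
#' @param X feature matrix.
#' @param y 0/1 labels containing both classes.
#' @return list with `curve` (data.frame fpr/tpr) and `auc`.
#' @export
roc_auc <- function(model, X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("roc_auc: need both classes in y", call. = FALSE)
  scores <- predict_score(model, X)
  r <- pROC::roc(response = y, predictor = scores, levels = c(0L, 1L),
                 direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  list(curve = curve, auc = as.numeric(pROC::auc(r)))
}

#' Gini importance of features
#'
#' Total Gini impurity decrease contributed by each feature across the tree's
#' splits, normalized to sum to 1; features never used in a split score 0.
#' When no split reduced impurity at all, importances are all zero.
#'
#' @param model a `regcl_model` of kind `decision_tree` or `random_forest`.
#' @return named numeric vector over the training features.
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "regcl_model"))
  imp <- switch(model$kind,
    decision_tree = model$fit$importance,
    random_forest = {
      v <- model$fit$importance[, "MeanDecreaseGini"]
      stats::setNames(as.numeric(v), rownames(model$fit$importance))
    },
    stop("gini_importance: not a tree-based model", call. = FALSE))
  tot <- sum(imp)
  if (tot > 0) imp / tot else imp * 0
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
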