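# Separable with a margin: class-0 signal < 0.4, class-1 signal > 0.6, so any
# training-subset split boundary lands inside the gap.
sep_data <- function(n = 40) {
  half <- n %/% 2
  sig <- c(runif(half, 0, 0.4), runif(n - half, 0.6, 1))
  x <- matrix(c(sig, runif(n)), ncol = 2,
              dimnames = list(NULL, c("signal", "noise")))
  list(X = x, y = rep(c(0L, 1L), c(half, n - half)))
}

test_that("the CART tree fits separable, constant and XOR structure", {
  withr::local_seed(61)
  d <- sep_data()
  m <- train_classifier(d$X, d$y)
  expect_equal(predict_class(m, d$X), d$y)

  # constant features -> a single majority leaf
  Xc <- matrix(1, 10, 2, dimnames = list(NULL, c("a", "b")))
  yc <- rep(c(0L, 1L), c(7, 3))
  mc <- train_classifier(Xc, yc)
  expect_true(mc$fit$tree$leaf)
  expect_equal(predict_score(mc, Xc), rep(0.3, 10))
  expect_equal(predict_class(mc, Xc), rep(0L, 10))

  # XOR requires zero-gain splits; the tree resolves it at depth 2
  Xx <- cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1))
  yx <- c(0L, 1L, 1L, 0L)
  mx <- train_classifier(Xx, yx)
  expect_equal(predict_class(mx, Xx), yx)
  expect_equal(regcl:::cart_depth(mx$fit$tree), 2L)

  expect_error(train_classifier(d$X, rep(1L, 40)), "both classes")
})

test_that("the tree agrees with an independent CART implementation on separable data", {
  skip_if_not_installed("rpart")
  withr::local_seed(62)
  n <- 60
  X <- matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 2] > 0.6)
  ours <- train_classifier(X, y)
  rp <- rpart::rpart(factor(y) ~ ., data.frame(X), method = "class",
                     control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                    minbucket = 1, xval = 0))
  expect_equal(predict_class(ours, X),
               as.integer(as.character(predict(rp, data.frame(X),
                                               type = "class"))))
})

test_that("alternate learners train and emit probability scores", {
  withr::local_seed(63)
  d <- sep_data(60)
  for (kind in c("naive_bayes", "random_forest", "svm_rbf", "svm_linear")) {
    m <- train_classifier(d$X, d$y, kind = kind, seed = 5)
    s <- predict_score(m, d$X)
    expect_true(all(s >= 0 & s <= 1))
    expect_gt(mean((s >= 0.5) == (d$y == 1)), 0.9)
  }
})

test_that("cross-validation is stratified, deterministic under seed, and calibrated", {
  withr::local_seed(64)
  d <- sep_data(50)
  cv1 <- cross_validate(d$X, d$y, rounds = 2, folds = 5, seed = 3)
  cv2 <- cross_validate(d$X, d$y, rounds = 2, folds = 5, seed = 3)
  expect_equal(cv1$per_round, cv2$per_round)
  expect_equal(cv1$accuracy, 1)

  # fold assignment partitions every sample exactly once per round
  fold <- with(list(), {regcl:::with_seed(1, regcl:::stratified_folds(d$y, 5))})
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 50L)
  expect_true(all(table(fold, d$y) >= 4))   # stratification balance

  # pure-noise features, balanced labels: accuracy near chance
  Xn <- matrix(runif(200 * 4), ncol = 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  yn <- rep(0:1, 100)
  cvn <- cross_validate(Xn, yn, rounds = 3, folds = 10, seed = 8)
  expect_gt(cvn$accuracy, 0.35)
  expect_lt(cvn$accuracy, 0.65)
})

test_that("ROC/AUC matches the trapezoid oracle and hits its extremes", {
  withr::local_seed(65)
  d <- sep_data(60)
  m <- train_classifier(d$X, d$y)
  ra <- roc_auc(m, d$X, d$y)
  expect_equal(ra$auc, 1)
  expect_true(all(diff(ra$curve$tpr) >= 0))

  # partly-noisy labels give an intermediate AUC equal to the direct sweep
  y2 <- d$y; y2[sample(60, 12)] <- 1L - y2[sample(60, 12)]
  m2 <- train_classifier(d$X[, 2, drop = FALSE], y2)
  ra2 <- roc_auc(m2, d$X[, 2, drop = FALSE], y2)
  s2 <- predict_score(m2, d$X[, 2, drop = FALSE])
  expect_equal(ra2$auc, trapezoid_auc(s2, y2), tolerance = 1e-9)
  expect_error(roc_auc(m, d$X, rep(1L, 60)), "both classes")
})

test_that("Gini importances normalize to one and localize to used features", {
  withr::local_seed(66)
  d <- sep_data(80)
  m <- train_classifier(d$X, d$y)
  imp <- gini_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(unname(imp["signal"]), 1)   # only informative split used
  expect_equal(unname(imp["noise"]), 0)
  expect_error(gini_importance(train_classifier(d$X, d$y, "svm_rbf")),
               "tree-based")
})
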