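test_that("missingness_prepare drops worst features then incomplete rows", {
  n <- 6
  feats <- data.frame(A = c(NA, NA, NA, 4, 5, 6), B = c(NA, NA, 3, 4, 5, 6),
                      C = c(NA, 2, NA, 4, 5, 6), D = c(NA, 2, 3, 4, 5, 6),
                      E = 1:6)
  prep <- missingness_prepare(feats, labels = rep(c("a", "b"), 3), k_drop = 3)
  expect_setequal(prep$dropped, c("A", "B", "C"))   # tie B/C by name
  expect_setequal(prep$kept, c("D", "E"))
  expect_equal(nrow(prep$X), 5)                     # row 1 excluded
  expect_false(anyNA(prep$X))

  # no missing anywhere: unchanged
  clean <- data.frame(A = 1:6, B = 6:1)
  prep2 <- missingness_prepare(clean, rep(c("a", "b"), 3))
  expect_length(prep2$dropped, 0)
  expect_equal(nrow(prep2$X), 6)

  # one row missing a kept feature is excluded, others kept
  clean$B[2] <- NA
  clean$C <- c(NA, NA, NA, NA, 5, 6); clean$D <- c(NA, NA, NA, 4, 5, 6)
  clean$E <- c(NA, NA, 3, 4, 5, 6)
  prep3 <- missingness_prepare(clean, rep(c("a", "b"), 3))
  expect_setequal(prep3$dropped, c("C", "D", "E"))
  expect_equal(nrow(prep3$X), 5)
})

test_that("L1 logistic regression separates, sparsifies, and splits duplicates", {
  x <- c(seq(-1, -0.02, length.out = 50), seq(0.02, 1, length.out = 50))
  y <- rep(0:1, each = 50)
  X <- cbind(x = x)
  fit <- fit_l1_logistic(X, y)
  expect_gt(fit$weights[1], 0)
  expect_equal(mean((predict(fit, X) >= 0.5) == y), 1.0)

  set.seed(21)
  n <- 200
  x1 <- rnorm(n); y2 <- as.integer(x1 + rnorm(n, 0, 0.3) > 0)
  noise <- rnorm(n)
  X2 <- scale(cbind(inf = x1, noise = noise))
  fit2 <- fit_l1_logistic(X2, y2)
  expect_lt(abs(fit2$weights[2]), 1e-3)
  expect_gt(abs(fit2$weights[1]), 0.1)

  X3 <- scale(cbind(a = x1, b = x1))
  fit3 <- fit_l1_logistic(X3, y2)
  fit1 <- fit_l1_logistic(scale(cbind(a = x1)), y2)
  expect_equal(fit3$weights[1] + fit3$weights[2], fit1$weights[1],
               tolerance = 1e-3)
  expect_error(fit_l1_logistic(X, rep(1, 100)), "classes")
})

test_that("gradient boosting learns XOR and is null on permuted labels", {
  set.seed(22)
  n <- 400
  X <- cbind(a = runif(n, -1, 1), b = runif(n, -1, 1))
  y <- as.integer(xor(X[, 1] > 0, X[, 2] > 0))
  fit <- fit_gradient_boosting(X, y, n_trees = 100, max_depth = 2)
  expect_gt(auc_roc(y, predict(fit, X)), 0.99)

  yperm <- sample(y)
  oof <- stratified_oof_probabilities(
    function(Xtr, ytr) fit_gradient_boosting(Xtr, ytr, n_trees = 60),
    X, yperm, k = 5, seed = 77)
  expect_gt(auc_roc(yperm, oof$prob), 0.43)
  expect_lt(auc_roc(yperm, oof$prob), 0.57)

  # deterministic given the seed
  f1 <- fit_gradient_boosting(X, y, n_trees = 30, seed = 5)
  f2 <- fit_gradient_boosting(X, y, n_trees = 30, seed = 5)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_error(fit_gradient_boosting(X, rep(0, n)), "classes")
})

test_that("stratified folds preserve class balance and coverage", {
  y <- rep(c(1L, 0L), each = 5)
  fold <- stratified_folds(y, k = 5, seed = 3)
  for (f in 1:5) {
    expect_equal(sum(y[fold == f]), 1L)
    expect_equal(sum(fold == f), 2L)
  }
  expect_identical(fold, stratified_folds(y, k = 5, seed = 3))
  expect_error(stratified_folds(c(1, 1, 1, 0, 0, 0, 0, 0), k = 5),
               "below")

  # each record predicted exactly once, by a model not trained on it
  set.seed(30)
  X <- matrix(rnorm(40), 20, 2); yy <- rep(0:1, 10)
  oof <- stratified_oof_probabilities(
    function(Xtr, ytr) fit_l1_logistic(Xtr, ytr), X, yy, k = 5, seed = 1)
  expect_false(anyNA(oof$prob))
  expect_equal(sort(unique(oof$fold)), 1:5)
})

test_that("AUC-ROC matches pair counting and the U identity", {
  expect_equal(auc_roc(c(0, 1), c(0.2, 0.9)), 1.0)
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_true(is.na(auc_roc(c(1, 1), c(0.1, 0.2))))

  set.seed(31)
  for (i in 1:100) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    p <- c(rnorm(n1), rnorm(n0))
    y <- rep(c(1, 0), c(n1, n0))
    U <- mann_whitney_u(p[y == 1], p[y == 0])$U
    expect_equal(auc_roc(y, p), U / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("average precision is the step-wise area", {
  expect_equal(auc_pr(c(0, 1), c(0.2, 0.9)), 1.0)
  # y=(1,0,1,0) by descending score: precisions 1, 1/2, 2/3, 1/2
  y <- c(0, 0, 1, 1); p <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(auc_pr(y, p), 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_true(is.na(auc_pr(c(1, 1), c(0.5, 0.6))))
})

test_that("youden_threshold maximizes J with the low-tau tie-break", {
  res <- youden_threshold(c(0, 1), c(0.2, 0.9))
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)

  res2 <- youden_threshold(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(res2$J, 0.5)
  expect_equal(res2$threshold, 0.35)     # tie resolved to the lower tau
  expect_equal(res2$sensitivity, 1.0)
  expect_equal(res2$specificity, 0.5)

  # exhaustive-scan oracle on random instances
  set.seed(32)
  for (i in 1:100) {
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(20), 2)
    got <- youden_threshold(y, p)
    Js <- vapply(sort(unique(p)), function(tau) {
      pred <- p >= tau
      sum(pred & y == 1) / sum(y) + sum(!pred & y == 0) / sum(y == 0) - 1
    }, numeric(1))
    expect_equal(got$J, max(Js), tolerance = 1e-12)
    expect_equal(got$threshold,
                 sort(unique(p))[which(Js >= max(Js) - 1e-12)[1]])
  }
})

test_that("evaluate_task runs the full chain on synthetic features", {
  set.seed(33)
  n <- 60
  feats <- data.frame(record_id = sprintf("r%03d", 1:(2 * n)),
                      good = c(rnorm(n) + 3, rnorm(n)),
                      ok = c(rnorm(n) + 1, rnorm(n)),
                      junk = rnorm(2 * n))
  labels <- rep(c("HCM", "DCM_I"), each = n)
  cv <- evaluate_task(feats, labels, c("HCM", "DCM_I"),
                      model = "l1_logistic", seed = 9)
  expect_s3_class(cv, "cv_result")
  expect_gt(cv$auc_roc_pooled, 0.95)
  expect_equal(length(cv$prob), 2 * n)
  expect_true(all(cv$sensitivity <= 1, cv$specificity <= 1))

  perm <- evaluate_task(feats, sample(labels), c("HCM", "DCM_I"),
                        model = "l1_logistic", seed = 9)
  expect_gt(perm$auc_roc_pooled, 0.35)
  expect_lt(perm$auc_roc_pooled, 0.65)

  # top-k restriction keeps only k features
  cvk <- evaluate_task(feats, labels, c("HCM", "DCM_I"),
                       model = "l1_logistic", top_k = 2, seed = 9)
  expect_length(cvk$kept_features, 2)

  # serialized result reloads identically
  path <- file.path(tempdir(), "cv.rds")
  saveRDS(cv, path)
  expect_equal(readRDS(path), cv)
})

test_that("no training-fold statistic leaks from test rows", {
  set.seed(34)
  X <- matrix(rnorm(200), 50, 4)
  y <- rep(0:1, 25)
  fit_fun <- function(Xtr, ytr) fit_l1_logistic(Xtr, ytr)
  base <- stratified_oof_probabilities(fit_fun, X, y, k = 5, seed = 2,
                                       standardize = TRUE)
  # perturb only the rows of test fold 1; the standardization fitted for
  # fold 1 (on folds 2..5) must be unchanged
  X2 <- X
  X2[base$fold == 1, ] <- X2[base$fold == 1, ] + 100
  after <- stratified_oof_probabilities(fit_fun, X2, y, k = 5, seed = 2,
                                        standardize = TRUE)
  expect_identical(base$fold, after$fold)
  expect_equal(base$fold_stats[[1]], after$fold_stats[[1]],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(base$fold_stats[[2]],
                                after$fold_stats[[2]])))
})
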