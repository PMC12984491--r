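# Missing-data handling, the two classifiers, stratified out-of-fold
# evaluation and threshold metrics for the three phenotype tasks.

#' Prepare an analytic subset
#'
#' Drops the `k_drop` features with the most missing cells (ties broken
#' alphabetically), then excludes rows with any remaining missing value
#' (complete-case analysis).  Both models consume the identical subset.
#'
#' @param features data.frame of numeric/logical feature columns; an
#'   optional `record_id` column is carried through as row metadata.
#' @param labels binary label per row.
#' @param k_drop number of worst-missingness features to drop.
#' @return list with `X` (numeric matrix, no missing), `y` (0/1),
#'   `kept`, `dropped` (feature names), `excluded` (row indices or
#'   record ids removed).
#' @export
missingness_prepare <- function(features, labels, k_drop = 3L) {
  if (!nrow(features)) stop("empty feature table")
  ids <- if ("record_id" %in% names(features)) {
    as.character(features$record_id)
  } else as.character(seq_len(nrow(features)))
  feats <- features[setdiff(names(features), "record_id")]
  feats <- feats[vapply(feats, function(c) is.numeric(c) || is.logical(c),
                        logical(1))]
  miss <- vapply(feats, function(c) sum(is.na(c)), integer(1))
  ord <- order(-miss, names(feats))
  # drop the k worst-missingness features (ties alphabetical); features
  # with no missing cells are never dropped, so a complete table passes
  # through unchanged
  n_drop <- min(k_drop, sum(miss > 0L))
  dropped <- if (n_drop > 0L) names(feats)[ord][seq_len(n_drop)] else
    character(0)
  kept <- setdiff(names(feats), dropped)
  X <- as.matrix(as.data.frame(lapply(feats[kept], as.numeric)))
  colnames(X) <- kept
  complete <- stats::complete.cases(X) & !is.na(labels)
  if (!any(complete)) stop("all rows excluded by complete-case rule")
  y <- as.integer(as.factor(labels[complete])) - 1L
  if ("record_id" %in% names(features)) {
    rownames(X) <- ids
  }
  list(X = X[complete, , drop = FALSE], y = y, kept = kept,
       dropped = dropped, excluded = ids[!complete],
       classes = levels(as.factor(labels[complete])))
}

#' L1-penalized logistic regression
#'
#' Minimizes the summed logistic loss plus `(1/inverse_reg) * ||w||_1`
#' with an unpenalized intercept (the liblinear C parameterization),
#' via glmnet with `lambda = 1/(n * inverse_reg)`.  Features should be
#' standardized with training-fold statistics before calling (the fit
#' itself does not rescale).
#'
#' @param X numeric matrix (standardized).
#' @param y binary 0/1.
#' @param inverse_reg the C parameter (default 0.1).
#' @param tol convergence threshold.
#' @return object of class `l1_logistic` with `weights`, `intercept`.
#' @export
fit_l1_logistic <- function(X, y, inverse_reg = 0.1, tol = 1e-9) {
  if (length(unique(y)) < 2L) stop("both classes required")
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (p == 1L) X <- cbind(X, `..pad` = 0)   # glmnet needs >= 2 columns
  lam <- 1 / (n * inverse_reg)
  fit <- glmnet::glmnet(X, factor(y), family = "binomial",
                        lambda = lam * c(16, 8, 4, 2, 1),
                        standardize = FALSE, thresh = tol,
                        maxit = 1e6)
  w <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  w <- w[seq_len(p + 1L)]
  structure(list(intercept = w[1L], weights = w[-1L],
                 feature_names = colnames(X), inverse_reg = inverse_reg),
            class = "l1_logistic")
}

#' @export
predict.l1_logistic <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  eta <- as.numeric(X[, seq_along(object$weights), drop = FALSE] %*%
                      object$weights + object$intercept)
  1 / (1 + exp(-eta))
}

#' Stratified k-fold assignment
#'
#' Folds preserve class proportions within one member; deterministic
#' given the seed.
#'
#' @param y binary 0/1 labels.
#' @param k folds.
#' @param seed RNG seed.
#' @return integer fold id per row.
#' @export
stratified_folds <- function(y, k = 5L, seed = 20250719L) {
  if (min(table(y)) < k) stop("class count below the number of folds")
  fold <- integer(length(y))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Out-of-fold probabilities under stratified cross-validation
#'
#' Each record is predicted exactly once by a model that never saw it;
#' standardization statistics are computed inside each training fold
#' only.
#'
#' @param model_fun function(X, y) returning a model with a `predict`
#'   method giving probabilities.
#' @param X numeric matrix.
#' @param y binary 0/1.
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param standardize z-score features with training-fold statistics
#'   (used for the linear model; tree models consume raw values).
#' @return list with `prob` (out-of-fold probability per row), `fold`
#'   (assignments), `fold_stats` (per-fold standardization means/sds).
#' @export
stratified_oof_probabilities <- function(model_fun, X, y, k = 5L,
                                         seed = 20250719L,
                                         standardize = FALSE) {
  fold <- stratified_folds(y, k, seed)
  prob <- rep(NA_real_, length(y))
  fold_stats <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sd <- apply(Xtr, 2L, stats::sd)
      sd[!is.finite(sd) | sd < 1e-12] <- 1
      Xtr <- scale(Xtr, mu, sd); Xte <- scale(Xte, mu, sd)
      fold_stats[[f]] <- list(mean = mu, sd = sd)
    }
    m <- model_fun(Xtr, y[tr])
    prob[te] <- stats::predict(m, Xte)
  }
  list(prob = prob, fold = fold, fold_stats = fold_stats)
}

#' Area under the ROC curve
#'
#' Rank statistic with midrank tie handling; equals the pair-counting
#' probability of superiority, i.e. `U/(n1 n2)`.
#'
#' @param y binary 0/1.
#' @param p scores/probabilities.
#' @return AUC in `[0, 1]`, `NA` for a single-class `y`.
#' @export
auc_roc <- function(y, p) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: AP =
#' sum_k (R_k - R_{k-1}) P_k over descending unique score thresholds.
#'
#' @param y binary 0/1.
#' @param p scores.
#' @return AP in `[0, 1]`, `NA` for a single-class `y`.
#' @export
auc_pr <- function(y, p) {
  n1 <- sum(y == 1L)
  if (n1 == 0L || all(y == 1L)) return(NA_real_)
  o <- order(-p)
  ys <- y[o]; ps <- p[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(ps[-1L] != ps[-length(ps)], TRUE)   # threshold boundaries
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Youden-optimal threshold
#'
#' Scans the unique probabilities as candidate thresholds (rule
#' `p >= tau` is positive), maximizing J = sensitivity + specificity - 1;
#' ties resolved toward the lowest threshold (favouring sensitivity).
#'
#' @param y binary 0/1.
#' @param p scores.
#' @return list with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_threshold <- function(y, p) {
  if (length(unique(y)) < 2L) {
    return(list(threshold = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, J = NA_real_))
  }
  taus <- sort(unique(p))
  best <- NULL
  for (tau in taus) {
    pred <- p >= tau
    sens <- sum(pred & y == 1L) / sum(y == 1L)
    spec <- sum(!pred & y == 0L) / sum(y == 0L)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12) {
      best <- list(threshold = tau, sensitivity = sens,
                   specificity = spec, J = J)
    }
  }
  best
}

#' Evaluate one classification task
#'
#' Full chain: missingness handling, optional top-k feature restriction
#' (the smaller obstructive-vs-non-obstructive task), stratified 5-fold
#' out-of-fold probabilities, then AUCs in both conventions
#' (mean-across-folds and pooled out-of-fold) plus Youden sensitivity/
#' specificity on the pooled probabilities.
#'
#' @param features data.frame (may include record_id).
#' @param labels label per row; rows with labels outside `task_groups`
#'   are dropped.
#' @param task_groups character pair: (positive class, negative class).
#' @param model `"l1_logistic"` or `"gradient_boosting"`.
#' @param top_k optional number of features pre-selected by
#'   [rank_features()] on the full task data (information leaks into CV,
#'   as in the original design; set `top_k_nested = TRUE` for honest
#'   nested selection).
#' @param k folds; `seed` RNG seed; `k_drop` worst-missingness features
#'   to remove; `options` extra model parameters.
#' @param top_k_nested re-rank features inside each training fold.
#' @param max_missing_frac structurally sparse columns (missing in more
#'   than this fraction of rows) are removed before the
#'   drop-3-then-complete-case rule; the extraction registry is a
#'   per-lead superset of the study's feature set, and e.g. a Q-wave
#'   amplitude is legitimately absent in most leads, which would
#'   otherwise empty the complete-case subset.
#' @return object of class `cv_result`.
#' @export
evaluate_task <- function(features, labels, task_groups,
                          model = c("l1_logistic", "gradient_boosting"),
                          top_k = NULL, top_k_nested = FALSE, k = 5L,
                          seed = 20250719L, k_drop = 3L,
                          max_missing_frac = 0.3, options = list()) {
  model <- match.arg(model)
  labels <- as.character(labels)
  sel <- labels %in% task_groups
  if (!any(labels[sel] == task_groups[1L]) ||
      !any(labels[sel] == task_groups[2L])) {
    stop("labels must cover both classes: ",
         paste(task_groups, collapse = " vs "))
  }
  feats <- features[sel, , drop = FALSE]
  labs <- labels[sel]
  # a missing Q/S/P amplitude means "no deflection above the floor" in
  # that lead: for the classifier its measured magnitude is zero (the
  # feature table itself keeps the missingness explicit)
  zero_fam <- grep("^(Q|S|P)_amp_", names(feats))
  for (jc in zero_fam) {
    feats[[jc]][is.na(feats[[jc]])] <- 0
  }
  sparse <- vapply(feats, function(col) {
    (is.numeric(col) || is.logical(col)) &&
      mean(is.na(col)) > max_missing_frac
  }, logical(1))
  sparse_cols <- names(feats)[sparse]
  feats <- feats[!sparse]
  prep <- missingness_prepare(feats, labs, k_drop = k_drop)
  prep$dropped <- c(sparse_cols, prep$dropped)
  # positive class = task_groups[1]
  y <- as.integer(prep$classes[prep$y + 1L] == task_groups[1L])
  X <- prep$X
  if (!is.null(top_k) && !top_k_nested) {
    cmp <- compare_groups(as.data.frame(X), prep$classes[prep$y + 1L],
                          groups = task_groups)
    keep <- rank_features(cmp, top_k)
    X <- X[, keep, drop = FALSE]
  }
  model_fun <- switch(model,
    l1_logistic = function(Xtr, ytr) {
      fit_l1_logistic(Xtr, ytr,
                      inverse_reg = options$inverse_reg %||% 0.1)
    },
    gradient_boosting = function(Xtr, ytr) {
      do.call(fit_gradient_boosting,
              c(list(X = Xtr, y = ytr, seed = seed),
                options[intersect(names(options),
                                  c("n_trees", "max_depth",
                                    "learning_rate", "subsample",
                                    "lambda", "min_child"))]))
    })
  if (!is.null(top_k) && top_k_nested) {
    inner <- model_fun
    model_fun <- function(Xtr, ytr) {
      cmp <- compare_groups(as.data.frame(Xtr),
                            ifelse(ytr == 1L, task_groups[1L],
                                   task_groups[2L]),
                            groups = task_groups)
      keep <- rank_features(cmp, top_k)
      m <- inner(Xtr[, keep, drop = FALSE], ytr)
      structure(list(inner = m, keep = keep), class = "nested_model")
    }
  }
  oof <- stratified_oof_probabilities(model_fun, X, y, k = k, seed = seed,
                                      standardize = model == "l1_logistic")
  per_fold <- lapply(seq_len(k), function(f) {
    i <- oof$fold == f
    c(auc_roc = auc_roc(y[i], oof$prob[i]),
      auc_pr = auc_pr(y[i], oof$prob[i]))
  })
  pf <- do.call(rbind, per_fold)
  yd <- youden_threshold(y, oof$prob)
  structure(list(
    task = paste(task_groups, collapse = "_vs_"), model = model,
    n = length(y), kept_features = colnames(X),
    dropped_features = prep$dropped, excluded = prep$excluded,
    fold = oof$fold, prob = oof$prob, y = y,
    auc_roc_mean = mean(pf[, "auc_roc"], na.rm = TRUE),
    auc_pr_mean = mean(pf[, "auc_pr"], na.rm = TRUE),
    auc_roc_pooled = auc_roc(y, oof$prob),
    auc_pr_pooled = auc_pr(y, oof$prob),
    per_fold = pf, threshold = yd$threshold,
    sensitivity = yd$sensitivity, specificity = yd$specificity,
    seed = seed), class = "cv_result")
}

#' @export
predict.nested_model <- function(object, newdata, ...) {
  stats::predict(object$inner, newdata[, object$keep, drop = FALSE])
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    paste0("<cv_result %s | %s> n=%d\n",
           "  AUC-ROC mean %.3f / pooled %.3f; AUC-PR mean %.3f / ",
           "pooled %.3f\n  Youden tau=%.3f sens=%.3f spec=%.3f\n"),
    x$task, x$model, x$n, x$auc_roc_mean, x$auc_roc_pooled,
    x$auc_pr_mean, x$auc_pr_pooled, x$threshold, x$sensitivity,
    x$specificity))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
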