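# Two-group feature comparison: Mann-Whitney U with an exact small-sample
# path, Cliff's delta, risk difference, Table-1-style comparison rows and
# top-k feature ranking.

#' Mann-Whitney U test
#'
#' Exact enumeration of the U null distribution when `n1 + n2 <= 12` and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples (missing values dropped first).
#' @return list with `U` (statistic of `x`), `p` (two-sided) and
#'   `method` (`"exact"`/`"approx"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    return(list(U = NA_real_, p = NA_real_, method = "empty"))
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= 12L && !ties) {
    cnt <- u_count_table(n1, n2)          # counts of U = 0..n1*n2
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(U + 1L)])       # P(U <= u)
    hi <- sum(cnt[seq.int(U + 1L, n1 * n2 + 1L)])  # P(U >= u)
    p <- min(1, 2 * min(lo, hi) / tot)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tab <- table(r)
  tiecor <- sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1))
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tiecor)
  if (sig2 <= 0) return(list(U = U, p = 1, method = "approx"))
  z <- (abs(U - mu) - 0.5) / sqrt(sig2)
  z <- max(z, 0)
  list(U = U, p = min(1, 2 * stats::pnorm(-z)), method = "approx")
}

# dynamic-programming count of rank-sum arrangements giving each U value
u_count_table <- function(n1, n2) {
  # f[u+1] = number of ways to choose n1 of n1+n2 ranks with U = u
  f <- matrix(0, n1 + 1L, n1 * n2 + 1L)
  f[1L, 1L] <- 1
  for (k in seq_len(n1 + n2)) {
    fn <- matrix(0, n1 + 1L, n1 * n2 + 1L)
    for (i in 0:min(k, n1)) {
      # adding element of rank k as a y (keeps i) or as an x
      fn[i + 1L, ] <- f[i + 1L, ]
      if (i >= 1L) {
        shift <- k - i         # x beats the (k - i) ys so far... see below
        prev <- f[i, ]
        if (shift >= 0L) {
          idx <- seq_len(n1 * n2 + 1L - shift)
          fn[i + 1L, idx + shift] <- fn[i + 1L, idx + shift] + prev[idx]
        }
      }
    }
    f <- fn
  }
  f[n1 + 1L, ]
}

#' Cliff's delta
#'
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (n1 n2)`; antisymmetric and
#' translation-invariant, equal to `2 AUC - 1` for the probability of
#' superiority.
#'
#' @param x,y numeric samples (missing dropped).
#' @return delta in `[-1, 1]`, `NA` if either sample is empty.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  # rank-based O((n1+n2) log): delta = 2*AUC - 1 with midrank ties
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  2 * auc - 1
}

#' Risk difference between two proportions
#'
#' @param k1,n1,k2,n2 event counts and group sizes.
#' @return `k1/n1 - k2/n2`, `NA` if a group is empty.
#' @export
risk_difference <- function(k1, n1, k2, n2) {
  if (n1 < 1L || n2 < 1L) return(NA_real_)
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  k1 / n1 - k2 / n2
}

# two-proportion z-test with continuity correction
two_prop_test <- function(k1, n1, k2, n2) {
  p <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se < 1e-12) return(1)
  z <- (abs(k1 / n1 - k2 / n2) - 0.5 * (1 / n1 + 1 / n2)) / se
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Compare feature distributions between two groups
#'
#' One row per feature: numeric features get a Mann-Whitney U p value and
#' Cliff's delta; logical features a two-proportion test and risk
#' difference.  No multiplicity adjustment is applied by default
#' (optionally appended, clearly labelled).  Rows are sorted by p.
#'
#' @param features data.frame of feature columns (numeric or logical);
#'   non-feature columns (e.g. record_id) are ignored.
#' @param labels group label per row (exactly 2 levels used).
#' @param groups optional character pair selecting/ordering the groups.
#' @param alpha significance threshold recorded in the output.
#' @param adjust also append Benjamini-Hochberg adjusted p values.
#' @return data.frame of comparison rows.
#' @export
compare_groups <- function(features, labels, groups = NULL, alpha = 0.05,
                           adjust = FALSE) {
  labels <- as.character(labels)
  if (is.null(groups)) groups <- unique(labels[!is.na(labels)])
  if (length(groups) != 2L) stop("need exactly 2 groups")
  i1 <- which(labels == groups[1L]); i2 <- which(labels == groups[2L])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("each group needs at least 2 members")
  }
  keep <- vapply(features, function(col) is.numeric(col) || is.logical(col),
                 logical(1))
  feats <- features[keep]
  rows <- lapply(names(feats), function(nm) {
    col <- feats[[nm]]
    x <- col[i1]; y <- col[i2]
    if (is.logical(col)) {
      k1 <- sum(x, na.rm = TRUE); m1 <- sum(!is.na(x))
      k2 <- sum(y, na.rm = TRUE); m2 <- sum(!is.na(y))
      if (m1 < 1L || m2 < 1L) return(NULL)
      data.frame(feature = nm, effect_type = "risk_difference",
                 effect = risk_difference(k1, m1, k2, m2),
                 p = two_prop_test(k1, m1, k2, m2),
                 median1 = k1 / m1, q1_lo = NA_real_, q1_hi = NA_real_,
                 median2 = k2 / m2, q2_lo = NA_real_, q2_hi = NA_real_,
                 n1 = m1, n2 = m2)
    } else {
      xv <- x[!is.na(x)]; yv <- y[!is.na(y)]
      if (length(xv) < 2L || length(yv) < 2L) return(NULL)
      if (stats::var(c(xv, yv)) < 1e-24) {
        return(data.frame(feature = nm, effect_type = "cliffs_delta",
                          effect = NA_real_, p = NA_real_,
                          median1 = stats::median(xv), q1_lo = NA_real_,
                          q1_hi = NA_real_, median2 = stats::median(yv),
                          q2_lo = NA_real_, q2_hi = NA_real_,
                          n1 = length(xv), n2 = length(yv)))
      }
      mw <- mann_whitney_u(xv, yv)
      q1 <- stats::quantile(xv, c(0.25, 0.75), names = FALSE)
      q2 <- stats::quantile(yv, c(0.25, 0.75), names = FALSE)
      data.frame(feature = nm, effect_type = "cliffs_delta",
                 effect = cliffs_delta(xv, yv), p = mw$p,
                 median1 = stats::median(xv), q1_lo = q1[1L],
                 q1_hi = q1[2L],
                 median2 = stats::median(yv), q2_lo = q2[1L],
                 q2_hi = q2[2L], n1 = length(xv), n2 = length(yv))
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no comparable features")
  attr(out, "groups") <- groups
  attr(out, "alpha") <- alpha
  if (adjust) out$p_adjusted_BH <- stats::p.adjust(out$p, "BH")
  out[order(out$p, out$feature), ]
}

#' Rank features by discriminatory ability
#'
#' Top-k by absolute effect size, ties broken by smaller p, then by name;
#' deterministic.  Computed on the full data set by default (mirroring
#' the study design); note that full-data selection leaks information
#' into any downstream cross-validation unless nested selection is used.
#'
#' @param rows a [compare_groups()] result.
#' @param k number of features to keep.
#' @return character vector of feature names (shorter than `k`, with a
#'   warning, when fewer valid rows exist).
#' @export
rank_features <- function(rows, k = 15L) {
  valid <- rows[!is.na(rows$effect) & !is.na(rows$p), ]
  ord <- order(-abs(valid$effect), valid$p, valid$feature)
  if (nrow(valid) < k) {
    warning("only ", nrow(valid), " valid rows; returning all")
    k <- nrow(valid)
  }
  valid$feature[ord[seq_len(k)]]
}

#' Write a Table-1-style comparison CSV
#'
#' @param rows a [compare_groups()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_compare_csv <- function(rows, path) {
  g <- attr(rows, "groups")
  fmt <- function(m, lo, hi) {
    ifelse(is.na(lo), sprintf("%.3g", m),
           sprintf("%.3g [%.3g, %.3g]", m, lo, hi))
  }
  out <- data.frame(
    feature = rows$feature,
    stats::setNames(data.frame(fmt(rows$median1, rows$q1_lo, rows$q1_hi),
                               fmt(rows$median2, rows$q2_lo, rows$q2_hi)),
                    paste0(g, "_median_IQR")),
    effect_size = rows$effect, effect_type = rows$effect_type, p = rows$p,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
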