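# Self-contained gradient-boosted trees for binary classification:
# second-order (Newton) boosting of depth-limited regression trees on the
# logistic loss, in the style of modern boosting libraries.  Exact greedy
# splits with cumulative-sum scans; deterministic given the seed.

# best split of one node: returns list(feature, threshold, gain) or NULL
gbt_best_split <- function(X, g, h, rows, lambda, min_child) {
  best <- NULL
  Gp <- sum(g[rows]); Hp <- sum(h[rows])
  parent <- Gp^2 / (Hp + lambda)
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    o <- order(x)
    xo <- x[o]
    gs <- cumsum(g[rows][o]); hs <- cumsum(h[rows][o])
    n <- length(xo)
    cand <- which(xo[-n] < xo[-1L])      # split between distinct values
    cand <- cand[cand >= min_child & (n - cand) >= min_child]
    if (!length(cand)) next
    gain <- gs[cand]^2 / (hs[cand] + lambda) +
      (Gp - gs[cand])^2 / (Hp - hs[cand] + lambda) - parent
    k <- which.max(gain)
    if (is.null(best) || gain[k] > best$gain) {
      best <- list(feature = j,
                   threshold = (xo[cand[k]] + xo[cand[k] + 1L]) / 2,
                   gain = gain[k])
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# grow one tree; returns a data.frame of nodes
gbt_grow_tree <- function(X, g, h, depth, lambda, min_child) {
  nodes <- list()
  grow <- function(rows, d) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, leaf = TRUE, feature = NA_integer_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_,
                         value = -sum(g[rows]) / (sum(h[rows]) + lambda))
    if (d >= depth || length(rows) < 2L * min_child) return(id)
    sp <- gbt_best_split(X, g, h, rows, lambda, min_child)
    if (is.null(sp)) return(id)
    lr <- rows[X[rows, sp$feature] < sp$threshold]
    rr <- setdiff(rows, lr)
    lid <- grow(lr, d + 1L)
    rid <- grow(rr, d + 1L)
    nodes[[id]]$leaf <<- FALSE
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  grow(seq_len(nrow(X)), 0L)
  nodes
}

gbt_tree_predict <- function(nodes, X) {
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    nd <- nodes[[id]]
    if (nd$leaf) { out[rows] <<- nd$value; return(invisible()) }
    left <- rows[X[rows, nd$feature] < nd$threshold]
    walk(nd$left, left)
    walk(nd$right, setdiff(rows, left))
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Fit a gradient-boosted tree classifier
#'
#' Additive regression trees fit to the logistic-loss gradients with
#' Newton leaf values (leaf = -sum g / (sum h + lambda)), shrinkage and
#' optional row subsampling.  Inputs are expected to be complete-case;
#' no native missing handling is used.
#'
#' @param X numeric matrix n x p.
#' @param y binary 0/1 vector.
#' @param n_trees,max_depth,learning_rate,subsample,lambda,min_child
#'   boosting hyperparameters (defaults: 200 trees, depth 3, rate 0.1,
#'   subsample 1, L2 leaf penalty 1, 5 rows per leaf).
#' @param seed RNG seed controlling subsampling (deterministic given the
#'   seed even when `subsample = 1`).
#' @return object of class `gbt_model`.
#' @export
fit_gradient_boosting <- function(X, y, n_trees = 200L, max_depth = 3L,
                                  learning_rate = 0.1, subsample = 1.0,
                                  lambda = 1.0, min_child = 5L,
                                  seed = 20250719L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes required")
  n <- nrow(X)
  base <- log(mean(y) / (1 - mean(y)))
  f <- rep(base, n)
  trees <- vector("list", n_trees)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-f))
    g <- p - y
    h <- pmax(p * (1 - p), 1e-6)
    rows <- if (subsample < 1) {
      sort(sample.int(n, max(2L * min_child, round(subsample * n))))
    } else seq_len(n)
    nodes <- gbt_grow_tree(X[rows, , drop = FALSE], g[rows], h[rows],
                           max_depth, lambda, min_child)
    step <- gbt_tree_predict(nodes, X)
    f <- f + learning_rate * step
    trees[[t]] <- nodes
  }
  structure(list(trees = trees, base = base,
                 learning_rate = learning_rate,
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               learning_rate = learning_rate,
                               subsample = subsample, lambda = lambda,
                               min_child = min_child, seed = seed)),
            class = "gbt_model")
}

#' Predict class-1 probabilities from a gradient-boosted model
#'
#' @param object a `gbt_model`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  f <- rep(object$base, nrow(X))
  for (nodes in object$trees) {
    f <- f + object$learning_rate * gbt_tree_predict(nodes, X)
  }
  1 / (1 + exp(-f))
}
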