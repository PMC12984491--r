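# brute-force oracles, independent of the implementations under test
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  Us <- apply(combos, 2, function(idx) {
    sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  list(U = U_obs, p = min(1, p))
}

oracle_cliffs <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

test_that("mann_whitney_u matches the printed 2x2 example", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)
  expect_equal(res$method, "exact")
})

test_that("exact Mann-Whitney equals full enumeration on small instances", {
  set.seed(101)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(100, n1 + n2)          # tie-free
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    got <- mann_whitney_u(x, y)
    want <- oracle_mw_exact(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12,
                 label = sprintf("p at n1=%d n2=%d rep=%d", n1, n2, rep))
  }
})

test_that("tied/large samples use the corrected normal approximation", {
  x <- c(1, 2, 3, 4)
  res <- mann_whitney_u(x, x)
  expect_equal(res$method, "approx")
  expect_equal(res$p, 1)

  set.seed(7)
  a <- rnorm(30); b <- rnorm(30) + 2
  res2 <- mann_whitney_u(a, b)
  expect_lt(res2$p, 1e-4)
  # missing values are dropped first
  expect_equal(mann_whitney_u(c(a, NA), c(b, NA))$p, res2$p)
})

test_that("cliffs_delta matches enumeration and its symmetries", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 3), c(2, 4)), -0.5)

  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(9)
    d <- cliffs_delta(x, y)
    expect_equal(d, oracle_cliffs(x, y), tolerance = 1e-12)
    expect_equal(cliffs_delta(y, x), -d, tolerance = 1e-12)
    expect_equal(cliffs_delta(x + 5, y + 5), d, tolerance = 1e-12)
    expect_equal(d, 2 * auc_roc(rep(1:0, c(7, 9)), c(x, y)) - 1,
                 tolerance = 1e-12)
  }
})

test_that("risk_difference is the plain difference of proportions", {
  expect_equal(risk_difference(10, 20, 5, 20), 0.25)
  expect_equal(risk_difference(6, 12, 10, 20), 0)
  expect_equal(risk_difference(20, 20, 0, 20), 1.0)
  expect_true(is.na(risk_difference(0, 0, 1, 2)))
})

test_that("compare_groups separates shifted features and handles Booleans", {
  set.seed(12)
  n <- 50
  feats <- data.frame(shifted = c(rnorm(n) + 3, rnorm(n)),
                      null = rnorm(2 * n),
                      flag_same = rep(c(TRUE, FALSE), n),
                      const = rep(1, 2 * n))
  labels <- rep(c("A", "B"), each = n)
  rows <- compare_groups(feats, labels, groups = c("A", "B"))
  sh <- rows[rows$feature == "shifted", ]
  expect_lt(sh$p, 0.001)
  expect_gt(abs(sh$effect), 0.8)
  expect_true(sh$q1_lo <= sh$median1 && sh$median1 <= sh$q1_hi)

  fl <- rows[rows$feature == "flag_same", ]
  expect_equal(fl$effect_type, "risk_difference")
  expect_equal(fl$effect, 0)

  expect_true(is.na(rows[rows$feature == "const", "p"]))
  expect_false(is.unsorted(rows$p[!is.na(rows$p)]))
})

test_that("rank_features picks top-k by |effect| with stated tie-breaks", {
  rows <- data.frame(feature = sprintf("f%02d", 1:20),
                     effect = seq(0.05, 1, length.out = 20),
                     p = rep(0.01, 20))
  expect_setequal(rank_features(rows, 15), sprintf("f%02d", 6:20))

  tie <- data.frame(feature = c("a", "b", "c"),
                    effect = c(0.5, 0.5, 0.9),
                    p = c(0.2, 0.01, 0.5))
  expect_equal(rank_features(tie, 2), c("c", "b"))

  expect_warning(out <- rank_features(tie, 15), "3 valid")
  expect_length(out, 3)
})

test_that("comparison rows export in a Table-1-like CSV", {
  set.seed(13)
  feats <- data.frame(x = rnorm(40), y = rnorm(40) + 1)
  rows <- compare_groups(feats, rep(c("G1", "G2"), 20),
                         groups = c("G1", "G2"))
  path <- file.path(tempdir(), "compare.csv")
  write_compare_csv(rows, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_true(all(c("feature", "effect_size", "p") %in% names(back)))
  expect_equal(nrow(back), 2)
})
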