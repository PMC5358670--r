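test_that("a clean two-cluster variable gets exactly one cut-point", {
  values <- c(1, 2, 3, 101, 102, 103)
  labels <- c(0, 0, 0, 1, 1, 1)
  cuts <- ebd_fit(values, labels)
  expect_length(cuts, 1)
  expect_gt(cuts, 3)
  expect_lt(cuts, 101)
  # and it attains the exhaustive optimum
  oracle <- oracle_ebd_best(values, labels)
  expect_equal(oracle_ebd_score(values, labels, cuts), oracle$score)
})

test_that("constant values and single-class labels are handled", {
  expect_equal(ebd_fit(rep(2.5, 10), rep(c(0, 1), 5)), numeric(0))
  expect_error(ebd_fit(1:10, rep(0, 10)), "two classes")
})

test_that("the dynamic program matches exhaustive cut-point enumeration", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- 12
    values <- round(rnorm(m), 2)
    labels <- sample(0:1, m, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
    for (lambda in c(0.1, 0.5, 2)) {
      cuts <- ebd_fit(values, labels, lambda = lambda)
      oracle <- oracle_ebd_best(values, labels, lambda = lambda)
      expect_equal(oracle_ebd_score(values, labels, cuts, lambda),
                   oracle$score, tolerance = 1e-10,
                   info = paste("seed", seed, "lambda", lambda))
    }
  }
})

test_that("the package scorer tracks the oracle on shuffled-label data", {
  # with labels independent of values, compare the package's score for the
  # empty scheme and for the strongest single cut against the from-scratch
  # oracle (the interesting regime: signal-free data, weak prior)
  for (seed in 1:10) {
    set.seed(100 + seed)
    values <- rnorm(40)
    labels <- sample(rep(0:1, 20))
    s0 <- oracle_ebd_score(values, labels, numeric(0))
    expect_equal(ebd_score(values, labels, numeric(0)), s0, tolerance = 1e-10)
    v <- sort(values)
    mids <- (v[-40] + v[-1]) / 2
    one_cut <- vapply(mids, function(c) {
      oracle_ebd_score(values, labels, c)
    }, numeric(1))
    j <- which.max(one_cut)
    expect_equal(ebd_score(values, labels, mids[j]), one_cut[j],
                 tolerance = 1e-10)
  }
})

test_that("ebd_fit is invariant to permutation of the input pairs", {
  set.seed(9)
  values <- rnorm(30)
  labels <- rep(0:1, 15)
  cuts <- ebd_fit(values, labels)
  perm <- sample(30)
  expect_equal(ebd_fit(values[perm], labels[perm]), cuts)
})

test_that("larger lambda never reduces the optimal number of cut-points", {
  set.seed(11)
  values <- c(rnorm(10, 0), rnorm(10, 5), rnorm(10, 10))
  labels <- rep(c(0, 1, 0), each = 10)
  k_prev <- -1L
  for (lambda in c(0.1, 0.5, 2, 10)) {
    k <- length(oracle_ebd_best(values, labels, lambda = lambda)$cuts)
    expect_gte(k, k_prev)
    # and the DP tracks the oracle at each lambda
    expect_equal(length(ebd_fit(values, labels, lambda = lambda)), k)
    k_prev <- k
  }
})

test_that("perfectly separated classes at m >= 10 yield exactly one cut", {
  set.seed(3)
  values <- c(runif(8, 0, 1), runif(8, 10, 11))
  labels <- rep(0:1, each = 8)
  expect_length(ebd_fit(values, labels), 1)
  expect_length(oracle_ebd_best(values, labels)$cuts, 1)
})

test_that("ebd_fit_all handles mixed separable/constant features", {
  ds <- two_feature_dataset(m = 20, seed = 2)
  scheme <- ebd_fit_all(ds)
  expect_gte(length(scheme$cutpoints$sep), 1)
  expect_length(scheme$cutpoints$flat, 0)
  # determinism
  expect_identical(scheme, ebd_fit_all(ds))
})

test_that("apply_scheme uses right-closed intervals and k+1 arities", {
  scheme <- structure(list(cutpoints = list(x = 5), lambda = 0.5),
                      class = "brl_scheme")
  disc <- apply_scheme(scheme, matrix(c(4, 5, 6), ncol = 1,
                                      dimnames = list(NULL, "x")),
                       labels = c("a", "b", "a"))
  expect_equal(as.integer(disc$codes), c(0L, 0L, 1L))
  expect_equal(disc$arities, 2L)

  scheme$cutpoints$x <- numeric(0)
  disc0 <- apply_scheme(scheme, matrix(c(1, 9, -3), ncol = 1,
                                       dimnames = list(NULL, "x")),
                        labels = c("a", "b", "a"))
  expect_equal(as.integer(disc0$codes), c(0L, 0L, 0L))
  expect_equal(disc0$arities, 1L)
})

test_that("out-of-range held-out values still code into [0, k]", {
  set.seed(7)
  train <- two_feature_dataset(m = 30, seed = 7)
  scheme <- ebd_fit_all(train)
  wild <- matrix(runif(40, -1e3, 1e3), ncol = 2,
                 dimnames = list(NULL, train$feature_names))
  disc <- apply_scheme(scheme, wild, labels = rep(c("a", "b"), 10))
  for (i in 1:2) {
    k <- length(scheme$cutpoints[[i]])
    expect_true(all(disc$codes[, i] >= 0 & disc$codes[, i] <= k))
    expect_equal(disc$arities[i], k + 1L)
  }
  expect_error(apply_scheme(scheme,
                            matrix(1, 1, 1, dimnames = list(NULL, "nope")),
                            labels = "a"),
               "does not cover")
})
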