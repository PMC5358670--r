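test_that("binary split enumeration covers every 2-block partition once", {
  expect_equal(enumerate_binary_splits(2), list(list(0L, 1L)))
  s3 <- enumerate_binary_splits(3)
  expect_length(s3, 3)
  canon <- lapply(s3, function(p) paste(sapply(p, paste, collapse = ","),
                                        collapse = "|"))
  expect_setequal(unlist(canon), c("0|1,2", "0,1|2", "0,2|1"))
  expect_length(enumerate_binary_splits(4), 7)
  expect_length(enumerate_binary_splits(1), 0)
  # every partition has code 0 in its first block and uses all codes
  for (p in enumerate_binary_splits(4)) {
    expect_true(0L %in% p[[1]])
    expect_setequal(unlist(p), 0:3)
  }
})

test_that("complete split yields one singleton block per value in order", {
  expect_equal(enumerate_complete_split(3), list(0L, 1L, 2L))
  expect_equal(enumerate_complete_split(2),
               lapply(enumerate_binary_splits(2)[[1]], identity))
  expect_length(enumerate_complete_split(4), 4)
})

test_that("specialize_leaf evaluates the right number of candidate splits", {
  data <- random_discrete(30, c(2L, 3L), 42)
  base <- singleton_model(data, 1L)
  brlearn:::reset_eval_counter()
  cand <- specialize_leaf(base, 1L, 2L, data)
  expect_equal(brlearn:::.search_env$evals, 4L) # 3 binary + 1 complete
  # full-tree rescore agrees with the incrementally computed score
  expect_equal(brlearn:::score_tree(cand$tree, data), cand$logscore,
               tolerance = 1e-12)

  data2 <- random_discrete(30, c(2L, 2L), 43)
  base2 <- singleton_model(data2, 1L)
  brlearn:::reset_eval_counter()
  cand2 <- specialize_leaf(base2, 1L, 2L, data2)
  expect_equal(brlearn:::.search_env$evals, 1L) # binary == complete
  expect_equal(brlearn:::score_tree(cand2$tree, data2), cand2$logscore,
               tolerance = 1e-12)

  # a worse candidate is still returned; acceptance is the caller's call
  expect_true(is.finite(cand2$logscore))
  expect_error(specialize_leaf(cand, 1L, 1L, data), "already on")
})

test_that("LSS recovers a predictor the target copies exactly", {
  set.seed(5)
  m <- 20
  codes <- cbind(sample(0:1, m, TRUE), vapply(1:5, function(i) {
    sample(0:1, m, TRUE)
  }, integer(m)))
  data <- brl_discrete(codes, rep(2L, 6), target_codes = codes[, 1],
                       target_arity = 2L)
  res <- lss_search(data, maxConj = 3)
  expect_equal(res$used_variables, 1L)
  expect_equal(res$n_leaves, 2L)
  expect_equal(res$logscore, oracle_lss_depth2_best_score(data),
               tolerance = 1e-10)
})

test_that("LSS beats every depth-1 model on XOR-structured data", {
  set.seed(8)
  m <- 40
  x1 <- sample(0:1, m, TRUE); x2 <- sample(0:1, m, TRUE)
  y <- as.integer(xor(x1, x2))
  noise <- vapply(1:3, function(i) sample(0:1, m, TRUE), integer(m))
  data <- brl_discrete(cbind(x1, x2, noise), rep(2L, 5), y, 2L)
  res <- lss_search(data, maxConj = 3)
  # every depth-1 (singleton) model in the exhaustive space scores lower
  singles <- vapply(1:5, function(v) singleton_model(data, v)$logscore,
                    numeric(1))
  expect_true(all(res$logscore >= singles))
  expect_setequal(res$used_variables, 1:2)
})

test_that("LSS merges contexts with identical class distributions", {
  # two binary genes; the class distribution under geneA=DOWN is the same
  # for both values of geneB, so the local tree needs only 3 leaves
  cells <- rbind(c(0.89, 0.11),  # A=UP,   B=UP
                 c(0.11, 0.89),  # A=UP,   B=DOWN
                 c(0.34, 0.66),  # A=DOWN, B=UP
                 c(0.34, 0.66))  # A=DOWN, B=DOWN
  data <- generate_cell_data(cells, c(2L, 2L), m = 400, seed = 17,
                             feature_names = c("geneA", "geneB"))
  res <- lss_search(data, maxConj = 2)
  expect_equal(res$n_leaves, 3L)
  expect_setequal(res$used_variables, 1:2)
})

test_that("GSS equals exhaustive parent-set enumeration on small spaces", {
  for (seed in 1:5) {
    data <- random_discrete(16, c(2L, 2L, 2L), seed)
    res <- gss_search(data, maxConj = 3, beamWidth = 100)
    expect_equal(res$logscore, oracle_gss_best_score(data),
                 tolerance = 1e-10, info = paste("seed", seed))
  }
  data4 <- random_discrete(20, c(2L, 3L, 2L, 2L), 99)
  res4 <- gss_search(data4, maxConj = 4, beamWidth = 100)
  expect_equal(res4$logscore, oracle_gss_best_score(data4), tolerance = 1e-10)
})

test_that("GSS trees are full expansions: leaf count is the arity product", {
  # class is the parity of x1 (arity 3) + x2 (arity 4): both parents are
  # needed, neither is marginally informative
  set.seed(21)
  m <- 240
  x1 <- sample(0:2, m, TRUE); x2 <- sample(0:3, m, TRUE)
  y <- (x1 + x2) %% 2
  data <- brl_discrete(cbind(x1, x2), c(3L, 4L), y, 2L)
  res <- gss_search(data, maxConj = 2)
  expect_setequal(res$used_variables, 1:2)
  expect_equal(res$n_leaves, 12L)

  x3 <- sample(0:1, m, TRUE)
  y3 <- (x1 + x2 + x3) %% 2
  data3 <- brl_discrete(cbind(x3, x1, x2), c(2L, 3L, 4L), y3, 2L)
  res3 <- gss_search(data3, maxConj = 3)
  expect_setequal(res3$used_variables, 1:3)
  expect_equal(res3$n_leaves, 24L)
})

test_that("LSS and GSS coincide when the best model is depth-1 and binary", {
  set.seed(31)
  m <- 40
  x1 <- sample(0:1, m, TRUE)
  noise <- vapply(1:4, function(i) sample(0:1, m, TRUE), integer(m))
  data <- brl_discrete(cbind(x1, noise), rep(2L, 5), x1, 2L)
  l <- lss_search(data, maxConj = 3)
  g <- gss_search(data, maxConj = 3)
  expect_equal(l$logscore, g$logscore, tolerance = 1e-10)
  expect_equal(l$used_variables, g$used_variables)
})

test_that("returned trees are valid and their leaves cover all instances", {
  for (seed in c(2, 12)) {
    data <- random_discrete(30, c(2L, 3L, 2L, 4L), seed)
    for (res in list(lss_search(data, maxConj = 3),
                     gss_search(data, maxConj = 3))) {
      expect_true(brlearn:::validate_tree(res$tree$root, data))
      leaves <- brlearn:::tree_leaves(res$tree$root)
      expect_equal(sum(vapply(leaves, function(l) sum(l$counts), numeric(1))),
                   30)
    }
  }
})

test_that("searches are deterministic and noise-only data yields one leaf", {
  data <- random_discrete(40, c(3L, 2L, 2L), 77)
  r1 <- lss_search(data); r2 <- lss_search(data)
  expect_identical(r1$logscore, r2$logscore)
  expect_identical(brlearn:::tree_signature(r1$tree$root),
                   brlearn:::tree_signature(r2$tree$root))
  g1 <- gss_search(data); g2 <- gss_search(data)
  expect_identical(g1$used_variables, g2$used_variables)

  flat <- brl_discrete(matrix(0L, 10, 2), c(1L, 1L),
                       rep(c(0L, 1L), 5), 2L)
  expect_equal(lss_search(flat)$n_leaves, 1L)
  expect_equal(gss_search(flat)$n_leaves, 1L)
})

test_that("doubling the variable count at most quadruples split evaluations", {
  make <- function(n, seed) {
    set.seed(seed)
    m <- 60
    x1 <- sample(0:1, m, TRUE)
    y <- ifelse(runif(m) < 0.9, x1, 1 - x1)
    noise <- vapply(seq_len(n - 1), function(i) sample(0:1, m, TRUE),
                    integer(m))
    brl_discrete(cbind(x1, noise), rep(2L, n), as.integer(y), 2L)
  }
  r8 <- lss_search(make(8, 4), maxConj = 4)
  r16 <- lss_search(make(16, 4), maxConj = 4)
  expect_lte(attr(r16, "n_evals") / attr(r8, "n_evals"), 4)
})
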