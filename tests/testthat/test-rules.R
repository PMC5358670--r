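# Discrete fixture shaped like the two-binary-gene worked example: leaf
# counts are chosen directly so the evidence pairs are exact.
fig_tree_data <- function() {
  # cells (A,B): (0,0) -> (50,5); (0,1) -> (2,18); (1,0) -> (17,33);
  # (1,1) -> (17,33) scaled down
  cell <- rbind(c(50, 5), c(2, 18), c(17, 33), c(17, 33))
  codes <- NULL; y <- NULL
  for (j in 1:4) {
    a <- (j - 1) %/% 2; b <- (j - 1) %% 2
    n <- sum(cell[j, ])
    codes <- rbind(codes, matrix(c(rep(a, n), rep(b, n)), ncol = 2))
    y <- c(y, rep(0L, cell[j, 1]), rep(1L, cell[j, 2]))
  }
  brl_discrete(codes, c(2L, 2L), y, 2L,
               feature_names = c("geneA", "geneB"),
               class_levels = c("true", "false"),
               value_labels = list(c("UP", "DOWN"), c("UP", "DOWN")))
}

test_that("a fully expanded two-binary-parent tree yields 4 rules", {
  data <- fig_tree_data()
  rb <- tree_to_rules(expand_parents(data, 1:2), data)
  expect_equal(unname(parsimony(rb)), c(4L, 2L))
  expect_equal(parsimony(rb)[["n_rules"]], 4L)
})

test_that("evidence (50, 5) smooths to probability 0.89 and odds 8.5", {
  data <- fig_tree_data()
  rb <- tree_to_rules(expand_parents(data, 1:2), data, alpha = 1)
  r1 <- rb$rules[[1]] # highest posterior odds first
  expect_equal(r1$tp, 50L)
  expect_equal(r1$fp, 5L)
  expect_equal(r1$posterior_probability, 51 / 57)
  expect_equal(sprintf("%.2f", r1$posterior_probability), "0.89")
  expect_equal(r1$posterior_odds, 51 / 6)
  expect_equal(r1$posterior_odds, 8.5)
  expect_equal(rb$class_levels[r1$predicted_class + 1], "true")
})

test_that("merged local trees drop to 3 rules with a bare geneA=DOWN rule", {
  cells <- rbind(c(0.89, 0.11), c(0.11, 0.89), c(0.34, 0.66), c(0.34, 0.66))
  data <- generate_cell_data(cells, c(2L, 2L), m = 400, seed = 17,
                             feature_names = c("geneA", "geneB"))
  global_rb <- tree_to_rules(expand_parents(data, 1:2), data)
  local_rb <- tree_to_rules(lss_search(data, maxConj = 2), data)
  expect_equal(parsimony(global_rb)[["n_rules"]], 4L)
  expect_equal(parsimony(local_rb)[["n_rules"]], 3L)
  n_conj <- vapply(local_rb$rules, function(r) length(r$antecedent),
                   integer(1))
  expect_equal(sort(n_conj), c(1L, 2L, 2L))
  solo <- local_rb$rules[[which(n_conj == 1)]]
  expect_equal(solo$antecedent[[1]]$var, 1L) # geneA alone
})

test_that("prediction routes each instance to exactly one rule", {
  data <- fig_tree_data()
  rb <- tree_to_rules(expand_parents(data, 1:2), data)
  # instance matching the (50,5) rule
  pred <- predict(rb, matrix(c(0L, 0L), 1, 2,
                             dimnames = list(NULL, c("geneA", "geneB"))))
  expect_equal(pred$class, "true")
  expect_equal(pred$probability, 51 / 57)
  # every joint assignment matches exactly one rule
  grid <- as.matrix(expand.grid(geneA = 0:1, geneB = 0:1))
  for (s in seq_len(nrow(grid))) {
    hits <- brlearn:::matching_rules(rb, grid[s, ])
    expect_length(hits, 1)
  }
})

test_that("zero-evidence rules predict the majority class at probability 1/2", {
  # target depends only on geneA; geneB value 1 never occurs with geneA=1
  codes <- cbind(c(0, 0, 0, 0, 1, 1, 1, 1), c(0, 1, 0, 1, 0, 0, 0, 0))
  y <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L)
  data <- brl_discrete(codes, c(2L, 2L), y, 2L,
                       class_levels = c("neg", "pos"))
  rb <- tree_to_rules(expand_parents(data, 1:2), data)
  empty <- Filter(function(r) sum(r$counts) == 0, rb$rules)
  expect_length(empty, 1)
  expect_equal(empty[[1]]$posterior_probability, 0.5)
  expect_equal(empty[[1]]$predicted_class, rb$majority_class)
  expect_equal(rb$class_levels[rb$majority_class + 1], "neg")
})

test_that("rule bases are mutually exclusive and exhaustive", {
  for (seed in 1:4) {
    data <- random_discrete(40, c(2L, 3L, 2L), seed)
    rb <- tree_to_rules(lss_search(data, maxConj = 3), data)
    # full enumeration of the joint value space
    grid <- as.matrix(expand.grid(lapply(data$arities, function(r) {
      seq_len(r) - 1L
    })))
    colnames(grid) <- data$feature_names
    for (s in seq_len(nrow(grid))) {
      expect_length(brlearn:::matching_rules(rb, grid[s, ]), 1)
    }
    # evidence reconstructs the training class marginals
    totals <- Reduce(`+`, lapply(rb$rules, `[[`, "counts"))
    expect_equal(totals, brlearn:::target_marginals(data))
  }
})

test_that("posterior probability is monotone in TP and FP", {
  probs_tp <- vapply(1:20, function(tp) (tp + 1) / ((tp + 1) + (5 + 1)),
                     numeric(1))
  expect_true(all(diff(probs_tp) > 0))
  probs_fp <- vapply(1:20, function(fp) (50 + 1) / ((50 + 1) + (fp + 1)),
                     numeric(1))
  expect_true(all(diff(probs_fp) < 0))
  # and the package computes the same functional form
  data <- fig_tree_data()
  rb <- tree_to_rules(expand_parents(data, 1:2), data)
  for (r in rb$rules) {
    expect_equal(r$posterior_probability,
                 (r$tp + 1) / ((r$tp + 1) + (r$fp + 1)))
    expect_equal(r$posterior_odds, (r$tp + 1) / (r$fp + 1))
  }
})

test_that("prediction on instances missing used variables fails clearly", {
  data <- fig_tree_data()
  rb <- tree_to_rules(expand_parents(data, 1:2), data)
  bad <- matrix(0L, 1, 1, dimnames = list(NULL, "geneA"))
  expect_error(predict(rb, bad), "geneB")
})

test_that("an empty-antecedent rule base counts (1, 0) for parsimony", {
  codes <- matrix(0L, nrow = 6, ncol = 1)
  data <- brl_discrete(codes, 1L, rep(c(0L, 1L), 3), 2L)
  rb <- tree_to_rules(lss_search(data), data)
  expect_equal(unname(parsimony(rb)), c(1L, 0L))
})
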