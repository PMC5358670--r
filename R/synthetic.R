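#' Simulate expression-like data with planted discriminative features
#'
#' Generates a continuous m-by-n matrix emulating a high-dimensional
#' gene-expression study in which only a small planted subset of features
#' carries class information. Noise features are class-independent Gaussians;
#' informative features receive a class-conditional mean shift (expressed in
#' units of the feature's standard deviation, so the effect size is
#' scale-free). At `rule_depth = 2` the class depends on the joint
#' configuration of a feature pair (an XOR-style interaction): each feature of
#' the pair is marginally uninformative.
#'
#' @param m Number of samples.
#' @param n Number of features.
#' @param informative For depth 1: list of `list(index, shift, sd)` entries
#'   (or a bare integer vector of indices, with `shift`/`sd` defaults), giving
#'   the feature index, the between-class mean shift in sd units, and the
#'   noise sd. For depth 2 the first two entries form the interacting pair.
#'   May be empty (pure noise).
#' @param rule_depth 1 (marginal effects, default) or 2 (pairwise
#'   interaction).
#' @param class_balance Proportion of samples in the positive class
#'   (default 0.5).
#' @param shift Default mean shift in sd units (3) used when `informative` is
#'   given as bare indices.
#' @param sd Default noise sd (1).
#' @param seed Integer seed; the full draw is deterministic given it.
#' @param class_levels Labels for the two classes.
#' @return A list with `dataset` (a [brl_dataset]) and `truth` (a list
#'   recording the planted features, shifts, depth and seed).
#' @export
brl_simulate <- function(m, n, informative = list(), rule_depth = 1L,
                         class_balance = 0.5, shift = 3, sd = 1, seed = 1L,
                         class_levels = c("control", "case")) {
  stopifnot(m >= 2, n >= 1, rule_depth %in% c(1L, 2L),
            class_balance > 0, class_balance < 1)
  if (is.numeric(informative) && !is.list(informative)) {
    informative <- lapply(informative, function(i) {
      list(index = as.integer(i), shift = shift, sd = sd)
    })
  }
  informative <- lapply(informative, function(e) {
    e$index <- as.integer(e$index)
    if (is.null(e$shift)) e$shift <- shift
    if (is.null(e$sd)) e$sd <- sd
    if (e$index < 1L || e$index > n) stop("informative index out of range", call. = FALSE)
    if (e$sd <= 0) stop("noise sd must be positive", call. = FALSE)
    e
  })
  if (rule_depth == 2L && length(informative) < 2L) {
    stop("rule_depth 2 needs at least two informative features", call. = FALSE)
  }
  rng <- local_rng(seed)
  y <- as.integer(rng$runif(m) < class_balance) # 1 = positive class
  values <- matrix(rng$rnorm(m * n), nrow = m, ncol = n)
  colnames(values) <- sprintf("gene%03d", seq_len(n))

  if (rule_depth == 1L) {
    for (e in informative) {
      values[, e$index] <- e$sd * values[, e$index] + e$shift * e$sd * y
    }
  } else {
    # joint configuration of the pair determines the class-conditional means:
    # positive class concentrates on the (hi,hi)/(lo,lo) diagonal, negative on
    # the off-diagonal, so neither feature is marginally shifted
    e1 <- informative[[1L]]; e2 <- informative[[2L]]
    arm <- as.integer(rng$runif(m) < 0.5) # which diagonal cell
    s1 <- ifelse(y == 1L, ifelse(arm == 1L, 1, -1), ifelse(arm == 1L, 1, -1) * -1)
    s2 <- ifelse(y == 1L, ifelse(arm == 1L, 1, -1), ifelse(arm == 1L, 1, -1))
    values[, e1$index] <- e1$sd * values[, e1$index] + e1$shift * e1$sd * s1 / 2
    values[, e2$index] <- e2$sd * values[, e2$index] + e2$shift * e2$sd * s2 / 2
  }
  labels <- class_levels[y + 1L]
  # guard against a degenerate draw at tiny m
  if (length(unique(labels)) < 2L) {
    y[1L] <- 1L - y[1L]
    labels <- class_levels[y + 1L]
  }
  dataset <- brl_dataset(values, labels, class_name = "class")
  truth <- list(informative = informative, rule_depth = rule_depth,
                class_balance = class_balance, seed = seed,
                positive_class = class_levels[2L])
  list(dataset = dataset, truth = truth)
}

#' Sample a discrete dataset from per-cell class distributions
#'
#' Draws instances over a small set of discrete predictors whose joint
#' configuration ("cell") determines the class distribution — the setting in
#' which local CPT structure pays off: when two cells share a class
#' distribution, a local tree can cover them with one merged leaf. Predictor
#' configurations are sampled uniformly.
#'
#' @param cell_probs Numeric matrix (or data frame) with one row per joint
#'   predictor configuration and one column per class; rows must sum to 1.
#'   Rows are ordered with the first predictor varying slowest.
#' @param arities Integer vector of predictor arities; `prod(arities)` must
#'   equal `nrow(cell_probs)`.
#' @param m Number of instances (>= 1).
#' @param seed Integer seed.
#' @param feature_names Optional predictor names.
#' @param class_levels Optional class names.
#' @return A [brl_discrete] dataset.
#' @export
generate_cell_data <- function(cell_probs, arities, m, seed = 1L,
                               feature_names = NULL, class_levels = NULL) {
  cell_probs <- as.matrix(cell_probs)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (any(cell_probs < 0) || any(cell_probs > 1)) {
    stop("cell probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(cell_probs) - 1) > 1e-8)) {
    stop("each cell's class probabilities must sum to 1", call. = FALSE)
  }
  arities <- as.integer(arities)
  J <- prod(arities)
  if (J != nrow(cell_probs)) {
    stop("prod(arities) must equal nrow(cell_probs)", call. = FALSE)
  }
  C <- ncol(cell_probs)
  n <- length(arities)
  rng <- local_rng(seed)
  cells <- rng$sample_int(J, m, replace = TRUE)
  codes <- matrix(0L, nrow = m, ncol = n)
  rest <- cells - 1L
  for (i in n:1) { # first predictor varies slowest
    codes[, i] <- rest %% arities[i]
    rest <- rest %/% arities[i]
  }
  u <- rng$runif(m)
  cum <- t(apply(cell_probs, 1L, cumsum))
  y <- integer(m)
  for (s in seq_len(m)) {
    y[s] <- findInterval(u[s], cum[cells[s], ], left.open = FALSE)
  }
  y <- pmin(y, C - 1L)
  if (is.null(feature_names)) feature_names <- paste0("X", seq_len(n))
  if (is.null(class_levels)) class_levels <- paste0("class", seq_len(C) - 1L)
  brl_discrete(codes, arities, target_codes = y, target_arity = C,
               feature_names = feature_names, class_levels = class_levels)
}
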