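#' Stratified k-fold partition of sample indices
#'
#' Samples are shuffled within each class (deterministically, from `seed`) and
#' dealt round-robin into `k` folds, so per-fold class proportions match the
#' global proportions to within one instance per class.
#'
#' @param labels Vector of class labels (any type; coerced to factor).
#' @param k Number of folds (>= 2, <= number of samples).
#' @param seed Integer seed controlling the within-class shuffle.
#' @return List of `k` integer index vectors, pairwise disjoint, whose union
#'   is `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  m <- length(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > m) stop("k (", k, ") exceeds the number of samples (", m, ")",
                  call. = FALSE)
  labels <- factor(labels)
  folds <- vector("list", k)
  rng <- local_rng(seed)
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    idx <- idx[rng$sample_perm(length(idx))]
    for (j in seq_along(idx)) {
      f <- ((j - 1L) %% k) + 1L
      folds[[f]] <- c(folds[[f]], idx[j])
    }
  }
  lapply(folds, sort)
}

# Seeded RNG that does not disturb the caller's global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    fn()
  }
  list(
    sample_perm = function(n) with_state(function() sample.int(n)),
    runif = function(n) with_state(function() stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size, replace = FALSE, prob = NULL) {
      with_state(function() sample.int(n, size, replace = replace, prob = prob))
    }
  )
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from the rank statistic: the probability
#' that a randomly chosen positive scores above a randomly chosen negative,
#' with tied scores counting one half.
#'
#' @param scores Numeric vector of predicted scores (higher = more positive).
#' @param labels Logical or 0/1 vector marking the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC is undefined when one class is absent", call. = FALSE)
  }
  r <- rank(scores) # ties averaged -> half credit for tied pairs
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One-vs-rest macro-averaged AUC for >= 2 classes. `probs` has one column per
# class level (the matched rule's smoothed class distribution).
macro_auc <- function(probs, labels, class_levels) {
  if (length(class_levels) == 2L) {
    pos <- class_levels[2L]
    return(auc_score(probs[, 2L], labels == pos))
  }
  aucs <- c()
  for (j in seq_along(class_levels)) {
    y <- labels == class_levels[j]
    if (any(y) && any(!y)) aucs <- c(aucs, auc_score(probs[, j], y))
  }
  mean(aucs)
}

#' Stratified cross-validation of a BRL model
#'
#' For each fold: fit the discretization scheme on the training split only,
#' train a model with the chosen search, predict the held-out split, and
#' record AUC, accuracy (percent), number of rules and number of distinct
#' variables. The summary reports the across-fold mean and standard error of
#' the mean (sample standard deviation divided by the square root of the
#' number of folds). Folds whose training split contains a single class are
#' skipped with a warning.
#'
#' For binary problems the AUC score is the predicted probability of the
#' second class level; with more classes a one-vs-rest macro average is
#' reported.
#'
#' @param dataset A [brl_dataset].
#' @param method `"lss"` or `"gss"`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment (default 1).
#' @inheritParams brl_train
#' @return An object of class `brl_cv`: a list with `folds` (data frame of
#'   per-fold metrics) and `summary` (data frame with mean and SEM per
#'   metric), plus the run parameters.
#' @export
run_cv <- function(dataset, method = c("lss", "gss"), k = 10L, seed = 1L,
                   maxConj = 8L, beamWidth = 1000L, lambda = 0.5, alpha = 1,
                   max_intervals = 16L) {
  stopifnot(inherits(dataset, "brl_dataset"))
  method <- match.arg(method)
  labels <- dataset$class_labels
  folds <- stratified_folds(labels, k, seed)
  class_levels <- levels(labels)

  rows <- list()
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    train_labels <- labels[train_idx]
    if (length(unique(train_labels)) < 2L) {
      warning("fold ", f, " skipped: training split has a single class")
      next
    }
    train <- subset_dataset(dataset, train_idx)
    fit <- brl_train(train, method = method, maxConj = maxConj,
                     beamWidth = beamWidth, lambda = lambda, alpha = alpha,
                     max_intervals = max_intervals)
    pred <- predict(fit, dataset$values[test_idx, , drop = FALSE])
    truth <- as.character(labels[test_idx])
    acc <- 100 * mean(pred$class == truth)
    prob_cols <- paste0("prob_", levels(train$class_labels))
    auc <- tryCatch(
      macro_auc(as.matrix(pred[prob_cols]), truth,
                levels(train$class_labels)),
      error = function(e) NA_real_
    )
    p <- parsimony(fit$rulebase)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, auc = auc, accuracy = acc,
      n_rules = p[["n_rules"]], n_variables = p[["n_variables"]],
      features = paste(used_feature_names(fit$rulebase), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("every fold was skipped", call. = FALSE)
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL

  metrics <- c("auc", "accuracy", "n_rules", "n_variables")
  mean_v <- vapply(metrics, function(mt) mean(per_fold[[mt]], na.rm = TRUE),
                   numeric(1))
  sem_v <- vapply(metrics, function(mt) {
    x <- per_fold[[mt]][!is.na(per_fold[[mt]])]
    if (length(x) < 2L) return(0)
    stats::sd(x) / sqrt(length(x))
  }, numeric(1))
  summary <- data.frame(metric = metrics, mean = unname(mean_v),
                        sem = unname(sem_v))
  structure(
    list(folds = per_fold, summary = summary, method = method, k = k,
         seed = seed,
         params = list(maxConj = maxConj, beamWidth = beamWidth,
                       lambda = lambda, alpha = alpha)),
    class = "brl_cv"
  )
}

#' @export
print.brl_cv <- function(x, ...) {
  cat("Stratified ", x$k, "-fold cross-validation (", toupper(x$method),
      ", seed ", x$seed, ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %8.4f +/- %.4f (SEM)\n", s$metric[i], s$mean[i],
                s$sem[i]))
  }
  invisible(x)
}
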