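#' K2 log score of a single leaf (parent configuration)
#'
#' The K2 metric's contribution of one parent configuration with class-count
#' vector \eqn{N_{jk}}: \eqn{\log[(r_t - 1)! / (N_j + r_t - 1)! \prod_k N_{jk}!]}
#' with \eqn{r_t} the number of target classes and \eqn{N_j = \sum_k N_{jk}}.
#' Computed via log-gamma, so it stays finite up to very large counts. An
#' empty leaf (all counts zero) contributes 0 (a unit factor).
#'
#' @param counts Non-negative integer vector of per-class counts in the leaf.
#' @param target_arity Number of target classes (>= 2). Defaults to
#'   `length(counts)`.
#' @return The leaf's log marginal-likelihood contribution (single numeric).
#' @export
k2_leaf_logscore <- function(counts, target_arity = length(counts)) {
  if (target_arity < 2L) stop("target_arity must be >= 2", call. = FALSE)
  if (length(counts) != target_arity) {
    stop("counts must have one entry per target class", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts are invalid", call. = FALSE)
  N <- sum(counts)
  lgamma(target_arity) - lgamma(N + target_arity) + sum(lgamma(counts + 1))
}

#' K2 log score of a model from its leaf counts
#'
#' Sums [k2_leaf_logscore()] over the leaves of a CPT tree. The leaves must
#' partition the training instances: the leaf totals must sum to `m` when it
#' is supplied.
#'
#' @param leaves List of per-class count vectors, one per leaf.
#' @param target_arity Number of target classes.
#' @param m Optional total number of training instances; when given, coverage
#'   (sum of leaf totals == m) is verified.
#' @return The model's K2 log score.
#' @export
k2_model_logscore <- function(leaves, target_arity, m = NULL) {
  tot <- sum(vapply(leaves, sum, numeric(1)))
  if (!is.null(m) && tot != m) {
    stop("leaves cover ", tot, " instances but the dataset has ", m,
         " (leaves must partition the data)", call. = FALSE)
  }
  sum(vapply(leaves, k2_leaf_logscore, numeric(1),
             target_arity = target_arity))
}

#' Count class matches of a rule antecedent
#'
#' Returns the per-class counts of instances satisfying every conjunct of an
#' antecedent, each conjunct being a variable index paired with a set of
#' admissible value codes.
#'
#' @param data A [brl_discrete] dataset.
#' @param antecedent List of conjuncts, each `list(var = i, codes = c(...))`
#'   with 1-based variable index and 0-based codes. An empty list matches
#'   every instance.
#' @return Integer vector of length `target_arity`: class counts among
#'   matching instances.
#' @export
count_matches <- function(data, antecedent) {
  stopifnot(inherits(data, "brl_discrete"))
  keep <- rep(TRUE, nrow(data$codes))
  for (cj in antecedent) {
    keep <- keep & (data$codes[, cj$var] %in% cj$codes)
  }
  tabulate(data$target_codes[keep] + 1L, nbins = data$target_arity)
}

# Class counts for a set of row indices.
class_counts_at <- function(data, idx) {
  tabulate(data$target_codes[idx] + 1L, nbins = data$target_arity)
}
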