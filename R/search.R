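## Beam-based structure search over target-centric Bayesian networks.
## Two regimes share the K2 score and the beam:
##  - gss_search: parent-set search; each model's CPT is the fully expanded
##    tree over its parents (one leaf per joint parent assignment).
##  - lss_search: local-structure search; models are decision-tree CPTs grown
##    by per-leaf binary and complete splits, so contexts with identical class
##    distributions need never be separated.

.score_eps <- 1e-9 # a specialization must beat this margin to count as better

new_candidate <- function(tree, logscore, id = 0L) {
  structure(list(tree = tree, logscore = logscore,
                 used_variables = tree$used_variables,
                 n_leaves = tree_n_leaves(tree$root), id = as.integer(id)),
            class = "brl_candidate")
}

#' @export
print.brl_candidate <- function(x, ...) {
  cat("Candidate model: log score ", format(x$logscore), ", ",
      x$n_leaves, " leaves, variables {",
      paste(x$used_variables, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Ordering used everywhere models compete: higher score first; ties go to
# fewer used variables, then fewer leaves, then earlier insertion.
candidate_order <- function(models) {
  score <- vapply(models, `[[`, numeric(1), "logscore")
  nvar <- vapply(models, function(m) length(m$used_variables), integer(1))
  nleaf <- vapply(models, function(m) as.numeric(m$n_leaves), numeric(1))
  id <- vapply(models, function(m) as.integer(m$id), integer(1))
  order(-score, nvar, nleaf, id)
}

better_candidate <- function(a, b) {
  # is `a` preferred over `b`?
  if (is.null(b)) return(TRUE)
  ord <- candidate_order(list(a, b))
  ord[1L] == 1L
}

# Capacity-bounded, score-ordered model store with structural dedup.
beam_new <- function(capacity) {
  list(capacity = as.integer(capacity), items = list(), keys = character(0))
}

beam_insert <- function(beam, model, key) {
  if (key %in% beam$keys) return(beam)
  beam$items <- c(beam$items, list(model))
  beam$keys <- c(beam$keys, key)
  if (length(beam$items) > beam$capacity) {
    ord <- candidate_order(beam$items)
    keep <- ord[seq_len(beam$capacity)]
    beam$items <- beam$items[keep]
    beam$keys <- beam$keys[keep]
  }
  beam
}

beam_pop <- function(beam) {
  ord <- candidate_order(beam$items)
  i <- ord[1L]
  model <- beam$items[[i]]
  beam$items <- beam$items[-i]
  beam$keys <- beam$keys[-i]
  list(model = model, beam = beam)
}

#' Best split of one variable at one leaf
#'
#' Evaluates every binary split of `variable` (all two-block partitions of its
#' value set) plus, when the arity exceeds 2, the complete split, applied at
#' the given leaf of the model's CPT tree. Only the affected leaf is
#' re-counted; the rest of the tree's score is reused. The highest-scoring
#' resulting model is returned regardless of whether it improves on the input
#' model — accepting or rejecting it is the caller's decision.
#'
#' @param model A `brl_candidate` (as produced by the searches or
#'   [singleton_model()]).
#' @param leaf Index of the leaf to split, as a position in the model's leaf
#'   list (depth-first order).
#' @param variable 1-based variable index; must not already lie on the leaf's
#'   path.
#' @param data The [brl_discrete] training data.
#' @return The best resulting `brl_candidate`.
#' @export
specialize_leaf <- function(model, leaf, variable, data) {
  leaves <- tree_leaves(model$tree$root)
  if (leaf < 1L || leaf > length(leaves)) stop("no such leaf", call. = FALSE)
  lf <- leaves[[leaf]]
  if (variable %in% lf$vars) {
    stop("variable ", variable, " is already on this leaf's path", call. = FALSE)
  }
  arity <- data$arities[variable]
  if (arity < 2L) stop("cannot split a variable of arity 1", call. = FALSE)

  partitions <- enumerate_binary_splits(arity)
  if (arity > 2L) partitions <- c(partitions, list(enumerate_complete_split(arity)))

  old_leaf_score <- k2_leaf_logscore(lf$counts, data$target_arity)
  base <- model$logscore - old_leaf_score

  cnt <- leaf_cell_counts(data, lf$idx, variable)
  best <- best_split_from_cells(cnt, partitions)
  best_score <- base + best$score
  blocks <- partitions[[best$which]]
  parts <- split_indices(data, lf$idx, variable, blocks)
  kids <- lapply(parts, function(p) new_leaf(class_counts_at(data, p), p))
  sub <- new_internal(variable, blocks, kids)
  root <- replace_node(model$tree$root, lf$path, sub)
  new_candidate(new_cpt_tree(root, "local"), best_score, model$id)
}

# Per-class x per-code count matrix of the rows `idx` on variable `var`.
leaf_cell_counts <- function(data, idx, var) {
  C <- data$target_arity
  r <- data$arities[var]
  tab <- tabulate(data$codes[idx, var] * C + data$target_codes[idx] + 1L,
                  nbins = r * C)
  matrix(tab, nrow = C) # column per code
}

# K2 leaf score without argument checking (search hot path).
k2_fast <- function(counts, C) {
  lgamma(C) - lgamma(sum(counts) + C) + sum(lgamma(counts + 1))
}

# 0/1 membership matrix of the first block of every binary partition of the
# codes 0..r-1, columns aligned with enumerate_binary_splits(r). Cached.
binary_split_masks <- function(r) {
  key <- as.character(r)
  if (!is.null(.search_env$masks[[key]])) return(.search_env$masks[[key]])
  parts <- enumerate_binary_splits(r)
  mask <- matrix(0, nrow = r, ncol = length(parts))
  for (j in seq_along(parts)) mask[parts[[j]][[1L]] + 1L, j] <- 1
  .search_env$masks[[key]] <- mask
  mask
}

# Score every partition of the variable's codes from the cell-count matrix
# (class x code) and return the best (first wins on ties). All binary splits
# are scored in one pass of matrix arithmetic; when the arity exceeds 2 the
# complete split is appended as the last candidate, matching the ordering of
# the `partitions` lists used by the searches. One evaluation per partition
# is counted toward the search's work counter.
best_split_from_cells <- function(cnt, partitions) {
  C <- nrow(cnt)
  r <- ncol(cnt)
  mask <- binary_split_masks(r)
  M1 <- cnt %*% mask
  M0 <- rowSums(cnt) - M1
  two_block <- function(M) {
    lgamma(C) - lgamma(colSums(M) + C) + colSums(lgamma(M + 1))
  }
  scores <- two_block(M1) + two_block(M0)
  if (r > 2L) {
    complete <- r * lgamma(C) - sum(lgamma(colSums(cnt) + C)) +
      sum(lgamma(cnt + 1))
    scores <- c(scores, complete)
  }
  .search_env$evals <- .search_env$evals + length(scores)
  best_i <- which.max(scores) # first maximum on ties
  list(score = scores[best_i], which = best_i)
}

#' Fully expanded CPT model over a given parent set
#'
#' Builds the global-structure model whose CPT tree is the complete expansion
#' over the given parents: one leaf per joint parent assignment, so the number
#' of leaves (and of rules after [tree_to_rules()]) is the product of the
#' parent arities.
#'
#' @param data A [brl_discrete] dataset.
#' @param parents Integer vector of 1-based variable indices.
#' @return A `brl_candidate` scored on `data`.
#' @export
expand_parents <- function(data, parents) {
  stopifnot(inherits(data, "brl_discrete"))
  tree <- full_cpt_tree(data, parents)
  new_candidate(tree, score_tree(tree, data))
}

#' Singleton model for one predictor
#'
#' The depth-1 model whose root is the complete split of one variable — the
#' seed models of both searches.
#'
#' @param data A [brl_discrete] dataset.
#' @param variable 1-based variable index with arity >= 2.
#' @param kind `"local"` or `"global"` tree bookkeeping.
#' @return A `brl_candidate`.
#' @export
singleton_model <- function(data, variable, kind = "local") {
  tree <- full_cpt_tree(data, variable)
  tree$structure_kind <- kind
  new_candidate(tree, score_tree(tree, data))
}

# --- evaluation counter (for complexity accounting in the search log) -------

.search_env <- new.env(parent = emptyenv())
.search_env$evals <- 0L
.search_env$masks <- list()

reset_eval_counter <- function() .search_env$evals <- 0L
bump_eval_counter <- function() .search_env$evals <- .search_env$evals + 1L

# --- local structure search -------------------------------------------------

#' Bayesian local structure search (BRL-LSS)
#'
#' Best-first beam search over decision-tree CPTs of the target. The beam is
#' seeded with singleton models (one per predictor of arity >= 2, each with
#' its complete split at the root). The search repeatedly pops the
#' best-scoring model, and for every variable and every leaf evaluates the
#' best binary/complete split of that variable at that leaf
#' ([specialize_leaf()]); a specialization is queued for further refinement
#' only when its K2 score strictly improves on the model it came from.
#' Models may not use more than `maxConj` distinct variables; a variable never
#' repeats on a root-to-leaf path. The best model ever seen is returned.
#'
#' Datasets in which no predictor has arity >= 2 yield the single-leaf model
#' (class marginals only).
#'
#' @param data A [brl_discrete] training dataset.
#' @param maxConj Maximum number of distinct variables a model may use
#'   (default 8).
#' @param beamWidth Beam capacity (default 1000).
#' @param max_steps Safety cap on the number of models popped for expansion.
#' @param patience Convergence criterion: the search halts after this many
#'   consecutive expansions that fail to improve the incumbent best model
#'   (the queue is score-ordered, so a long run without improvement means the
#'   remaining queued models trail the incumbent).
#' @return The best `brl_candidate`, with attributes `n_evals` (count of
#'   split evaluations) and `n_steps` (models expanded).
#' @export
lss_search <- function(data, maxConj = 8L, beamWidth = 1000L,
                       max_steps = 5000L, patience = 100L) {
  stopifnot(inherits(data, "brl_discrete"), maxConj >= 1L, beamWidth >= 1L)
  eligible <- which(data$arities >= 2L)
  reset_eval_counter()
  if (length(eligible) == 0L) {
    out <- new_candidate(trivial_tree(data), score_tree(trivial_tree(data), data))
    attr(out, "n_evals") <- 0L; attr(out, "n_steps") <- 0L
    return(out)
  }

  next_id <- 0L
  beam <- beam_new(beamWidth)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  best <- NULL
  split_cache <- lapply(data$arities, function(r) {
    if (r < 2L) return(list())
    p <- enumerate_binary_splits(r)
    if (r > 2L) p <- c(p, list(enumerate_complete_split(r)))
    p
  })
  for (v in eligible) {
    mod <- singleton_model(data, v, kind = "local")
    next_id <- next_id + 1L
    mod$id <- next_id
    key <- tree_signature(mod$tree$root)
    assign(key, TRUE, envir = seen)
    beam <- beam_insert(beam, mod, key)
    if (better_candidate(mod, best)) best <- mod
  }

  steps <- 0L
  stale <- 0L
  while (length(beam$items) > 0L && steps < max_steps && stale < patience) {
    popped <- beam_pop(beam)
    beam <- popped$beam
    model <- popped$model
    steps <- steps + 1L
    improved_best <- FALSE
    if (better_candidate(model, best)) { best <- model; improved_best <- TRUE }

    used <- model$used_variables
    at_limit <- length(used) >= maxConj
    leaves <- tree_leaves(model$tree$root)
    leaf_scores <- vapply(leaves, function(l) {
      k2_fast(l$counts, data$target_arity)
    }, numeric(1))
    for (v in eligible) {
      if (at_limit && !(v %in% used)) next
      partitions <- split_cache[[v]]
      for (li in seq_along(leaves)) {
        lf <- leaves[[li]]
        if (v %in% lf$vars) next
        cnt <- leaf_cell_counts(data, lf$idx, v)
        bs <- best_split_from_cells(cnt, partitions)
        new_score <- model$logscore - leaf_scores[li] + bs$score
        if (new_score > model$logscore + .score_eps) {
          # materialize the winning split only now
          blocks <- partitions[[bs$which]]
          parts <- split_indices(data, lf$idx, v, blocks)
          kids <- lapply(parts, function(p) {
            new_leaf(class_counts_at(data, p), p)
          })
          root <- replace_node(model$tree$root, lf$path,
                               new_internal(v, blocks, kids))
          key <- tree_signature(root)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            cand <- new_candidate(new_cpt_tree(root, "local"), new_score)
            next_id <- next_id + 1L
            cand$id <- next_id
            beam <- beam_insert(beam, cand, key)
            if (better_candidate(cand, best)) { best <- cand; improved_best <- TRUE }
          }
        }
      }
    }
    stale <- if (improved_best) 0L else stale + 1L
  }
  best$tree$structure_kind <- "local"
  attr(best, "n_evals") <- .search_env$evals
  attr(best, "n_steps") <- steps
  best
}

# --- global structure search ------------------------------------------------

# K2 score of the fully expanded CPT over a parent set. Only cells observed
# in the data are tabulated — empty cells of the expanded tree contribute a
# unit factor (log 0 contribution), so the score equals the full expansion's.
# The joint cell key is built in doubles (exact below 2^53), so very wide
# parent sets score correctly even when the cell space dwarfs the data.
joint_parent_score <- function(data, parents) {
  C <- data$target_arity
  if (length(parents) == 0L) {
    return(k2_leaf_logscore(target_marginals(data), C))
  }
  r <- data$arities[parents]
  cell <- rep(0, nrow(data$codes))
  stride <- 1
  for (i in seq_along(parents)) {
    cell <- cell + as.numeric(data$codes[, parents[i]]) * stride
    stride <- stride * r[i]
  }
  compact <- match(cell, unique(cell))
  J <- max(compact)
  tab <- tabulate((compact - 1L) * C + data$target_codes + 1L, nbins = J * C)
  cnt <- matrix(tab, nrow = C)
  bump_eval_counter()
  N <- colSums(cnt)
  J * lgamma(C) - sum(lgamma(N + C)) + sum(lgamma(cnt + 1))
}

#' Bayesian global structure search (BRL-GSS)
#'
#' Best-first beam search over parent sets of the target, each candidate
#' parameterized by the fully expanded CPT over its parents (one leaf per
#' joint parent assignment, so the leaf count is the product of the parent
#' arities). The beam is seeded with all single-parent models. Variables are
#' then explored one at a time — the explored set is shared across the whole
#' beam — in decreasing order of their singleton score: each exploration
#' extends every beam member lacking that variable (subject to `maxConj`) and
#' merges the results back into the beam. The best model ever scored is
#' returned as a `brl_candidate` whose tree is the expanded CPT.
#'
#' @inheritParams lss_search
#' @return The best `brl_candidate`, with attribute `n_evals`.
#' @export
gss_search <- function(data, maxConj = 8L, beamWidth = 1000L) {
  stopifnot(inherits(data, "brl_discrete"), maxConj >= 1L, beamWidth >= 1L)
  eligible <- which(data$arities >= 2L)
  reset_eval_counter()
  if (length(eligible) == 0L) {
    tree <- trivial_tree(data, kind = "global")
    out <- new_candidate(tree, score_tree(tree, data))
    attr(out, "n_evals") <- 0L
    return(out)
  }

  # parent sets kept as sorted integer vectors; beam entries are light
  # records, the tree is only materialized for the winner
  entry <- function(parents, score, id) {
    list(parents = parents, logscore = score,
         used_variables = parents, n_leaves = prod(data$arities[parents]),
         id = id)
  }
  set_key <- function(parents) paste(parents, collapse = ",")

  single_scores <- vapply(eligible, function(v) joint_parent_score(data, v),
                          numeric(1))
  ord <- order(-single_scores, eligible)
  explore_order <- eligible[ord]

  seen <- new.env(hash = TRUE, parent = emptyenv())
  best <- NULL
  next_id <- 0L
  items <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    next_id <- next_id + 1L
    e <- entry(eligible[i], single_scores[i], next_id)
    assign(set_key(e$parents), TRUE, envir = seen)
    items[[i]] <- e
    if (better_candidate(e, best)) best <- e
  }
  truncate_beam <- function(items) {
    ord <- candidate_order(items)
    items[ord[seq_len(min(length(items), beamWidth))]]
  }
  items <- truncate_beam(items)

  for (v in explore_order) {
    extensions <- list()
    for (e in items) {
      if (v %in% e$parents) next
      if (length(e$parents) >= maxConj) next
      parents <- sort(c(e$parents, v))
      key <- set_key(parents)
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      s <- joint_parent_score(data, parents)
      next_id <- next_id + 1L
      ext <- entry(parents, s, next_id)
      extensions[[length(extensions) + 1L]] <- ext
      if (better_candidate(ext, best)) best <- ext
    }
    if (length(extensions) > 0L) {
      items <- truncate_beam(c(items, extensions))
    }
  }

  tree <- full_cpt_tree(data, best$parents)
  out <- new_candidate(tree, score_tree(tree, data), best$id)
  attr(out, "n_evals") <- .search_env$evals
  out
}
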