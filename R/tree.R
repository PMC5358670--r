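## CPT decision trees.
## A node is a plain list:
##   leaf:     list(leaf = TRUE, counts = <int vector per class>, idx = <rows>)
##   internal: list(leaf = FALSE, var = <1-based variable index>,
##                  blocks = <list of 0-based code vectors, disjoint and
##                            jointly exhaustive over the variable's codes>,
##                  children = <list of nodes, one per block>)
## The `idx` on a leaf holds the training rows routed there; it is carried
## during search (so splits re-count only the affected leaf) and dropped when
## a tree is frozen into a model.

new_leaf <- function(counts, idx = NULL) {
  list(leaf = TRUE, counts = as.integer(counts), idx = idx)
}

new_internal <- function(var, blocks, children) {
  list(leaf = FALSE, var = as.integer(var), blocks = blocks,
       children = children)
}

#' Enumerate binary splits of a variable's value set
#'
#' All partitions of the codes `0 .. arity-1` into two non-empty blocks, each
#' partition listed exactly once with the block containing code 0 first. There
#' are `2^(arity-1) - 1` such partitions.
#'
#' @param arity Number of discrete values of the variable.
#' @return List of partitions; each partition is a list of two integer vectors
#'   of 0-based codes. Empty list when `arity < 2`.
#' @export
enumerate_binary_splits <- function(arity) {
  if (arity < 2L) return(list())
  rest <- seq_len(arity - 1L) # codes 1..arity-1
  out <- vector("list", 2L^(arity - 1L) - 1L)
  k <- 0L
  # subsets of `rest` joined with code 0, excluding the full set
  for (mask in 0:(2L^(arity - 1L) - 2L)) {
    members <- rest[bitwAnd(mask, 2L^(seq_len(arity - 1L) - 1L)) > 0L]
    k <- k + 1L
    out[[k]] <- list(c(0L, members), setdiff(rest, members))
  }
  out
}

#' The complete split of a variable's value set
#'
#' One singleton block per value, in code order.
#'
#' @param arity Number of discrete values (>= 2).
#' @return List of `arity` integer vectors, each a single 0-based code.
#' @export
enumerate_complete_split <- function(arity) {
  if (arity < 2L) stop("complete split needs arity >= 2", call. = FALSE)
  lapply(seq_len(arity) - 1L, identity)
}

# Split the instance rows of a leaf by a partition of variable codes.
split_indices <- function(data, idx, var, blocks) {
  codes <- data$codes[idx, var]
  lapply(blocks, function(b) idx[codes %in% b])
}

# Collect the leaves of a tree with their path metadata.
# Returns a list of list(path = child-index vector from the root,
#                        vars = variables on the path, counts, idx).
tree_leaves <- function(node, path = integer(0), vars = integer(0)) {
  if (node$leaf) {
    return(list(list(path = path, vars = vars, counts = node$counts,
                     idx = node$idx)))
  }
  out <- list()
  for (i in seq_along(node$children)) {
    out <- c(out, tree_leaves(node$children[[i]], c(path, i),
                              c(vars, node$var)))
  }
  out
}

# Replace the node at `path` (vector of child indices) with `subtree`.
replace_node <- function(node, path, subtree) {
  if (length(path) == 0L) return(subtree)
  i <- path[1L]
  node$children[[i]] <- replace_node(node$children[[i]], path[-1L], subtree)
  node
}

# Distinct variables used anywhere in the tree.
tree_variables <- function(node) {
  if (node$leaf) return(integer(0))
  vars <- node$var
  for (ch in node$children) vars <- c(vars, tree_variables(ch))
  sort(unique(vars))
}

tree_n_leaves <- function(node) {
  if (node$leaf) return(1L)
  sum(vapply(node$children, tree_n_leaves, integer(1)))
}

# Canonical serialization used for duplicate detection in the beam.
tree_signature <- function(node) {
  if (node$leaf) return("L")
  blocks <- vapply(node$blocks, function(b) paste(b, collapse = "."),
                   character(1))
  kids <- vapply(node$children, tree_signature, character(1))
  paste0("(", node$var, ":",
         paste(paste0(blocks, "=", kids), collapse = ","), ")")
}

# Structural validity: blocks partition the variable's code set, no variable
# repeats on a root-to-leaf path, every leaf holds a count vector of the
# target arity. Returns TRUE or stops with a message.
validate_tree <- function(node, data, path_vars = integer(0)) {
  if (node$leaf) {
    if (length(node$counts) != data$target_arity) {
      stop("leaf count vector has wrong length", call. = FALSE)
    }
    return(TRUE)
  }
  if (node$var %in% path_vars) {
    stop("variable ", node$var, " repeats on a root-to-leaf path", call. = FALSE)
  }
  all_codes <- sort(unlist(node$blocks))
  if (!identical(all_codes, seq_len(data$arities[node$var]) - 1L)) {
    stop("blocks of variable ", node$var,
         " do not partition its value set", call. = FALSE)
  }
  if (length(node$blocks) < 2L || length(node$children) != length(node$blocks)) {
    stop("internal node must have one child per block and >= 2 blocks",
         call. = FALSE)
  }
  for (ch in node$children) validate_tree(ch, data, c(path_vars, node$var))
  TRUE
}

# A CPT tree bundled with its bookkeeping.
new_cpt_tree <- function(root, structure_kind) {
  structure(list(root = root, used_variables = tree_variables(root),
                 structure_kind = structure_kind),
            class = "brl_tree")
}

#' @export
print.brl_tree <- function(x, ...) {
  cat("CPT tree (", x$structure_kind, " structure): ",
      tree_n_leaves(x$root), " leaves over ",
      length(x$used_variables), " variable(s)\n", sep = "")
  invisible(x)
}

# Fully expanded CPT tree over a parent set: nested complete splits in
# ascending variable order. Leaves carry counts (and rows) from `data`.
full_cpt_tree <- function(data, parents) {
  parents <- sort(as.integer(parents))
  build <- function(vars, idx) {
    if (length(vars) == 0L) {
      return(new_leaf(class_counts_at(data, idx), idx))
    }
    v <- vars[1L]
    blocks <- enumerate_complete_split(data$arities[v])
    parts <- split_indices(data, idx, v, blocks)
    kids <- lapply(parts, function(p) build(vars[-1L], p))
    new_internal(v, blocks, kids)
  }
  root <- build(parents, seq_len(nrow(data$codes)))
  new_cpt_tree(root, "global")
}

# Single-leaf tree: the empty model (class marginals only).
trivial_tree <- function(data, kind = "local") {
  new_cpt_tree(new_leaf(target_marginals(data), seq_len(nrow(data$codes))),
               kind)
}

# Score a tree's leaves under K2.
score_tree <- function(tree, data) {
  leaves <- tree_leaves(tree$root)
  k2_model_logscore(lapply(leaves, `[[`, "counts"), data$target_arity,
                    m = nrow(data$codes))
}
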