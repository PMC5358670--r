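#' Convert a CPT tree into a probabilistic rule base
#'
#' Reads out one IF-THEN rule per leaf of the tree. The antecedent is the
#' conjunction of (variable, branch value-set) pairs along the root-to-leaf
#' path; the consequent is the class with the largest smoothed count in the
#' leaf (ties go to the training majority class). Evidence is reported as
#' TP (count of the predicted class in the leaf) and FP (all other classes);
#' the smoothed posterior probability is `(TP+alpha) / ((TP+alpha)+(FP+alpha))`
#' and the posterior odds are `(TP+alpha) / (FP+alpha)`. Leaves with no
#' training evidence are retained (probability 1/2, prediction = majority
#' class), preserving mutual exclusivity and exhaustiveness.
#'
#' @param tree A `brl_tree` (or a `brl_candidate`, whose tree is used).
#' @param data The [brl_discrete] training data the tree was learned on.
#' @param alpha Smoothing factor added to TP and FP (default 1).
#' @param scheme Optional `brl_scheme`; when attached, the rule base can
#'   predict directly on continuous data.
#' @param model_logscore Optional K2 log score to record.
#' @return An object of class `brl_rulebase`: a list with `rules` (each rule a
#'   list with `antecedent`, `predicted_class`, `counts`, `tp`, `fp`, `alpha`,
#'   `posterior_probability`, `posterior_odds`, `class_distribution`), plus
#'   `class_levels`, `majority_class`, `feature_names`, `value_labels`,
#'   `arities`, `scheme`, `model_logscore` and `class_name`. Rules are ordered
#'   by posterior odds, descending.
#' @export
tree_to_rules <- function(tree, data, alpha = 1, scheme = NULL,
                          model_logscore = NULL) {
  if (inherits(tree, "brl_candidate")) {
    if (is.null(model_logscore)) model_logscore <- tree$logscore
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "brl_tree"), inherits(data, "brl_discrete"),
            alpha > 0)
  marg <- target_marginals(data)
  majority <- which.max(marg) - 1L # ties: first class level

  walk <- function(node, ante) {
    if (node$leaf) return(list(list(ante = ante, counts = node$counts)))
    out <- list()
    for (i in seq_along(node$children)) {
      cj <- list(list(var = node$var, codes = node$blocks[[i]]))
      out <- c(out, walk(node$children[[i]], c(ante, cj)))
    }
    out
  }
  raw <- walk(tree$root, list())

  rules <- lapply(raw, function(r) {
    counts <- r$counts
    sm <- counts + alpha
    mx <- max(sm)
    top <- which(sm == mx) - 1L
    pred <- if (length(top) > 1L) {
      if (majority %in% top) majority else top[1L]
    } else top
    tp <- counts[pred + 1L]
    fp <- sum(counts) - tp
    list(
      antecedent = r$ante,
      predicted_class = as.integer(pred),
      counts = as.integer(counts),
      tp = as.integer(tp),
      fp = as.integer(fp),
      alpha = alpha,
      posterior_probability = (tp + alpha) / ((tp + alpha) + (fp + alpha)),
      posterior_odds = (tp + alpha) / (fp + alpha),
      class_distribution = sm / sum(sm)
    )
  })
  ord <- order(-vapply(rules, `[[`, numeric(1), "posterior_odds"),
               seq_along(rules))
  rules <- rules[ord]

  structure(
    list(rules = rules,
         class_levels = data$class_levels,
         class_name = data$class_name,
         majority_class = as.integer(majority),
         feature_names = data$feature_names,
         value_labels = data$value_labels,
         arities = data$arities,
         scheme = scheme,
         model_logscore = model_logscore),
    class = "brl_rulebase"
  )
}

# Render one antecedent conjunct as text.
conjunct_text <- function(rb, cj) {
  labs <- rb$value_labels[[cj$var]][cj$codes + 1L]
  val <- if (length(labs) == 1L) labs else paste0("{", paste(labs, collapse = ", "), "}")
  paste0(rb$feature_names[cj$var], " in ", val)
}

rule_text <- function(rb, rule, index) {
  ante <- if (length(rule$antecedent) == 0L) "TRUE" else {
    paste(vapply(rule$antecedent, function(cj) conjunct_text(rb, cj),
                 character(1)), collapse = " AND ")
  }
  sprintf(
    "Rule %d: IF %s THEN %s = %s\n  [%s]  TP=%d FP=%d  posterior probability = %.4f  posterior odds = %.4f",
    index, ante, rb$class_name, rb$class_levels[rule$predicted_class + 1L],
    paste(sprintf("%.3f", rule$class_distribution), collapse = ", "),
    rule$tp, rule$fp, rule$posterior_probability, rule$posterior_odds)
}

#' @export
print.brl_rulebase <- function(x, ...) {
  p <- parsimony(x)
  cat("Rule base: ", p[["n_rules"]], " rules over ", p[["n_variables"]],
      " variable(s)", sep = "")
  if (!is.null(x$model_logscore)) {
    cat(", model log score ", format(x$model_logscore), sep = "")
  }
  cat("\n")
  for (i in seq_along(x$rules)) cat(rule_text(x, x$rules[[i]], i), "\n")
  invisible(x)
}

#' Parsimony metrics of a rule base
#'
#' @param rulebase A `brl_rulebase`.
#' @return Named integer vector: `n_rules` (number of rules) and
#'   `n_variables` (distinct variables appearing in any antecedent).
#' @export
parsimony <- function(rulebase) {
  stopifnot(inherits(rulebase, "brl_rulebase"))
  vars <- unlist(lapply(rulebase$rules, function(r) {
    vapply(r$antecedent, `[[`, integer(1), "var")
  }))
  c(n_rules = length(rulebase$rules),
    n_variables = length(unique(vars)))
}

# Does a coded instance (integer vector) satisfy a rule's antecedent?
matches_rule <- function(rule, codes) {
  for (cj in rule$antecedent) {
    if (!(codes[cj$var] %in% cj$codes)) return(FALSE)
  }
  TRUE
}

# Indices of rules matched by a coded instance (ME&E implies exactly one).
matching_rules <- function(rulebase, codes) {
  which(vapply(rulebase$rules, matches_rule, logical(1), codes = codes))
}

#' Predict with a rule base
#'
#' Each instance is routed to the single rule whose antecedent it satisfies
#' (the rule base is mutually exclusive and exhaustive over its used
#' variables) and receives that rule's predicted class and smoothed
#' probability. When the rule's smoothed class distribution is tied, the
#' training majority class is predicted.
#'
#' @param object A `brl_rulebase`.
#' @param newdata A numeric matrix or data frame of continuous features (the
#'   attached discretization scheme is applied first), or a [brl_discrete]
#'   dataset, or an integer matrix of 0-based codes with named columns.
#' @param ... Unused.
#' @return A data frame with one row per instance: `class` (predicted label),
#'   `probability` (smoothed probability of the predicted class), `rule`
#'   (index of the matched rule), and one `prob_<level>` column per class
#'   giving the matched rule's smoothed class distribution.
#' @export
predict.brl_rulebase <- function(object, newdata, ...) {
  codes <- coerce_codes(object, newdata)
  used <- sort(unique(unlist(lapply(object$rules, function(r) {
    vapply(r$antecedent, `[[`, integer(1), "var")
  }))))
  if (length(used) > 0L && any(is.na(codes[, used, drop = FALSE]))) {
    stop("instances are missing values for variables used by the rule base",
         call. = FALSE)
  }
  m <- nrow(codes)
  cls <- integer(m); prob <- numeric(m); ridx <- integer(m)
  dist <- matrix(NA_real_, nrow = m, ncol = length(object$class_levels))
  for (s in seq_len(m)) {
    hits <- matching_rules(object, codes[s, ])
    if (length(hits) != 1L) {
      stop("instance ", s, " matched ", length(hits),
           " rules; the rule base is not exclusive/exhaustive for it",
           call. = FALSE)
    }
    rule <- object$rules[[hits]]
    cls[s] <- rule$predicted_class
    prob[s] <- rule$posterior_probability
    ridx[s] <- hits
    dist[s, ] <- rule$class_distribution
  }
  out <- data.frame(class = object$class_levels[cls + 1L],
                    probability = prob, rule = ridx,
                    stringsAsFactors = FALSE)
  colnames(dist) <- paste0("prob_", object$class_levels)
  cbind(out, as.data.frame(dist))
}

# Turn whatever the user supplies into a 0-based code matrix whose columns
# line up with the rule base's feature indexing.
coerce_codes <- function(rulebase, newdata) {
  if (inherits(newdata, "brl_discrete")) {
    check_feature_cover(rulebase, colnames(newdata$codes))
    return(align_columns(rulebase, newdata$codes))
  }
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  stopifnot(is.matrix(newdata))
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(rulebase$feature_names)) {
      stop("unnamed input must have one column per rule-base feature",
           call. = FALSE)
    }
    colnames(newdata) <- rulebase$feature_names
  }
  if (is.double(newdata) && !is.null(rulebase$scheme)) {
    check_feature_cover(rulebase, colnames(newdata))
    sub <- newdata[, intersect(rulebase$feature_names, colnames(newdata)),
                   drop = FALSE]
    coded <- matrix(NA_integer_, nrow = nrow(sub), ncol = ncol(sub),
                    dimnames = dimnames(sub))
    for (nm in colnames(sub)) {
      coded[, nm] <- discretize_values(sub[, nm],
                                       rulebase$scheme$cutpoints[[nm]])
    }
    return(align_columns(rulebase, coded))
  }
  storage.mode(newdata) <- "integer"
  check_feature_cover(rulebase, colnames(newdata))
  align_columns(rulebase, newdata)
}

used_feature_names <- function(rulebase) {
  vars <- unique(unlist(lapply(rulebase$rules, function(r) {
    vapply(r$antecedent, `[[`, integer(1), "var")
  })))
  rulebase$feature_names[vars]
}

check_feature_cover <- function(rulebase, present) {
  need <- used_feature_names(rulebase)
  missing <- setdiff(need, present)
  if (length(missing) > 0L) {
    stop("input is missing variable(s) used by the rule base: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

align_columns <- function(rulebase, codes) {
  out <- matrix(NA_integer_, nrow = nrow(codes),
                ncol = length(rulebase$feature_names),
                dimnames = list(NULL, rulebase$feature_names))
  common <- intersect(rulebase$feature_names, colnames(codes))
  out[, common] <- codes[, common, drop = FALSE]
  out
}
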