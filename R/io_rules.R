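#' Write a rule base to disk
#'
#' Two formats are supported. `"text"` is a human-readable listing — one block
#' per rule with its antecedent conjunction, predicted class, TP/FP evidence,
#' smoothed posterior probability and posterior odds. `"machine"` is a JSON
#' document that also embeds the discretization scheme, class levels and the
#' model's K2 log score, so a saved model can predict on raw continuous data
#' after [read_rulebase()].
#'
#' @param rulebase A non-empty `brl_rulebase`.
#' @param path Output path.
#' @param format `"text"` or `"machine"`.
#' @return Invisibly, `path`.
#' @export
write_rulebase <- function(rulebase, path, format = c("machine", "text")) {
  stopifnot(inherits(rulebase, "brl_rulebase"))
  format <- match.arg(format)
  if (length(rulebase$rules) == 0L) stop("empty rule base", call. = FALSE)
  if (format == "text") {
    lines <- c(
      sprintf("# rule base: %d rules, %d variables, model log score %s",
              parsimony(rulebase)[["n_rules"]],
              parsimony(rulebase)[["n_variables"]],
              format(rulebase$model_logscore)),
      vapply(seq_along(rulebase$rules), function(i) {
        rule_text(rulebase, rulebase$rules[[i]], i)
      }, character(1))
    )
    tryCatch(writeLines(lines, path),
             error = function(e) stop("cannot write '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
    return(invisible(path))
  }

  doc <- list(
    format = "brlearn-rulebase",
    version = 1L,
    class_name = rulebase$class_name,
    class_levels = rulebase$class_levels,
    majority_class = rulebase$majority_class,
    model_logscore = rulebase$model_logscore,
    feature_names = rulebase$feature_names,
    arities = rulebase$arities,
    value_labels = rulebase$value_labels,
    scheme = if (is.null(rulebase$scheme)) NULL else {
      list(lambda = rulebase$scheme$lambda,
           cutpoints = rulebase$scheme$cutpoints)
    },
    rules = lapply(rulebase$rules, function(r) {
      list(
        antecedent = lapply(r$antecedent, function(cj) {
          list(feature = rulebase$feature_names[cj$var],
               codes = as.integer(cj$codes))
        }),
        predicted_class = r$predicted_class,
        counts = r$counts,
        alpha = r$alpha
      )
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  tryCatch(writeLines(json, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a machine-format rule base
#'
#' Reconstructs a `brl_rulebase` written by [write_rulebase()] with
#' `format = "machine"`. Evidence-derived quantities (TP, FP, posterior
#' probability, odds, class distribution) are recomputed from the stored
#' counts and smoothing factor, so the round trip is exact.
#'
#' @param path Path to a machine-format rule-base file.
#' @return A `brl_rulebase`.
#' @export
read_rulebase <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "brlearn-rulebase") {
    stop("'", path, "' is not a machine-format rule base", call. = FALSE)
  }
  feature_names <- unlist(doc$feature_names)
  class_levels <- unlist(doc$class_levels)
  majority <- as.integer(doc$majority_class)
  scheme <- NULL
  if (!is.null(doc$scheme)) {
    cp <- lapply(doc$scheme$cutpoints, function(x) as.numeric(unlist(x)))
    names(cp) <- names(doc$scheme$cutpoints)
    scheme <- structure(list(cutpoints = cp,
                             lambda = as.numeric(doc$scheme$lambda)),
                        class = "brl_scheme")
  }
  rules <- lapply(doc$rules, function(r) {
    counts <- as.integer(unlist(r$counts))
    alpha <- as.numeric(r$alpha)
    pred <- as.integer(r$predicted_class)
    tp <- counts[pred + 1L]
    fp <- sum(counts) - tp
    sm <- counts + alpha
    list(
      antecedent = lapply(r$antecedent, function(cj) {
        list(var = match(cj$feature, feature_names),
             codes = as.integer(unlist(cj$codes)))
      }),
      predicted_class = pred,
      counts = counts,
      tp = as.integer(tp), fp = as.integer(fp), alpha = alpha,
      posterior_probability = (tp + alpha) / ((tp + alpha) + (fp + alpha)),
      posterior_odds = (tp + alpha) / (fp + alpha),
      class_distribution = sm / sum(sm)
    )
  })
  structure(
    list(rules = rules,
         class_levels = class_levels,
         class_name = if (is.null(doc$class_name)) "class" else doc$class_name,
         majority_class = majority,
         feature_names = feature_names,
         value_labels = lapply(doc$value_labels, function(x) unlist(x)),
         arities = as.integer(unlist(doc$arities)),
         scheme = scheme,
         model_logscore = if (is.null(doc$model_logscore)) NULL else
           as.numeric(doc$model_logscore)),
    class = "brl_rulebase"
  )
}

#' Write a discretization scheme to a JSON file
#'
#' @param scheme A `brl_scheme`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "brl_scheme"))
  doc <- list(format = "brlearn-scheme", version = 1L,
              lambda = scheme$lambda, cutpoints = scheme$cutpoints)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a discretization scheme written by [write_scheme()]
#'
#' @param path Path to a scheme file.
#' @return A `brl_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "brlearn-scheme") {
    stop("'", path, "' is not a scheme file", call. = FALSE)
  }
  cp <- lapply(doc$cutpoints, function(x) as.numeric(unlist(x)))
  names(cp) <- names(doc$cutpoints)
  structure(list(cutpoints = cp, lambda = as.numeric(doc$lambda)),
            class = "brl_scheme")
}
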