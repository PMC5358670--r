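#' Train a Bayesian rule model
#'
#' End-to-end training on a continuous dataset: fit a supervised Bayesian
#' discretization scheme ([ebd_fit_all()]), encode the data, run the chosen
#' structure search ([gss_search()] or [lss_search()]), and read the winning
#' CPT tree out as a rule base ([tree_to_rules()]). A [brl_discrete] dataset
#' may be supplied instead, in which case the discretization step is skipped.
#'
#' @param dataset A [brl_dataset] (continuous) or [brl_discrete] dataset.
#' @param method `"lss"` (local structure search, the default) or `"gss"`
#'   (global structure search).
#' @param maxConj Maximum number of distinct variables in a model (default 8).
#' @param beamWidth Beam capacity (default 1000).
#' @param lambda Discretization prior parameter (default 0.5); ignored for
#'   discrete input.
#' @param alpha Rule smoothing factor (default 1).
#' @param max_intervals Per-feature cap on discretization intervals.
#' @return An object of class `brl_model`: a list with `method`, `params`,
#'   `scheme` (or `NULL`), `model` (the winning `brl_candidate`),
#'   `rulebase`, and `logscore`.
#' @export
brl_train <- function(dataset, method = c("lss", "gss"), maxConj = 8L,
                      beamWidth = 1000L, lambda = 0.5, alpha = 1,
                      max_intervals = 16L) {
  method <- match.arg(method)
  scheme <- NULL
  if (inherits(dataset, "brl_dataset")) {
    scheme <- ebd_fit_all(dataset, lambda = lambda,
                          max_intervals = max_intervals)
    disc <- apply_scheme(scheme, dataset)
  } else if (inherits(dataset, "brl_discrete")) {
    disc <- dataset
  } else {
    stop("dataset must be a brl_dataset or brl_discrete", call. = FALSE)
  }
  cand <- if (method == "gss") {
    gss_search(disc, maxConj = maxConj, beamWidth = beamWidth)
  } else {
    lss_search(disc, maxConj = maxConj, beamWidth = beamWidth)
  }
  rb <- tree_to_rules(cand$tree, disc, alpha = alpha, scheme = scheme,
                      model_logscore = cand$logscore)
  structure(
    list(method = method,
         params = list(maxConj = maxConj, beamWidth = beamWidth,
                       lambda = lambda, alpha = alpha),
         scheme = scheme, model = cand, rulebase = rb,
         logscore = cand$logscore),
    class = "brl_model"
  )
}

#' @export
print.brl_model <- function(x, ...) {
  p <- parsimony(x$rulebase)
  cat("BRL model (", toupper(x$method), "): log score ", format(x$logscore),
      ", ", p[["n_rules"]], " rules, ", p[["n_variables"]],
      " variable(s)\n", sep = "")
  invisible(x)
}

#' @rdname predict.brl_rulebase
#' @export
predict.brl_model <- function(object, newdata, ...) {
  predict(object$rulebase, newdata, ...)
}
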