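#' Supervised Bayesian discretization (EBD)
#'
#' Finds the set of cut-points for one continuous variable that maximizes a
#' Bayesian score: a geometric prior over the number of cut-points with mean
#' `lambda`, times the product over intervals of the multinomial-Dirichlet
#' marginal likelihood of the class labels falling in that interval (uniform
#' Dirichlet parameter 1 per class). Candidate cut-points are midpoints between
#' consecutive distinct sorted values across which the class composition
#' changes; the optimum over all candidate subsets is found by dynamic
#' programming over boundaries.
#'
#' The prior is \eqn{P(k) = (1/(1+\lambda)) (\lambda/(1+\lambda))^k} for `k`
#' cut-points, so each additional cut-point costs
#' \eqn{\log(\lambda/(1+\lambda))} in log score and the expected number of
#' cut-points under the prior is `lambda`.
#'
#' @param values Numeric vector of length m (m >= 2).
#' @param labels Integer vector of 0-based class codes (>= 2 classes present),
#'   or a factor.
#' @param lambda Positive prior parameter controlling the expected number of
#'   cut-points (default 0.5).
#' @param max_intervals Cap on the number of intervals the dynamic program may
#'   use (default 16); a guard, not usually binding.
#'
#' @return Numeric vector of strictly increasing cut-points (possibly empty).
#'   A variable whose values are all equal, or across which the class never
#'   changes, yields `numeric(0)`.
#' @export
ebd_fit <- function(values, labels, lambda = 0.5, max_intervals = 16L) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  m <- length(values)
  stopifnot(m >= 2L, length(labels) == m, lambda > 0, max_intervals >= 1L)
  n_class <- length(unique(labels))
  if (n_class < 2L) {
    stop("ebd_fit requires at least two classes among the labels", call. = FALSE)
  }
  n_levels <- max(labels) + 1L

  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]

  cand <- ebd_candidates(v, y, n_levels)
  if (length(cand$pos) == 0L) return(numeric(0))

  # boundary instance positions: 0, candidate positions, m
  pos <- c(0L, cand$pos, m)
  B <- length(pos) - 1L # number of segments
  np <- length(pos)
  # cumulative class counts at each boundary position
  ind <- matrix(0L, nrow = m, ncol = n_levels)
  ind[cbind(seq_len(m), y + 1L)] <- 1L
  cum_all <- apply(ind, 2L, cumsum)
  cum <- rbind(0, cum_all[pos[-1L], , drop = FALSE])

  # S[j, i]: marginal-likelihood score of the interval between boundaries
  # j and i (j < i)
  S <- matrix(-Inf, nrow = np, ncol = np)
  for (i in 2:np) {
    j <- seq_len(i - 1L)
    cnt <- cum[rep(i, length(j)), , drop = FALSE] - cum[j, , drop = FALSE]
    S[j, i] <- lgamma(n_levels) - lgamma(rowSums(cnt) + n_levels) +
      rowSums(lgamma(cnt + 1))
  }
  pen <- log(lambda / (1 + lambda)) # per cut-point log-prior cost

  kmax <- min(max_intervals, B)
  # f[i, t]: best interval-likelihood sum for prefix ending at boundary i,
  # using t intervals; back[i, t]: previous boundary index
  f <- matrix(-Inf, nrow = np, ncol = kmax)
  back <- matrix(NA_integer_, nrow = np, ncol = kmax)
  f[2:np, 1L] <- S[1L, 2:np]
  back[2:np, 1L] <- 1L
  if (kmax >= 2L) {
    for (t in 2:kmax) {
      for (i in (t + 1L):np) {
        j <- t:(i - 1L)
        s <- f[j, t - 1L] + S[j, i]
        bj <- which.max(s)
        f[i, t] <- s[bj]
        back[i, t] <- j[bj]
      }
    }
  }
  tot <- f[np, ] + (seq_len(kmax) - 1L) * pen
  t_best <- which.max(tot) # ties: fewest intervals (which.max takes first)

  # walk back to recover chosen boundary positions
  cuts_pos <- integer(0)
  i <- np
  for (t in seq(t_best, 1L)) {
    j <- back[i, t]
    if (t > 1L) cuts_pos <- c(pos[j], cuts_pos)
    i <- j
  }
  if (length(cuts_pos) == 0L) return(numeric(0))
  # cut value: midpoint between the values either side of the boundary
  vapply(cuts_pos, function(p) (v[p] + v[p + 1L]) / 2, numeric(1))
}

# Candidate boundaries: positions p (1-based, boundary after instance p in the
# sorted order) between distinct adjacent values, kept unless the two adjacent
# value-groups are each pure and of the same class (such a boundary can never
# help any scoring rule that depends on class composition only).
ebd_candidates <- function(v_sorted, y_sorted, n_levels) {
  m <- length(v_sorted)
  grp_end <- which(diff(v_sorted) > 0) # boundary after these positions
  if (length(grp_end) == 0L) return(list(pos = integer(0)))
  grp_start <- c(1L, grp_end + 1L)
  grp_stop <- c(grp_end, m)
  keep <- logical(length(grp_end))
  for (g in seq_along(grp_end)) {
    left <- y_sorted[grp_start[g]:grp_stop[g]]
    right <- y_sorted[grp_start[g + 1L]:grp_stop[g + 1L]]
    pure_same <- length(unique(left)) == 1L && length(unique(right)) == 1L &&
      left[1L] == right[1L]
    keep[g] <- !pure_same
  }
  list(pos = grp_end[keep])
}

# Marginal likelihood of a class-count vector under a multinomial with a
# uniform Dirichlet(1,...,1) prior: (C-1)! / (N+C-1)! * prod(n_k!), in logs.
dirichlet_multinomial_logscore <- function(counts) {
  C <- length(counts)
  N <- sum(counts)
  lgamma(C) - lgamma(N + C) + sum(lgamma(counts + 1))
}

#' Log score of a given cut-point set under the EBD criterion
#'
#' Scores an arbitrary discretization of one variable (not necessarily the
#' optimum): log geometric prior on the number of cut-points plus the summed
#' interval marginal likelihoods. Exposed so that alternative cut-point sets
#' can be compared on the same scale as [ebd_fit()].
#'
#' @inheritParams ebd_fit
#' @param cutpoints Numeric vector of strictly increasing thresholds.
#' @return Log score (single numeric).
#' @export
ebd_score <- function(values, labels, cutpoints, lambda = 0.5) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  n_levels <- max(labels) + 1L
  codes <- discretize_values(values, cutpoints)
  k <- length(cutpoints)
  s <- -log(1 + lambda) + k * log(lambda / (1 + lambda))
  for (j in 0:k) {
    cnt <- tabulate(labels[codes == j] + 1L, nbins = n_levels)
    s <- s + dirichlet_multinomial_logscore(cnt)
  }
  s
}

#' Fit a discretization scheme for every feature of a dataset
#'
#' Applies [ebd_fit()] independently to each feature against the class labels.
#' Deterministic given the input.
#'
#' @param dataset A [brl_dataset].
#' @param lambda Positive prior parameter (default 0.5).
#' @param max_intervals Per-feature cap on intervals (default 16).
#' @return An object of class `brl_scheme`: a list with `cutpoints` (named
#'   list of numeric vectors, one per feature, in feature order) and `lambda`.
#' @export
ebd_fit_all <- function(dataset, lambda = 0.5, max_intervals = 16L) {
  stopifnot(inherits(dataset, "brl_dataset"))
  y <- as.integer(dataset$class_labels) - 1L
  cp <- lapply(seq_along(dataset$feature_names), function(i) {
    ebd_fit(dataset$values[, i], y, lambda = lambda,
            max_intervals = max_intervals)
  })
  names(cp) <- dataset$feature_names
  structure(list(cutpoints = cp, lambda = lambda), class = "brl_scheme")
}

#' @export
print.brl_scheme <- function(x, ...) {
  k <- vapply(x$cutpoints, length, integer(1))
  cat("Discretization scheme (lambda = ", x$lambda, "): ",
      length(k), " features, ", sum(k > 0), " with cut-points\n", sep = "")
  invisible(x)
}

# Map continuous values to 0-based interval codes under right-closed
# intervals: code j iff c_j < v <= c_{j+1}, with c_0 = -Inf, c_{k+1} = +Inf.
discretize_values <- function(values, cutpoints) {
  if (length(cutpoints) == 0L) return(rep(0L, length(values)))
  findInterval(values, cutpoints, left.open = TRUE)
}

# Human-readable interval labels for a cut-point vector.
interval_labels <- function(cutpoints, digits = 6) {
  k <- length(cutpoints)
  if (k == 0L) return("(-inf, inf)")
  cp <- signif(cutpoints, digits)
  labs <- character(k + 1L)
  labs[1L] <- paste0("(-inf, ", cp[1L], "]")
  if (k > 1L) {
    for (j in 2:k) labs[j] <- paste0("(", cp[j - 1L], ", ", cp[j], "]")
  }
  labs[k + 1L] <- paste0("(", cp[k], ", inf)")
  labs
}

#' Apply a discretization scheme
#'
#' Encodes a continuous dataset (or plain numeric matrix) through the scheme's
#' cut-points. Intervals are right-closed: value `v` maps to code `j` when
#' `c_j < v <= c_{j+1}` with sentinels at plus/minus infinity. The recorded
#' arity of a variable is (number of cut-points + 1) even if some interval is
#' empty in this particular dataset, so a scheme learned on a training fold
#' yields consistent codes on held-out data.
#'
#' @param scheme A `brl_scheme` from [ebd_fit_all()].
#' @param dataset A [brl_dataset], or a numeric matrix with column names
#'   covered by the scheme (in which case `labels` must be supplied).
#' @param labels Optional class labels when `dataset` is a plain matrix.
#' @return A [brl_discrete] dataset.
#' @export
apply_scheme <- function(scheme, dataset, labels = NULL) {
  stopifnot(inherits(scheme, "brl_scheme"))
  if (inherits(dataset, "brl_dataset")) {
    values <- dataset$values
    labels <- dataset$class_labels
    class_name <- dataset$class_name
  } else {
    values <- as.matrix(dataset)
    if (is.null(labels)) stop("labels required for a plain matrix", call. = FALSE)
    labels <- factor(labels)
    class_name <- "class"
  }
  feats <- colnames(values)
  missing_feats <- setdiff(feats, names(scheme$cutpoints))
  if (length(missing_feats) > 0L) {
    stop("scheme does not cover feature(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  n <- length(feats)
  codes <- matrix(0L, nrow = nrow(values), ncol = n,
                  dimnames = list(NULL, feats))
  arities <- integer(n)
  vlabels <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- scheme$cutpoints[[feats[i]]]
    codes[, i] <- discretize_values(values[, i], cp)
    arities[i] <- length(cp) + 1L
    vlabels[[i]] <- interval_labels(cp)
  }
  brl_discrete(codes, arities,
               target_codes = as.integer(labels) - 1L,
               target_arity = nlevels(labels),
               value_labels = vlabels, feature_names = feats,
               class_levels = levels(labels), class_name = class_name)
}
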