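# Independent oracles used to check the package's scoring and search paths.
# These deliberately re-derive everything from first principles (factorials,
# full scans, exhaustive enumeration) rather than calling package internals.

# K2 leaf contribution by direct factorial arithmetic: exact integer
# numerator/denominator (doubles are exact well past the count ranges used
# in tests), then one log.
oracle_k2_leaf <- function(counts, target_arity = length(counts)) {
  num <- factorial(target_arity - 1) * prod(factorial(counts))
  den <- factorial(sum(counts) + target_arity - 1)
  log(num) - log(den)
}

oracle_k2_model <- function(leaf_list, target_arity) {
  sum(vapply(leaf_list, oracle_k2_leaf, numeric(1),
             target_arity = target_arity))
}

# All-pairs Mann-Whitney AUC: wins + half-ties over all (positive, negative)
# pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# EBD-style score of an explicit cut-point set, from scratch: geometric prior
# with mean lambda over the number of cut-points plus per-interval
# Dirichlet(1) multinomial evidence via factorials.
oracle_ebd_score <- function(values, labels, cuts, lambda = 0.5) {
  C <- length(unique(labels))
  lev <- sort(unique(labels))
  k <- length(cuts)
  s <- -log(1 + lambda) + k * log(lambda / (1 + lambda))
  bounds <- c(-Inf, sort(cuts), Inf)
  for (j in seq_len(k + 1)) {
    inb <- values > bounds[j] & values <= bounds[j + 1]
    cnt <- vapply(lev, function(l) sum(labels[inb] == l), numeric(1))
    s <- s + oracle_k2_leaf(cnt, C)
  }
  s
}

# Exhaustive EBD optimum: enumerate every subset of the midpoints between
# distinct adjacent sorted values (a superset of the class-boundary
# candidates) and return the best score and a best cut set. When that set is
# too large to enumerate, fall back to the class-boundary midpoints (a cut
# between two pure runs of the same class adds a prior penalty without
# changing any interval's purity, so it can never be part of an optimum).
oracle_ebd_best <- function(values, labels, lambda = 0.5) {
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  dv <- which(diff(v) > 0)
  mids <- (v[dv] + v[dv + 1]) / 2
  if (length(mids) > 14) {
    starts <- c(1, dv + 1)
    stops <- c(dv, length(v))
    keep <- vapply(seq_along(dv), function(g) {
      left <- y[starts[g]:stops[g]]
      right <- y[starts[g + 1]:stops[g + 1]]
      !(length(unique(left)) == 1 && length(unique(right)) == 1 &&
          left[1] == right[1])
    }, logical(1))
    mids <- mids[keep]
  }
  B <- length(mids)
  stopifnot(B <= 14) # keep enumeration honest and fast
  best <- -Inf
  best_cuts <- numeric(0)
  for (mask in 0:(2^B - 1)) {
    cuts <- mids[bitwAnd(mask, 2^(seq_len(B) - 1)) > 0]
    s <- oracle_ebd_score(values, labels, cuts, lambda)
    if (s > best + 1e-12) {
      best <- s
      best_cuts <- cuts
    }
  }
  list(score = best, cuts = best_cuts)
}

# Exhaustive parent-set search: score every non-empty subset of the eligible
# variables as a fully expanded CPT (counts via a full scan per joint cell).
oracle_gss_best_score <- function(data, maxConj = ncol(data$codes)) {
  vars <- which(data$arities >= 2)
  best <- -Inf
  for (mask in 1:(2^length(vars) - 1)) {
    parents <- vars[bitwAnd(mask, 2^(seq_along(vars) - 1)) > 0]
    if (length(parents) > maxConj) next
    key <- apply(data$codes[, parents, drop = FALSE], 1,
                 paste, collapse = "|")
    leaf_list <- lapply(split(seq_len(nrow(data$codes)), key), function(idx) {
      vapply(seq_len(data$target_arity) - 1,
             function(k) sum(data$target_codes[idx] == k), numeric(1))
    })
    s <- oracle_k2_model(leaf_list, data$target_arity)
    if (s > best) best <- s
  }
  best
}

# Full-scan match counting for an antecedent.
oracle_count_matches <- function(data, antecedent) {
  out <- integer(data$target_arity)
  for (s in seq_len(nrow(data$codes))) {
    ok <- TRUE
    for (cj in antecedent) {
      if (!(data$codes[s, cj$var] %in% cj$codes)) { ok <- FALSE; break }
    }
    if (ok) out[data$target_codes[s] + 1L] <- out[data$target_codes[s] + 1L] + 1L
  }
  out
}

# Exhaustive search over local trees of depth <= 2 for all-binary data:
# every root variable with its complete split, each leaf optionally split by
# one other variable. Returns the best K2 score.
oracle_lss_depth2_best_score <- function(data) {
  stopifnot(all(data$arities[data$arities >= 2] == 2))
  vars <- which(data$arities >= 2)
  C <- data$target_arity
  counts_of <- function(idx) {
    vapply(seq_len(C) - 1, function(k) sum(data$target_codes[idx] == k),
           numeric(1))
  }
  best <- -Inf
  for (root in vars) {
    side <- lapply(0:1, function(b) which(data$codes[, root] == b))
    # options per leaf: no split (NA) or split by any other variable
    opts <- c(NA, setdiff(vars, root))
    for (o1 in opts) for (o2 in opts) {
      leaf_list <- list()
      for (b in 1:2) {
        o <- if (b == 1) o1 else o2
        idx <- side[[b]]
        if (is.na(o)) {
          leaf_list <- c(leaf_list, list(counts_of(idx)))
        } else {
          leaf_list <- c(leaf_list,
                         list(counts_of(idx[data$codes[idx, o] == 0]),
                              counts_of(idx[data$codes[idx, o] == 1])))
        }
      }
      s <- oracle_k2_model(leaf_list, C)
      if (s > best) best <- s
    }
  }
  best
}

# Small random discrete dataset (binary classes) for property tests.
random_discrete <- function(m, arities, seed, target_arity = 2L) {
  set.seed(seed)
  codes <- vapply(arities, function(r) sample.int(r, m, replace = TRUE) - 1L,
                  integer(m))
  brl_discrete(matrix(codes, nrow = m), arities,
               target_codes = sample.int(target_arity, m, replace = TRUE) - 1L,
               target_arity = target_arity)
}

# Continuous fixture with a separable feature and a constant feature.
two_feature_dataset <- function(m = 20, seed = 1) {
  set.seed(seed)
  y <- rep(c("case", "control"), length.out = m)
  sep <- ifelse(y == "case", 5, 0) + rnorm(m, sd = 0.3)
  brl_dataset(cbind(sep = sep, flat = rep(1.5, m)), y)
}
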