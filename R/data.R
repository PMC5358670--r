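#' Construct a continuous dataset
#'
#' Bundles a sample-by-feature matrix of continuous measurements (for example
#' normalized gene-expression intensities) with a categorical class label per
#' sample. This is the input type for discretization, training and
#' cross-validation.
#'
#' @param values Numeric matrix, one row per sample and one column per feature.
#' @param class_labels Vector (coerced to factor) of class labels, one per row
#'   of `values`. At least two distinct labels must be present and none may be
#'   missing.
#' @param feature_names Optional character vector of feature names; defaults to
#'   the column names of `values` or `V1..Vn`.
#' @param class_name Name of the class variable (used in file headers).
#'
#' @return An object of class `brl_dataset` with elements `values`,
#'   `feature_names`, `class_labels` and `class_name`.
#' @export
brl_dataset <- function(values, class_labels, feature_names = NULL,
                        class_name = "class") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (m < 2L) stop("a dataset needs at least 2 samples", call. = FALSE)
  if (n < 1L) stop("a dataset needs at least 1 feature", call. = FALSE)
  if (length(class_labels) != m) {
    stop("class_labels length (", length(class_labels),
         ") does not match number of rows (", m, ")", call. = FALSE)
  }
  if (anyNA(class_labels)) {
    stop("missing class labels are not allowed", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing feature values are not supported; remove or impute them ",
         "before loading", call. = FALSE)
  }
  class_labels <- factor(class_labels)
  class_labels <- droplevels(class_labels)
  if (nlevels(class_labels) < 2L) {
    stop("the class column must contain at least two distinct labels",
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("V", seq_len(n))
  }
  if (length(feature_names) != n || anyDuplicated(feature_names)) {
    stop("feature_names must be unique and match the number of columns",
         call. = FALSE)
  }
  colnames(values) <- feature_names
  structure(
    list(values = values, feature_names = feature_names,
         class_labels = class_labels, class_name = class_name),
    class = "brl_dataset"
  )
}

#' @export
print.brl_dataset <- function(x, ...) {
  cat("Continuous dataset: ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  cat("Class '", x$class_name, "': ", sep = "")
  print(table(x$class_labels))
  invisible(x)
}

#' @export
dim.brl_dataset <- function(x) dim(x$values)

#' Construct a discrete dataset
#'
#' Integer-coded instances over variables of known arity plus a coded target.
#' Codes are 0-based consecutive integers per variable; a variable with arity
#' `r` takes codes `0 .. r-1`. This is the substrate on which all K2 scoring
#' and structure search operates.
#'
#' @param codes Integer matrix, one row per instance, one column per variable.
#' @param arities Integer vector of per-variable arities (`r_i`); every code in
#'   column `i` must lie in `[0, r_i)`. Arity 1 is legal (a constant variable).
#' @param target_codes Integer vector of 0-based class codes.
#' @param target_arity Number of classes (>= 2).
#' @param value_labels List (one element per variable) of character vectors
#'   giving a human-readable label per code, e.g. `"(-inf, 3.2]"`.
#' @param feature_names Character vector of variable names.
#' @param class_levels Character vector of class names, one per target code.
#' @param class_name Name of the class variable.
#'
#' @return An object of class `brl_discrete` with the fields above.
#' @export
brl_discrete <- function(codes, arities, target_codes, target_arity,
                         value_labels = NULL, feature_names = NULL,
                         class_levels = NULL, class_name = "class") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  m <- nrow(codes)
  n <- ncol(codes)
  arities <- as.integer(arities)
  target_codes <- as.integer(target_codes)
  if (length(arities) != n) stop("arities must have one entry per variable", call. = FALSE)
  if (length(target_codes) != m) stop("target_codes must have one entry per instance", call. = FALSE)
  if (any(arities < 1L)) stop("arities must be >= 1", call. = FALSE)
  if (target_arity < 2L) stop("target_arity must be >= 2", call. = FALSE)
  for (i in seq_len(n)) {
    ci <- codes[, i]
    if (any(ci < 0L) || any(ci >= arities[i])) {
      stop("codes out of range for variable ", i, call. = FALSE)
    }
  }
  if (any(target_codes < 0L) || any(target_codes >= target_arity)) {
    stop("target codes out of range", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(codes)
    if (is.null(feature_names)) feature_names <- paste0("V", seq_len(n))
  }
  colnames(codes) <- feature_names
  if (is.null(class_levels)) class_levels <- paste0("class", seq_len(target_arity) - 1L)
  if (is.null(value_labels)) {
    value_labels <- lapply(arities, function(r) as.character(seq_len(r) - 1L))
  }
  structure(
    list(codes = codes, arities = arities, value_labels = value_labels,
         target_codes = target_codes, target_arity = as.integer(target_arity),
         feature_names = feature_names, class_levels = class_levels,
         class_name = class_name),
    class = "brl_discrete"
  )
}

#' @export
print.brl_discrete <- function(x, ...) {
  cat("Discrete dataset: ", nrow(x$codes), " instances x ",
      ncol(x$codes), " variables (max arity ", max(x$arities), ")\n", sep = "")
  cat("Target '", x$class_name, "' with ", x$target_arity, " classes: ",
      paste(x$class_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Class counts of the target
#'
#' @param data A `brl_discrete` dataset.
#' @return Integer vector of length `target_arity`: instances per class.
#' @keywords internal
target_marginals <- function(data) {
  tabulate(data$target_codes + 1L, nbins = data$target_arity)
}

#' Read a delimited expression matrix with a class column
#'
#' Reads a CSV/TSV file whose rows are samples and whose columns are features,
#' one column holding the categorical class label. A header row is required;
#' all non-class columns must be numeric.
#'
#' @param path Path to the file.
#' @param class_column Name of the class column (default `"class"`).
#' @param delimiter Field delimiter; `","` or `"\t"`.
#'
#' @return A [brl_dataset] with features in file order and the class column
#'   excluded from the features.
#' @export
read_dataset <- function(path, class_column = "class", delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!class_column %in% names(df)) {
    stop("class column '", class_column, "' not found in header of ", path,
         call. = FALSE)
  }
  labels <- df[[class_column]]
  feats <- df[setdiff(names(df), class_column)]
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0L) {
        stop("non-numeric value in feature '", nm, "' at data row ", bad[1L],
             ": '", col[bad[1L]], "'", call. = FALSE)
      }
      feats[[nm]] <- num
    }
  }
  values <- as.matrix(feats)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing feature value at row ", bad[1L], ", feature '",
         colnames(values)[bad[2L]], "'", call. = FALSE)
  }
  brl_dataset(values, labels, class_name = class_column)
}

#' Write a continuous dataset to a delimited file
#'
#' Inverse of [read_dataset()]: the class column is written alongside the
#' features under the dataset's `class_name`.
#'
#' @param dataset A [brl_dataset].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, delimiter = ",") {
  stopifnot(inherits(dataset, "brl_dataset"))
  df <- as.data.frame(dataset$values, check.names = FALSE)
  df[[dataset$class_name]] <- as.character(dataset$class_labels)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write dataset to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Restrict a dataset to a subset of samples
#'
#' @param dataset A [brl_dataset].
#' @param idx Integer row indices to keep.
#' @return A [brl_dataset] over the selected rows.
#' @export
subset_dataset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "brl_dataset"))
  brl_dataset(dataset$values[idx, , drop = FALSE],
              as.character(dataset$class_labels)[idx],
              feature_names = dataset$feature_names,
              class_name = dataset$class_name)
}
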