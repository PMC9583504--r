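#' Ordered multi-group biomarker data
#'
#' Bundles a subject-by-marker numeric table together with an ordinal outcome
#' into the grouped form used by all objective functions: one matrix of
#' observations per outcome category, categories in increasing order.
#'
#' @param x Numeric matrix or data frame, one row per subject and one column
#'   per marker. All values must be finite.
#' @param labels Vector of ordinal outcome labels, one per row of `x`.
#' @param levels Optional vector giving the category labels in increasing
#'   order. Defaults to `sort(unique(labels))`. Every label must occur in
#'   `levels`, and every level must be observed at least once.
#'
#' @return An object of class `"biomarker_data"`: a list with elements
#'   `groups` (list of M numeric matrices, increasing category order),
#'   `levels` (character vector of category labels), `d` (number of markers)
#'   and `n` (integer vector of per-category sample sizes).
#'
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- rep(c(0, 1), each = 10)
#' bd <- biomarker_data(x, y)
#' bd
#' @seealso [read_biomarker_data()], [ehum()], [fit_combination()]
#' @export
biomarker_data <- function(x, labels, levels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    stop("marker values must be finite (no NA/NaN/Inf)")
  }
  if (nrow(x) != length(labels)) {
    stop("`labels` must have one entry per row of `x`")
  }
  if (is.null(levels)) {
    levels <- sort(unique(labels))
  }
  levels <- as.character(levels)
  labels <- as.character(labels)
  if (!all(labels %in% levels)) {
    stop("all labels must be among the supplied `levels`")
  }
  if (length(levels) < 2L) {
    stop("at least two outcome categories are required")
  }
  groups <- lapply(levels, function(lv) x[labels == lv, , drop = FALSE])
  n <- vapply(groups, nrow, integer(1))
  if (any(n < 1L)) {
    stop("every category in `levels` must contain at least one observation")
  }
  structure(
    list(groups = groups, levels = levels, d = ncol(x), n = n),
    class = "biomarker_data"
  )
}

#' Assemble biomarker data from a list of per-category matrices
#'
#' Lower-level constructor used by the scenario generators: `groups[[j]]`
#' holds the observations of the j-th category, categories in increasing
#' order.
#'
#' @param groups List of numeric matrices with a common column count.
#' @param levels Optional category labels (defaults to `0:(M-1)`).
#' @return A `"biomarker_data"` object.
#' @export
biomarker_groups <- function(groups, levels = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two matrices")
  }
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  d <- unique(vapply(groups, ncol, integer(1)))
  if (length(d) != 1L) {
    stop("all groups must share the same number of markers")
  }
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    stop("marker values must be finite (no NA/NaN/Inf)")
  }
  n <- vapply(groups, nrow, integer(1))
  if (any(n < 1L)) stop("every group needs at least one observation")
  if (is.null(levels)) levels <- as.character(seq_along(groups) - 1L)
  structure(
    list(groups = groups, levels = as.character(levels), d = d, n = n),
    class = "biomarker_data"
  )
}

#' Read biomarker data from a delimited file
#'
#' Reads a long-format CSV or TSV file with one row per subject, numeric
#' marker columns and one ordinal label column.
#'
#' @param file Path to a `.csv` or `.tsv`/`.txt` file.
#' @param label_col Name (or index) of the outcome column.
#' @param marker_cols Optional names/indices of the marker columns; defaults
#'   to every column except `label_col`.
#' @param levels Optional explicit category order, passed to
#'   [biomarker_data()].
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @return A `"biomarker_data"` object.
#' @export
read_biomarker_data <- function(file, label_col, marker_cols = NULL,
                                levels = NULL, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", file, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.numeric(label_col)) label_col <- names(df)[label_col]
  if (!label_col %in% names(df)) {
    stop("label column '", label_col, "' not found in file")
  }
  if (is.null(marker_cols)) {
    marker_cols <- setdiff(names(df), label_col)
  } else if (is.numeric(marker_cols)) {
    marker_cols <- names(df)[marker_cols]
  }
  x <- as.matrix(df[, marker_cols, drop = FALSE])
  if (!is.numeric(x)) stop("marker columns must be numeric")
  biomarker_data(x, df[[label_col]], levels = levels)
}

#' @export
print.biomarker_data <- function(x, ...) {
  cat("Ordered biomarker data: ", x$d, " marker(s), ",
      length(x$groups), " categories\n", sep = "")
  cat("  categories (increasing): ", paste(x$levels, collapse = " < "),
      "\n", sep = "")
  cat("  group sizes: ", paste(x$n, collapse = ", "),
      "  (n = ", sum(x$n), ")\n", sep = "")
  invisible(x)
}

#' Linear combination scores per category
#'
#' Projects every observation onto the combination vector `beta`, returning
#' one score vector per outcome category (in increasing category order).
#'
#' @param beta Numeric coefficient vector of length `d`. Need not be unit
#'   norm; all objectives are invariant to positive rescaling of `beta`.
#' @param data A [biomarker_data()] object.
#' @return Named list of numeric score vectors, one per category.
#' @examples
#' bd <- biomarker_groups(list(matrix(0, 1, 2), matrix(1, 1, 2)))
#' combination_scores(c(0.6, 0.8), bd)
#' @export
combination_scores <- function(beta, data) {
  s <- score_list(beta, data)
  names(s) <- data$levels
  s
}

# internal: unchecked-ish fast path shared by all objectives
score_list <- function(beta, data) {
  stopifnot(inherits(data, "biomarker_data"))
  beta <- as.numeric(beta)
  if (length(beta) != data$d) {
    stop("length of `beta` (", length(beta),
         ") does not match the number of markers (", data$d, ")")
  }
  if (!all(is.finite(beta))) stop("`beta` must be finite")
  lapply(data$groups, function(g) drop(g %*% beta))
}

# Euclidean norm / normalization helpers used throughout
l2norm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  nv <- l2norm(v)
  if (nv == 0) stop("cannot normalize the zero vector")
  v / nv
}
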