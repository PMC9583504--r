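#' Greedy correlation screening of markers
#'
#' Iteratively removes the marker with the highest mean absolute pairwise
#' correlation until all remaining pairwise correlations are below
#' `threshold`. Ties are broken toward the earliest column, so the result
#' is deterministic.
#'
#' @param x Numeric matrix or data frame of marker values (subjects in
#'   rows). Constant columns are an error: their correlation is undefined.
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return Integer vector of retained column indices, with attribute
#'   `"removed"` holding the removed indices in removal order.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x <- cbind(x, x[, 1] + rnorm(100, sd = 0.1))  # near-duplicate of column 1
#' greedy_correlation_filter(x, 0.8)
#' @export
greedy_correlation_filter <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("at least two markers are required")
  if (!(threshold > 0 && threshold <= 1)) {
    stop("`threshold` must be in (0, 1]")
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    stop("constant marker column(s): ",
         paste(which(sds == 0 | is.na(sds)), collapse = ", "),
         " (correlation undefined)")
  }
  keep <- seq_len(ncol(x))
  removed <- integer(0)
  cm <- abs(stats::cor(x))
  diag(cm) <- 0
  while (length(keep) > 1L && max(cm[keep, keep]) >= threshold) {
    mean_abs <- rowMeans(cm[keep, keep, drop = FALSE])
    worst <- keep[which.max(mean_abs)]  # which.max takes the first on ties
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  structure(keep, removed = removed, threshold = threshold)
}

#' Youden-index cut-points for an ordinal outcome
#'
#' For each of the M - 1 adjacent splits of the ordered categories
#' (categories <= j versus > j), finds the score threshold maximizing
#' Youden's index, sensitivity + specificity - 1, over the midpoints of
#' adjacent sorted unique scores (an exhaustive set of candidate decision
#' thresholds). Ties are broken toward the smallest threshold. The summary
#' value is the mean of the per-split maxima; with three or more categories
#' treat it as one reasonable aggregation, and consult the per-split values.
#'
#' @param scores Numeric combination scores, one per subject.
#' @param labels Ordinal outcome labels, one per subject.
#' @param levels Optional explicit increasing category order.
#' @return An object of class `"hum_cutpoints"`: list with `splits` (data
#'   frame: split, threshold, sensitivity, specificity, youden), `youden`
#'   (summary value) and `levels`.
#' @examples
#' yc <- youden_cutpoints(c(1, 2, 3, 2.5, 4, 5), rep(0:1, each = 3))
#' yc
#' @export
youden_cutpoints <- function(scores, labels, levels = NULL) {
  scores <- as.numeric(scores)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length")
  }
  if (is.null(levels)) levels <- sort(unique(labels))
  levels <- as.character(levels)
  labels <- as.character(labels)
  if (!all(labels %in% levels)) stop("labels outside `levels`")
  M <- length(levels)
  if (M < 2L) stop("at least two categories must be present")
  cls <- match(labels, levels)

  rows <- lapply(seq_len(M - 1L), function(j) {
    pos <- cls > j
    su <- sort(unique(scores))
    mid <- if (length(su) > 1L) (su[-length(su)] + su[-1L]) / 2 else numeric(0)
    # midpoints of adjacent unique scores exhaust the informative thresholds;
    # the two out-of-range thresholds (classify-none / classify-all, J = 0)
    # complete "all possible" cut-offs
    cand <- c(su[1L] - 1, mid, su[length(su)] + 1)
    stats_at <- vapply(cand, function(cut) {
      c(sens = mean(scores[pos] > cut), spec = mean(scores[!pos] <= cut))
    }, numeric(2))
    jind <- stats_at["sens", ] + stats_at["spec", ] - 1
    best <- which.max(jind)  # first (smallest threshold) on ties
    data.frame(split = j, threshold = cand[best],
               sensitivity = stats_at["sens", best],
               specificity = stats_at["spec", best],
               youden = jind[best])
  })
  splits <- do.call(rbind, rows)
  rownames(splits) <- NULL
  structure(
    list(splits = splits, youden = mean(splits$youden), levels = levels),
    class = "hum_cutpoints"
  )
}

#' @export
print.hum_cutpoints <- function(x, ...) {
  cat("Youden-index cut-points (", length(x$levels), " ordered categories)\n",
      sep = "")
  print(x$splits, row.names = FALSE, digits = 4)
  cat("summary Youden index:", format(x$youden, digits = 4), "\n")
  invisible(x)
}

#' Stratified bootstrap confidence intervals for the HUM and coefficients
#'
#' Resamples subjects with replacement within each outcome category
#' (preserving the ordered-group design, so no category can empty),
#' re-estimates the combination on each resample, and returns normal-theory
#' intervals estimate +/- z * se_B, where se_B is the standard deviation of
#' the bootstrap replicates. Coefficient replicates are sign-aligned to the
#' point estimate before the standard error is computed (beta and -beta are
#' the same direction).
#'
#' @param data A [biomarker_data()] object.
#' @param B Number of bootstrap resamples, `>= 2`.
#' @param alpha Miscoverage level of the 100(1 - alpha)% interval.
#' @param estimator Function `data -> "hum_fit"`; defaults to
#'   [fit_combination()] with the given `method`/`objective`/`control`.
#' @inheritParams fit_combination
#' @param seed Optional integer seed.
#' @return An object of class `"hum_boot"`: list with `hum` (estimate, se,
#'   lower, upper), `beta` (data frame with one row per coefficient),
#'   `B`, `alpha`, and the matrix of replicate coefficients.
#' @export
bootstrap_ci <- function(data, B = 200L, alpha = 0.05,
                         method = "scor", objective = "ehum",
                         control = scor_control(), estimator = NULL,
                         seed = NULL) {
  stopifnot(inherits(data, "biomarker_data"), B >= 2, alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(estimator)) {
    estimator <- function(dat) {
      fit_combination(dat, method = method, objective = objective,
                      control = control)
    }
  }
  point <- estimator(data)
  z <- stats::qnorm(1 - alpha / 2)

  resample <- function() {
    biomarker_groups(
      lapply(data$groups, function(g) {
        g[sample.int(nrow(g), nrow(g), replace = TRUE), , drop = FALSE]
      }),
      levels = data$levels
    )
  }
  reps <- lapply(seq_len(B), function(b) {
    fit <- estimator(resample())
    b_aligned <- if (sum(fit$beta * point$beta) < 0) -fit$beta else fit$beta
    list(value = fit$value, beta = b_aligned)
  })
  vals <- vapply(reps, `[[`, numeric(1), "value")
  betas <- do.call(rbind, lapply(reps, `[[`, "beta"))

  se_hum <- stats::sd(vals)
  se_beta <- apply(betas, 2L, stats::sd)
  structure(
    list(
      hum = c(estimate = point$value, se = se_hum,
              lower = point$value - z * se_hum,
              upper = point$value + z * se_hum),
      beta = data.frame(estimate = point$beta, se = se_beta,
                        lower = point$beta - z * se_beta,
                        upper = point$beta + z * se_beta),
      B = B, alpha = alpha, replicates = betas
    ),
    class = "hum_boot"
  )
}

#' @export
print.hum_boot <- function(x, ...) {
  cat(sprintf("Stratified bootstrap (B = %d, %d%% CI)\n", x$B,
              round(100 * (1 - x$alpha))))
  cat(sprintf("  HUM: %.3f +/- %.3f  [%.3f, %.3f]\n",
              x$hum["estimate"], stats::qnorm(1 - x$alpha / 2) * x$hum["se"],
              x$hum["lower"], x$hum["upper"]))
  cat("  coefficients:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Collapse ordinal categories
#'
#' Merges outcome grades into coarser ordered classes (e.g. severity grades
#' 2-4 into a single "moderate to severe" class). The grouping must
#' preserve the category order: as the original grades increase, the
#' assigned class may never decrease.
#'
#' @param labels Vector of ordinal labels.
#' @param map Named vector mapping each original level (names) to its new
#'   class label (values).
#' @param levels Optional explicit increasing order of the original levels.
#' @return Ordered factor of collapsed labels, with attribute `"sizes"`
#'   giving the per-class counts.
#' @examples
#' grades <- c(0, 1, 2, 3, 4, 2, 0)
#' collapse_categories(grades, c("0" = 0, "1" = 1, "2" = 2, "3" = 2, "4" = 2))
#' @export
collapse_categories <- function(labels, map, levels = NULL) {
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels))
  levels <- as.character(levels)
  if (!all(labels %in% levels)) stop("labels outside `levels`")
  if (is.null(names(map)) || !all(levels %in% names(map))) {
    stop("`map` must be named and cover every original level")
  }
  new_by_level <- as.character(map[levels])
  # order preservation: the sequence of new classes along the ordered
  # original levels must be non-decreasing blocks
  ranks <- match(new_by_level, unique(new_by_level))
  if (is.unsorted(ranks)) {
    stop("`map` does not preserve the category order")
  }
  out <- factor(new_by_level[match(labels, levels)],
                levels = unique(new_by_level), ordered = TRUE)
  attr(out, "sizes") <- table(out)
  out
}
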