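#' Empirical hypervolume under the ROC manifold (EHUM)
#'
#' The empirical HUM of a candidate combination vector is the fraction of all
#' cross-category M-tuples (one observation from each category) whose
#' combination scores are strictly increasing in category order:
#' \deqn{D_E(\beta) = \frac{1}{n_1 \cdots n_M} \sum_{i_1} \cdots \sum_{i_M}
#'   I(\beta^T X_{M,i_M} > \cdots > \beta^T X_{1,i_1}).}
#' For M = 2 this is the Mann-Whitney estimate of the AUC; for M = 3 it is
#' the empirical volume under the ROC surface. Ties contribute zero (strict
#' inequalities), so tied scores can make the objective non-smooth on
#' measure-zero sets of `beta`.
#'
#' The value is computed by per-category sorting and cumulative chain
#' counting (O(n log n) per category boundary) rather than enumerating all
#' \eqn{\prod n_j} tuples, and is invariant to positive rescaling of `beta`
#' and to any strictly increasing transform applied to all scores.
#'
#' @inheritParams combination_scores
#' @return A single number in \[0, 1\].
#' @examples
#' bd <- biomarker_groups(list(matrix(c(0, 3)), matrix(c(1, 4))))
#' ehum(1, bd)  # 3 of the 4 pairs are correctly ordered
#' @seealso [ulba_pa()], [ulba_pm()], [fit_combination()]
#' @export
ehum <- function(beta, data) {
  ehum_from_scores(score_list(beta, data))
}

# chain-counting DP over ordered categories; scores is a list of numeric
# vectors in increasing category order
ehum_from_scores <- function(scores) {
  M <- length(scores)
  w <- rep(1, length(scores[[1L]]))
  prev <- scores[[1L]]
  for (j in 2:M) {
    o <- order(prev)
    cw <- cumsum(w[o])
    # number of strictly smaller previous scores, weighted by chain counts
    idx <- findInterval(scores[[j]], prev[o], left.open = TRUE)
    w <- c(0, cw)[idx + 1L]
    prev <- scores[[j]]
  }
  sum(w) / prod(vapply(scores, length, integer(1)))
}

#' Adjacent-category exceedance probability
#'
#' Mann-Whitney-type empirical estimate of
#' \eqn{P(\beta^T X_{j+1} > \beta^T X_j)}: the fraction of cross pairs in
#' which the score from category j+1 strictly exceeds the score from
#' category j.
#'
#' @inheritParams combination_scores
#' @param j Lower category index of the adjacent pair, `1 <= j <= M - 1`.
#' @return A single number in \[0, 1\].
#' @export
pairwise_exceedance <- function(beta, data, j) {
  s <- score_list(beta, data)
  M <- length(s)
  if (length(j) != 1L || is.na(j) || j < 1L || j > M - 1L) {
    stop("`j` must be a single index between 1 and M - 1 = ", M - 1L)
  }
  exceedance_from_scores(s[[j]], s[[j + 1L]])
}

exceedance_from_scores <- function(lower, upper) {
  sp <- sort(lower)
  sum(findInterval(upper, sp, left.open = TRUE)) /
    (length(lower) * length(upper))
}

#' ULBA objectives: average and minimum adjacent exceedance
#'
#' The upper- and lower-bound approach replaces the hard-to-maximize EHUM by
#' surrogates built from the M - 1 adjacent-category exceedance
#' probabilities: `ulba_pa()` returns their arithmetic mean
#' \eqn{P_A(\beta)} (associated with a lower bound on the HUM) and
#' `ulba_pm()` their minimum \eqn{P_M(\beta)} (an upper bound):
#' \deqn{\max\{0, (M-1) P_A(\beta) - (M-2)\} \le D(\beta) \le P_M(\beta).}
#' For M = 2 both coincide with [ehum()].
#'
#' @inheritParams combination_scores
#' @return A single number in \[0, 1\].
#' @export
ulba_pa <- function(beta, data) {
  s <- score_list(beta, data)
  mean(adjacent_exceedances(s))
}

#' @rdname ulba_pa
#' @export
ulba_pm <- function(beta, data) {
  s <- score_list(beta, data)
  min(adjacent_exceedances(s))
}

adjacent_exceedances <- function(scores) {
  M <- length(scores)
  vapply(seq_len(M - 1L), function(j) {
    exceedance_from_scores(scores[[j]], scores[[j + 1L]])
  }, numeric(1))
}

#' Single-marker EHUM with the best orientation
#'
#' Evaluates the EHUM of marker `k` alone at both orientations (+1 and -1)
#' and returns the better sign and its value. Used to rank markers in the
#' step-down comparator and to anchor or orient starting points; a tie is
#' broken toward +1.
#'
#' @param data A [biomarker_data()] object.
#' @param k Marker (column) index, `1 <= k <= d`.
#' @return List with elements `sign` (+1 or -1) and `value`.
#' @export
individual_ehum <- function(data, k) {
  stopifnot(inherits(data, "biomarker_data"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > data$d) {
    stop("`k` must be a single marker index between 1 and d = ", data$d)
  }
  s <- lapply(data$groups, function(g) g[, k])
  vp <- ehum_from_scores(s)
  vm <- ehum_from_scores(lapply(s, function(x) -x))
  if (vm > vp) list(sign = -1, value = vm) else list(sign = 1, value = vp)
}

#' Objective closure over a fixed dataset
#'
#' Returns a function of `beta` evaluating the chosen objective on `data`,
#' the form consumed by [scor_maximize()] and the comparator optimizers.
#'
#' @param data A [biomarker_data()] object.
#' @param objective One of `"ehum"`, `"ulba_pa"`, `"ulba_pm"`.
#' @return A function `beta -> value` with attribute `"objective"`.
#' @export
hum_objective <- function(data, objective = c("ehum", "ulba_pa", "ulba_pm")) {
  objective <- match.arg(objective)
  stopifnot(inherits(data, "biomarker_data"))
  groups <- data$groups
  d <- data$d
  f <- switch(objective,
    ehum = function(s) ehum_from_scores(s),
    ulba_pa = function(s) mean(adjacent_exceedances(s)),
    ulba_pm = function(s) min(adjacent_exceedances(s))
  )
  out <- function(beta) {
    if (length(beta) != d) {
      stop("length of `beta` does not match the number of markers")
    }
    f(lapply(groups, function(g) drop(g %*% beta)))
  }
  attr(out, "objective") <- objective
  out
}

# default starting point for data-driven fits: equal weights with each
# marker oriented by its individual EHUM
default_start <- function(data) {
  signs <- vapply(seq_len(data$d),
                  function(k) individual_ehum(data, k)$sign, numeric(1))
  signs / sqrt(data$d)
}
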