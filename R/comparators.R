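#' Fit an optimal biomarker combination
#'
#' High-level interface: estimates the unit-norm coefficient vector
#' maximizing the chosen objective on `data`, by the spherical pattern
#' search ([scor_maximize()]) or one of the comparator estimators.
#'
#' @param data A [biomarker_data()] object.
#' @param method One of `"scor"`, `"nm"` (anchored Nelder-Mead),
#'   `"stepdown"`, `"minmax"`.
#' @param objective One of `"ehum"`, `"ulba_pa"`, `"ulba_pm"`.
#' @param control A [scor_control()] list (used by `method = "scor"`).
#' @param start Optional starting vector for `"scor"`; defaults to equal
#'   weights with each marker oriented by its individual EHUM.
#' @return An object of class `"hum_fit"`: list with `beta` (unit norm;
#'   length 2 for `"minmax"`, which operates on the per-subject
#'   maximum/minimum reduction), `value` (achieved training objective),
#'   `method`, `objective` and `reduced` (`TRUE` for min-max).
#' @examples
#' set.seed(1)
#' bd <- generate_scenario(1, d = 3, M = 2, n_per_class = 20)
#' fit <- fit_combination(bd, method = "scor", objective = "ehum")
#' fit
#' @seealso [predict.hum_fit()], [run_experiment()]
#' @export
fit_combination <- function(data,
                            method = c("scor", "nm", "stepdown", "minmax"),
                            objective = c("ehum", "ulba_pa", "ulba_pm"),
                            control = scor_control(), start = NULL) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  switch(method,
    scor = {
      obj <- hum_objective(data, objective)
      if (is.null(start)) start <- default_start(data)
      fit <- scor_maximize(obj, start, control)
      hum_fit(fit$beta, fit$value, "scor", objective)
    },
    nm = nm_maximize(data, objective),
    stepdown = step_down(data, objective),
    minmax = min_max(data, objective)
  )
}

hum_fit <- function(beta, value, method, objective, reduced = FALSE) {
  structure(
    list(beta = beta, value = value, method = method,
         objective = objective, reduced = reduced),
    class = "hum_fit"
  )
}

#' @export
print.hum_fit <- function(x, ...) {
  cat("Biomarker combination fit (", x$method, ", ", x$objective, ")\n",
      sep = "")
  if (x$reduced) {
    cat("  subject-level reduction: score = b1 * max(markers) + b2 * min(markers)\n")
  }
  cat("  achieved objective: ", format(x$value, digits = 4), "\n", sep = "")
  cat("  coefficients: ", paste(format(round(x$beta, 4)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Combination scores for new subjects
#'
#' @param object A `"hum_fit"`.
#' @param newdata A [biomarker_data()] object or a numeric matrix of marker
#'   values. For a min-max fit the per-subject maximum/minimum reduction is
#'   applied before projection.
#' @param ... Unused.
#' @return For a matrix, a numeric score vector; for `biomarker_data`, a
#'   named list of per-category score vectors.
#' @export
predict.hum_fit <- function(object, newdata, ...) {
  project <- function(m) {
    if (object$reduced) {
      m <- cbind(apply(m, 1L, max), apply(m, 1L, min))
    }
    if (ncol(m) != length(object$beta)) {
      stop("newdata has ", ncol(m), " markers; fit expects ",
           length(object$beta))
    }
    drop(m %*% object$beta)
  }
  if (inherits(newdata, "biomarker_data")) {
    s <- lapply(newdata$groups, project)
    names(s) <- newdata$levels
    s
  } else {
    project(as.matrix(newdata))
  }
}

# internal: test-set EHUM of a fit
test_ehum <- function(fit, data) {
  ehum_from_scores(predict(fit, data))
}

#' Anchored Nelder-Mead comparator
#'
#' The first marker's coefficient is fixed at +1 or -1, whichever gives the
#' larger individual EHUM; the remaining d - 1 coefficients are then
#' optimized without constraint by the Nelder-Mead simplex
#' ([stats::optim()]), and the result is normalized to unit norm.
#'
#' @inheritParams fit_combination
#' @return A `"hum_fit"`.
#' @export
nm_maximize <- function(data, objective = c("ehum", "ulba_pa", "ulba_pm")) {
  objective <- match.arg(objective)
  stopifnot(inherits(data, "biomarker_data"))
  d <- data$d
  a1 <- individual_ehum(data, 1L)$sign
  obj <- hum_objective(data, objective)
  if (d == 1L) {
    return(hum_fit(a1, obj(a1), "nm", objective))
  }
  opt <- stats::optim(
    rep(0, d - 1L),
    function(p) -obj(c(a1, p)),
    method = "Nelder-Mead",
    control = list(maxit = 200L * (d - 1L))
  )
  beta <- unitize(c(a1, opt$par))
  hum_fit(beta, obj(beta), "nm", objective)
}

#' Step-down comparator
#'
#' Markers are ranked by their individual EHUM (descending; ties keep the
#' original column order). The top marker's coefficient is fixed at its
#' better sign, then markers are added one at a time, each new scalar
#' coefficient chosen to maximize the objective with all earlier
#' coefficients held fixed — a dense grid over \[-5, 5\] refined by
#' golden-section search around the best grid point. The final vector is
#' normalized.
#'
#' @inheritParams fit_combination
#' @param grid_n Number of grid points for each 1-D inner search.
#' @return A `"hum_fit"`.
#' @export
step_down <- function(data, objective = c("ehum", "ulba_pa", "ulba_pm"),
                      grid_n = 201L) {
  objective <- match.arg(objective)
  stopifnot(inherits(data, "biomarker_data"))
  d <- data$d
  obj <- hum_objective(data, objective)
  ind <- lapply(seq_len(d), function(k) individual_ehum(data, k))
  ord <- order(-vapply(ind, `[[`, numeric(1), "value"), seq_len(d))
  beta <- numeric(d)
  beta[ord[1L]] <- ind[[ord[1L]]]$sign
  if (d > 1L) {
    grid <- seq(-5, 5, length.out = grid_n)
    h <- grid[2L] - grid[1L]
    for (k in ord[-1L]) {
      f <- function(c) {
        b <- beta
        b[k] <- c
        obj(b)
      }
      gv <- vapply(grid, f, numeric(1))
      # ties broken toward the smallest coefficient magnitude, so a marker
      # that adds nothing is not handed an arbitrary large weight
      tied <- which(gv == max(gv))
      c0 <- grid[tied[which.min(abs(grid[tied]))]]
      ref <- stats::optimize(f, lower = c0 - h, upper = c0 + h,
                             maximum = TRUE)
      beta[k] <- if (ref$objective > max(gv)) ref$maximum else c0
    }
  }
  beta <- unitize(beta)
  hum_fit(beta, obj(beta), "stepdown", objective)
}

#' Min-max comparator
#'
#' Each subject's d marker values are reduced to their maximum and minimum,
#' and the single free direction of the resulting 2-marker combination is
#' chosen by dense search over the unit circle. After the O(d) reduction the
#' search cost does not depend on d. Requires `d >= 2`.
#'
#' @inheritParams fit_combination
#' @param n_angles Number of equally spaced angles searched on the circle.
#' @return A `"hum_fit"` with `reduced = TRUE`; `beta` has length 2
#'   (weights of the per-subject maximum and minimum) and `value` is the
#'   achieved objective of the reduced score on `data`.
#' @export
min_max <- function(data, objective = c("ehum", "ulba_pa", "ulba_pm"),
                    n_angles = 2000L) {
  objective <- match.arg(objective)
  stopifnot(inherits(data, "biomarker_data"))
  if (data$d < 2L) {
    stop("min-max reduction needs at least two markers")
  }
  red <- biomarker_groups(
    lapply(data$groups, function(g) {
      cbind(apply(g, 1L, max), apply(g, 1L, min))
    }),
    levels = data$levels
  )
  obj <- hum_objective(red, objective)
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  vals <- vapply(theta, function(a) obj(c(cos(a), sin(a))), numeric(1))
  best <- theta[which.max(vals)]
  hum_fit(c(cos(best), sin(best)), max(vals), "minmax", objective,
          reduced = TRUE)
}
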