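#' Scenario generators for the simulation study
#'
#' Draws ordered multi-group marker data from one of three designs, with
#' category index i running over 0, ..., M-1 and marker index j over
#' 1, ..., d:
#'
#' * **Scenario 1** — d-variate normal, mean
#'   \eqn{\mu_{ij} = (-1)^j \, i \, (1 + 0.1 (j - 1))}, identity covariance.
#'   Category 0 is centered at the origin; higher categories move outward
#'   along an alternating-sign direction.
#' * **Scenario 2** — same means with AR(1)-type covariance
#'   \eqn{a_{st} = 0.5^{|s-t|}} (correlated markers).
#' * **Scenario 3** — independent three-parameter Weibull margins: marker j
#'   in category i has scale \eqn{\lambda_i = i + 1}, shape
#'   \eqn{k_j = 0.5 j} and location \eqn{\gamma_j = (-5)^j} (support
#'   \eqn{[\gamma_j, \infty)}). Non-normal, heavy-tailed for small j, with
#'   category differences only through the scale.
#'
#' @param scenario 1, 2 or 3.
#' @param d Number of markers.
#' @param M Number of ordered categories.
#' @param n_per_class Sample size per category: a scalar or a length-M
#'   vector.
#' @param seed Optional integer seed (`set.seed()` is called when supplied);
#'   otherwise the current RNG state is used.
#' @return A [biomarker_data()] object with category labels `0:(M-1)`.
#' @examples
#' bd <- generate_scenario(1, d = 5, M = 2, n_per_class = 15, seed = 1)
#' bd
#' @export
generate_scenario <- function(scenario, d, M = 2L, n_per_class = 15L,
                              seed = NULL) {
  if (!scenario %in% 1:3) stop("`scenario` must be 1, 2 or 3")
  stopifnot(d >= 1, M >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- rep_len(as.integer(n_per_class), M)
  if (any(n < 1L)) stop("sample sizes must be positive")
  j <- seq_len(d)
  chol_S <- if (scenario == 2) {
    chol(0.5^abs(outer(j, j, "-")))
  } else NULL
  groups <- lapply(0:(M - 1L), function(i) {
    if (scenario %in% c(1, 2)) {
      mu <- (-1)^j * i * (1 + 0.1 * (j - 1))
      z <- matrix(stats::rnorm(n[i + 1L] * d), n[i + 1L], d)
      if (scenario == 2) z <- z %*% chol_S
      sweep(z, 2L, mu, "+")
    } else {
      vapply(j, function(jj) {
        stats::rweibull(n[i + 1L], shape = 0.5 * jj, scale = i + 1) +
          (-5)^jj
      }, numeric(n[i + 1L]))
    }
  })
  # vapply over markers returns a vector when n == 1
  groups <- lapply(groups, function(g) matrix(g, ncol = d))
  biomarker_groups(groups, levels = 0:(M - 1L))
}

#' Population-optimal direction for the normal scenarios
#'
#' For equal-covariance multivariate normal categories the HUM-optimal
#' combination for M = 2 is the Fisher direction
#' \eqn{\Sigma^{-1} (\mu_1 - \mu_0)}, which for Scenario 1 (identity
#' covariance) reduces to the normalized mean difference. Used as the truth
#' in parameter-recovery checks and as the `"oracle"` method of
#' [run_experiment()].
#'
#' @param scenario 1 or 2.
#' @param d Number of markers.
#' @return Unit-norm numeric vector of length `d`.
#' @export
scenario_optimal_direction <- function(scenario, d) {
  if (!scenario %in% 1:2) {
    stop("an analytic optimal direction is available for scenarios 1 and 2 only")
  }
  j <- seq_len(d)
  delta <- (-1)^j * (1 + 0.1 * (j - 1))
  if (scenario == 2) {
    S <- 0.5^abs(outer(j, j, "-"))
    delta <- solve(S, delta)
  }
  unitize(delta)
}

#' Train/test replication experiment
#'
#' Reproduces the simulation-study design: per replication, draw a training
#' set, estimate the combination vector by the chosen method and objective,
#' draw an independent test set of identical design, and record the EHUM of
#' the estimated vector on the test set.
#'
#' @inheritParams generate_scenario
#' @param method `"scor"`, `"nm"`, `"stepdown"`, `"minmax"`, or `"oracle"`
#'   (the analytic direction of [scenario_optimal_direction()]; no
#'   training-data fit).
#' @param objective Training objective: `"ehum"`, `"ulba_pa"` or
#'   `"ulba_pm"`. The test-set metric is always EHUM.
#' @param reps Number of replications.
#' @param control A [scor_control()] list for `method = "scor"`.
#' @param seed Optional integer seed for reproducibility of the whole
#'   experiment.
#' @return An object of class `"hum_experiment"`: list with `test_ehum`
#'   (length-`reps` vector), `mean`, `sd` (dispersion across replications),
#'   `se` (`sd/sqrt(reps)`) and the experiment settings.
#' @examples
#' ex <- run_experiment(1, d = 3, M = 2, n_per_class = 10, method = "oracle",
#'                      reps = 5, seed = 1)
#' ex
#' @export
run_experiment <- function(scenario, d, M = 2L, n_per_class = 15L,
                           method = c("scor", "nm", "stepdown", "minmax",
                                      "oracle"),
                           objective = c("ehum", "ulba_pa", "ulba_pm"),
                           reps = 100L, control = scor_control(),
                           seed = NULL) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  oracle <- if (method == "oracle") {
    hum_fit(scenario_optimal_direction(scenario, d), NA_real_, "oracle",
            objective)
  } else NULL
  vals <- vapply(seq_len(reps), function(r) {
    train <- generate_scenario(scenario, d, M, n_per_class)
    fit <- if (method == "oracle") {
      oracle
    } else {
      fit_combination(train, method = method, objective = objective,
                      control = control)
    }
    test <- generate_scenario(scenario, d, M, n_per_class)
    test_ehum(fit, test)
  }, numeric(1))
  structure(
    list(test_ehum = vals,
         mean = mean(vals),
         sd = stats::sd(vals),
         se = stats::sd(vals) / sqrt(reps),
         scenario = scenario, d = d, M = M,
         n_per_class = rep_len(n_per_class, M),
         method = method, objective = objective, reps = reps),
    class = "hum_experiment"
  )
}

#' @export
print.hum_experiment <- function(x, ...) {
  cat("Train/test replication experiment\n")
  cat(sprintf("  scenario %d, d = %d, M = %d, n = (%s), %s/%s, %d reps\n",
              x$scenario, x$d, x$M, paste(x$n_per_class, collapse = ","),
              x$method, x$objective, x$reps))
  cat(sprintf("  mean test EHUM %.3f (sd %.3f, se %.4f)\n",
              x$mean, x$sd, x$se))
  invisible(x)
}

#' Orientation-aligned mean squared error of coefficient estimates
#'
#' Because the objectives are invariant to the sign convention of the score
#' (beta and -beta describe the same separating direction up to
#' orientation), each estimate is first flipped into the half-space of the
#' truth; the MSE is then the average squared Euclidean distance.
#'
#' @param estimates A numeric vector, a list of vectors, or a matrix with
#'   one estimate per row.
#' @param truth Unit-norm reference vector.
#' @return Mean squared Euclidean distance after sign alignment.
#' @examples
#' truth <- c(1, 0)
#' coefficient_mse(list(truth, -truth), truth)  # antipodal estimates: 0
#' @export
coefficient_mse <- function(estimates, truth) {
  truth <- as.numeric(truth)
  if (is.numeric(estimates) && is.null(dim(estimates))) {
    estimates <- list(estimates)
  }
  if (is.matrix(estimates)) {
    estimates <- asplit(estimates, 1L)
  }
  sq <- vapply(estimates, function(e) {
    e <- as.numeric(e)
    if (length(e) != length(truth)) {
      stop("estimate and truth dimensions differ")
    }
    if (sum(e * truth) < 0) e <- -e
    sum((e - truth)^2)
  }, numeric(1))
  mean(sq)
}
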