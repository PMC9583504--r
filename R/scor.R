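#' Tuning parameters for the spherical pattern search
#'
#' @param s_init Initial (and per-run reset) step size, `> phi`. Large
#'   values promote distant exploratory moves early in a run.
#' @param rho Step decay rate, `> 1`. The step size is divided by `rho`
#'   whenever an iteration improves the incumbent by less than `tol_fun`;
#'   the same divisor shrinks a per-direction local step until its
#'   adjustment root becomes real.
#' @param phi Step-size threshold, `> 0`. A run ends once its step size
#'   falls below `phi`; a direction is abandoned for the iteration once its
#'   local step does.
#' @param tol_fun Minimum improvement that keeps the step size unchanged.
#' @param lambda Sparsity threshold: before each move on coordinate i, every
#'   other coefficient with absolute value below `lambda` is set to zero and
#'   the unit-norm adjustment is computed over the remaining coordinates.
#'   Use 0 (default) when no sparse solution is expected.
#' @param max_iter Iteration cap per run.
#' @param max_runs Cap on the number of runs.
#' @param stall_runs Stop after this many consecutive runs that fail to
#'   improve the incumbent value by at least `tol_fun`. Complements the
#'   identical-solution stopping rule, which cannot fire while equal-valued
#'   (tie) moves keep relocating the solution along a flat plateau.
#' @param maximize Orientation flag; set `FALSE` to minimize.
#'
#' @return A list of class `"scor_control"`.
#' @seealso [scor_maximize()]
#' @export
scor_control <- function(s_init = 2, rho = 1.5, phi = 1e-6, tol_fun = 1e-6,
                         lambda = 0, max_iter = 50000L, max_runs = 1000L,
                         stall_runs = 10L, maximize = TRUE) {
  stopifnot(s_init > phi, phi > 0, rho > 1, tol_fun >= 0, lambda >= 0,
            max_iter >= 1, max_runs >= 1, stall_runs >= 1)
  structure(
    list(s_init = s_init, rho = rho, phi = phi, tol_fun = tol_fun,
         lambda = lambda, max_iter = as.integer(max_iter),
         max_runs = as.integer(max_runs),
         stall_runs = as.integer(stall_runs),
         maximize = isTRUE(maximize)),
    class = "scor_control"
  )
}

#' Read optimizer settings from a YAML or JSON file
#'
#' Field names mirror the arguments of [scor_control()]; unknown fields are
#' an error.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A `"scor_control"` list.
#' @export
scor_control_from_file <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON configuration requires the 'jsonlite' package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(scor_control)))
  if (length(unknown)) {
    stop("unknown scor_control field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(scor_control, vals)
}

#' Unit-norm adjustment step
#'
#' When coordinate `i` of a unit vector is perturbed by `s`, every other
#' active coordinate must receive a common adjustment `t` for the move to
#' land back on the unit sphere. With m active coordinates,
#' B = sum of the active coefficients and Z = squared mass of the zeroed
#' coordinates, `t` solves
#' \deqn{m t^2 + 2 B t + (2 s \beta_i + s^2 - Z) = 0.}
#' Of the two real roots the one of smaller absolute value is returned, so
#' that the move contracts to the identity as `s -> 0`; a negative
#' discriminant means no on-sphere adjustment exists for this step size,
#' which is a normal outcome reported as `NA` (callers shrink the step and
#' retry).
#'
#' @param beta Unit-norm numeric vector.
#' @param i Index of the coordinate receiving the step.
#' @param s Signed step size (0 is allowed and yields `t = 0`).
#' @param active Indices adjusted by `t`; defaults to all coordinates except
#'   `i`. Coordinates in neither `active` nor `i` are treated as zeroed by
#'   the sparsity rule.
#' @return The adjustment `t`, or `NA_real_` when no real root exists.
#' @examples
#' b <- c(0.289, -0.816, 0.5) / sqrt(sum(c(0.289, -0.816, 0.5)^2))
#' t2 <- adjustment_step(b, 2, 0.03)
#' moved <- b + c(t2, 0.03, t2)
#' sum(moved^2)  # back on the unit sphere
#' @export
adjustment_step <- function(beta, i, s, active = NULL) {
  d <- length(beta)
  if (is.null(active)) active <- setdiff(seq_len(d), i)
  m <- length(active)
  if (m == 0L) return(NA_real_)
  B <- sum(beta[active])
  zeroed <- setdiff(seq_len(d), c(i, active))
  C <- 2 * s * beta[i] + s * s - sum(beta[zeroed]^2)
  disc <- B * B - m * C
  if (disc < 0) return(NA_real_)
  sq <- sqrt(disc)
  r1 <- (-B + sq) / m
  r2 <- (-B - sq) / m
  if (abs(r1) <= abs(r2)) r1 else r2
}

#' Sparsity screening before a coordinate move
#'
#' Zeroes every coefficient other than `beta[i]` whose absolute value is
#' below `lambda` and reports the surviving (active) adjustment
#' coordinates, over which [adjustment_step()] restores unit norm exactly.
#'
#' @param beta Unit-norm numeric vector.
#' @param i Coordinate about to receive the exploratory step (never zeroed).
#' @param lambda Sparsity threshold, `>= 0`.
#' @return List with `beta` (screened vector) and `active` (integer indices).
#' @export
apply_sparsity <- function(beta, i, lambda) {
  stopifnot(lambda >= 0)
  d <- length(beta)
  others <- setdiff(seq_len(d), i)
  zero <- others[abs(beta[others]) < lambda]
  beta[zero] <- 0
  list(beta = beta, active = setdiff(others, zero))
}

# One exploratory move: perturb coordinate i by the (decaying) local step
# sgn * s, adjust the active coordinates back onto the sphere. Returns the
# candidate or NULL when the direction is abandoned (|local step| < phi
# without a real root).
scor_move <- function(beta, i, sgn, s, control) {
  d <- length(beta)
  if (d == 1L) {
    return(list(beta = sgn, step = sgn * s))
  }
  scr <- apply_sparsity(beta, i, control$lambda)
  sl <- sgn * s
  if (length(scr$active) == 0L) {
    # everything else zeroed: the only on-sphere moves are the poles
    bi <- beta[i] + sl
    if (bi == 0) return(NULL)
    cand <- numeric(d)
    cand[i] <- sign(bi)
    return(list(beta = cand, step = sl))
  }
  repeat {
    # original beta carries the zeroed coordinates' squared mass into the
    # constant term of the quadratic
    t <- adjustment_step(beta, i, sl, scr$active)
    if (!is.na(t)) break
    sl <- sl / control$rho
    if (abs(sl) < control$phi) return(NULL)
  }
  cand <- scr$beta
  cand[scr$active] <- cand[scr$active] + t
  cand[i] <- cand[i] + sl
  list(beta = cand / l2norm(cand), step = sl)
}

#' Candidate solutions of one pattern-search iteration
#'
#' Generates the up-to-2d unit-norm candidates around the current solution:
#' for every coordinate a positive and a negative exploratory step, each
#' with its unit-norm adjustment applied to the remaining (active)
#' coordinates. Directions whose local step decayed below `phi` without a
#' real adjustment root are omitted. Candidates appear in the deterministic
#' scan order coordinate 1 "+", coordinate 1 "-", coordinate 2 "+", ... used
#' for tie-breaking.
#'
#' @param beta Current unit-norm solution.
#' @param s Current (positive) step size.
#' @param control A [scor_control()] list.
#' @return List of candidates, each a list with `beta`, `i`, `sign` and the
#'   local `step` actually used.
#' @export
scor_candidates <- function(beta, s, control = scor_control()) {
  d <- length(beta)
  out <- vector("list", 2L * d)
  k <- 0L
  for (i in seq_len(d)) {
    for (sgn in c(1, -1)) {
      mv <- scor_move(beta, i, sgn, s, control)
      if (is.null(mv)) next
      k <- k + 1L
      out[[k]] <- list(beta = mv$beta, i = i, sign = sgn, step = mv$step)
    }
  }
  out[seq_len(k)]
}

# One iteration: evaluate the candidate set, take the argmax over the 2d+1
# points (candidates preferred on exact ties with the incumbent, earliest
# candidate preferred among tied candidates), decay the step when the
# improvement falls short of tol_fun.
scor_step <- function(state, objective, control) {
  cands <- scor_candidates(state$beta, state$step, control)
  best_v <- -Inf
  best_b <- NULL
  for (cand in cands) {
    v <- objective(cand$beta)
    state$evaluations <- state$evaluations + 1L
    if (v > best_v) {
      best_v <- v
      best_b <- cand$beta
    }
  }
  improvement <- 0
  if (!is.null(best_b) && best_v >= state$value) {
    improvement <- best_v - state$value
    state$beta <- best_b
    state$value <- best_v
  }
  if (improvement < control$tol_fun) {
    state$step <- state$step / control$rho
  }
  state$iteration <- state$iteration + 1L
  state
}

# One run: iterate from a reset step size until the step falls below phi or
# the iteration cap is reached.
scor_run <- function(objective, state, control, trace_env) {
  state$step <- control$s_init
  state$iteration <- 0L
  while (state$step >= control$phi && state$iteration < control$max_iter) {
    state <- scor_step(state, objective, control)
    if (!is.null(trace_env)) {
      trace_env$run[[length(trace_env$run) + 1L]] <- state$run
      trace_env$iteration[[length(trace_env$iteration) + 1L]] <- state$iteration
      trace_env$step[[length(trace_env$step) + 1L]] <- state$step
      trace_env$value[[length(trace_env$value) + 1L]] <- state$value
    }
  }
  state
}

#' Maximize a black-box function on the unit sphere
#'
#' Derivative-free pattern search over the surface of the unit sphere in
#' `d` dimensions. Each iteration perturbs every coordinate of the current
#' solution by +/- the current step size, restores unit norm through the
#' [adjustment_step()] applied to the remaining coordinates, and adopts the
#' best of the 2d candidates and the incumbent; the step size decays
#' geometrically when no sufficient improvement is found. Runs restart the
#' step size from `s_init` at the current solution; the search stops when
#' two consecutive runs return the same solution, when `stall_runs`
#' consecutive runs fail to improve the value, or at `max_runs`.
#'
#' Designed for the discontinuous, piecewise-constant, multi-modal
#' objectives arising from empirical HUM estimation, but applicable to any
#' bounded function of a unit vector (e.g. single-index or directional
#' problems where the norm is fixed for identifiability).
#'
#' @param objective Function mapping a unit-norm numeric vector to a single
#'   finite number.
#' @param start Starting vector of length `d`; normalized (with a warning)
#'   when its norm is not 1 within 1e-8. Vectors such as rounded reported
#'   solutions are accepted.
#' @param control A [scor_control()] list.
#' @param trace Logical; record the per-iteration step size and incumbent
#'   value (modest overhead, useful for diagnostics).
#' @return An object of class `"scor_fit"`: list with `beta` (the solution,
#'   unit norm), `value` (objective at `beta`, on the original scale also
#'   for minimization), `runs`, `evaluations`, `converged` (`TRUE` unless
#'   the run cap was hit) and, when `trace = TRUE`, a data frame `trace`
#'   with columns run/iteration/step/value.
#' @examples
#' # the maximizer of a linear functional v'beta on the sphere is v/||v||
#' fit <- scor_maximize(function(b) sum(b * c(3, 4)), start = c(1, 0))
#' round(fit$beta, 3)
#' @export
scor_maximize <- function(objective, start, control = scor_control(),
                          trace = FALSE) {
  stopifnot(is.function(objective), inherits(control, "scor_control"))
  start <- as.numeric(start)
  if (length(start) < 1L || !all(is.finite(start))) {
    stop("`start` must be a finite numeric vector")
  }
  if (abs(l2norm(start) - 1) > 1e-8) {
    warning("`start` does not have unit norm; normalizing")
  }
  beta <- unitize(start)
  obj <- if (control$maximize) objective else function(b) -objective(b)

  state <- list(beta = beta, value = obj(beta), step = control$s_init,
                iteration = 0L, run = 0L, evaluations = 1L)
  trace_env <- if (trace) {
    new.env(parent = emptyenv())
  } else NULL
  if (trace) {
    trace_env$run <- list(); trace_env$iteration <- list()
    trace_env$step <- list(); trace_env$value <- list()
  }

  prev_beta <- NULL
  stall <- 0L
  converged <- FALSE
  run_values <- numeric(0)
  for (r in seq_len(control$max_runs)) {
    state$run <- r
    v0 <- state$value
    state <- scor_run(obj, state, control, trace_env)
    run_values[r] <- state$value
    if (!is.null(prev_beta) &&
        max(abs(state$beta - prev_beta)) < 1e-12) {
      converged <- TRUE
      break
    }
    stall <- if (state$value - v0 < control$tol_fun) stall + 1L else 0L
    if (stall >= control$stall_runs) {
      converged <- TRUE
      break
    }
    prev_beta <- state$beta
  }

  out <- list(
    beta = state$beta,
    value = if (control$maximize) state$value else -state$value,
    runs = state$run,
    run_values = if (control$maximize) run_values else -run_values,
    evaluations = state$evaluations,
    converged = converged
  )
  if (trace) {
    out$trace <- data.frame(
      run = unlist(trace_env$run),
      iteration = unlist(trace_env$iteration),
      step = unlist(trace_env$step),
      value = if (control$maximize) unlist(trace_env$value) else
        -unlist(trace_env$value)
    )
  }
  class(out) <- "scor_fit"
  out
}

#' @export
print.scor_fit <- function(x, ...) {
  cat("Spherical pattern-search fit\n")
  cat("  value: ", format(x$value, digits = 6),
      "  (", x$evaluations, " evaluations, ", x$runs, " runs)\n", sep = "")
  cat("  beta:  ", paste(format(round(x$beta, 4)), collapse = " "), "\n",
      sep = "")
  invisible(x)
}
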