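test_that("adjustment step solves the unit-norm quadratic", {
  set.seed(23)
  for (r in 1:25) {
    d <- sample(2:6, 1)
    beta <- random_unit(d)
    i <- sample(d, 1)
    s <- runif(1, -0.5, 0.5)
    t <- adjustment_step(beta, i, s)
    if (is.na(t)) next
    moved <- beta
    moved[-i] <- moved[-i] + t
    moved[i] <- moved[i] + s
    expect_equal(sum(moved^2), 1, tolerance = 1e-12)
    # independent root check: polyroot of (d-1) t^2 + 2Bt + (2 s b_i + s^2)
    roots <- polyroot(c(2 * s * beta[i] + s^2, 2 * sum(beta[-i]), d - 1))
    roots <- Re(roots[abs(Im(roots)) < 1e-9])
    expect_equal(t, roots[which.min(abs(roots))], tolerance = 1e-9)
  }
})

test_that("adjustment step handles a rounded reported solution point", {
  # rounded solution point (0.289, -0.816, 0.5), exploratory move on the
  # second coordinate with s = 0.03
  beta <- c(0.289, -0.816, 0.5)
  beta <- beta / sqrt(sum(beta^2))
  t2 <- adjustment_step(beta, 2, 0.03)
  expect_false(is.na(t2))
  moved <- beta + c(t2, 0.03, t2)
  expect_equal(sum(moved^2), 1, tolerance = 1e-10)
})

test_that("degenerate geometry reports no real root", {
  # from (1, 0) a step +0.5 on coordinate 1 cannot stay on the circle
  expect_true(is.na(adjustment_step(c(1, 0), 1, 0.5)))
  # s = 0 gives the identity move
  expect_equal(adjustment_step(random_unit(4), 2, 0), 0)
})

test_that("chosen root vanishes as the step size shrinks", {
  set.seed(29)
  for (r in 1:50) {
    d <- sample(2:5, 1)
    beta <- random_unit(d)
    i <- sample(d, 1)
    for (sgn in c(1, -1)) {
      ts <- vapply(10^-(3:10), function(s) {
        abs(adjustment_step(beta, i, sgn * s))
      }, numeric(1))
      # a root exists for all sufficiently small steps ...
      real <- !is.na(ts)
      first_ok <- if (all(real)) 1L else max(which(!real)) + 1L
      expect_lte(first_ok, length(ts) - 2L)
      # ... and its magnitude shrinks to zero with the step
      tail_ts <- ts[first_ok:length(ts)]
      expect_true(all(diff(tail_ts) <= 1e-8))
      expect_lt(tail_ts[length(tail_ts)], 1e-4)
    }
  }
})

test_that("geometric step halving eventually yields a real root", {
  set.seed(31)
  for (r in 1:100) {
    d <- sample(2:6, 1)
    beta <- random_unit(d)
    i <- sample(d, 1)
    s <- runif(1, -2, 2)
    k <- 0
    while (is.na(adjustment_step(beta, i, s / 2^k)) && k < 200) k <- k + 1
    expect_lt(k, 200)
  }
})

test_that("sparsity screening zeroes small coefficients", {
  beta <- random_unit(5)
  scr <- apply_sparsity(beta, 2, 0)
  expect_equal(scr$active, c(1, 3, 4, 5))
  expect_equal(scr$beta, beta)

  scr1 <- apply_sparsity(beta, 2, 1)
  expect_equal(scr1$active, integer(0))
  expect_equal(scr1$beta[-2], rep(0, 4))

  # screened move still lands on the sphere via the generalized quadratic
  b <- c(0.9, 0.1, sqrt(1 - 0.81 - 0.01))
  scr2 <- apply_sparsity(b, 1, 0.2)
  expect_equal(scr2$active, 3L)
  expect_equal(scr2$beta[2], 0)
  t <- adjustment_step(b, 1, 0.05, active = scr2$active)
  moved <- scr2$beta
  moved[1] <- moved[1] + 0.05
  moved[3] <- moved[3] + t
  expect_equal(sum(moved^2), 1, tolerance = 1e-12)
})

test_that("candidate sets stay on the sphere and respect the 2d cap", {
  set.seed(37)
  ctrl <- scor_control()
  for (r in 1:20) {
    d <- sample(2:5, 1)
    beta <- random_unit(d)
    cands <- scor_candidates(beta, runif(1, 0.01, 2), ctrl)
    expect_lte(length(cands), 2 * d)
    for (cand in cands) {
      expect_equal(sum(cand$beta^2), 1, tolerance = 1e-8)
    }
  }
  # an interior point with a modest step admits all 2d moves
  beta <- random_unit(3)
  cands <- scor_candidates(beta, 1e-3, ctrl)
  expect_length(cands, 6L)
  expect_equal(vapply(cands, `[[`, numeric(1), "i"), rep(1:3, each = 2))
  expect_equal(vapply(cands, `[[`, numeric(1), "sign"), rep(c(1, -1), 3))
})

test_that("linear objectives are maximized at the analytic optimum", {
  v <- c(3, 4) / 5
  fit <- scor_maximize(function(b) sum(b * v), start = c(1, 0))
  expect_equal(fit$beta, v, tolerance = 1e-4)
  expect_equal(fit$value, 1, tolerance = 1e-6)

  # f(beta) = beta_1 over the 3-sphere peaks at e_1
  fit3 <- scor_maximize(function(b) b[1], start = random_unit(3))
  expect_equal(fit3$beta, c(1, 0, 0), tolerance = 1e-4)

  # minimization reverses the orientation
  fitm <- scor_maximize(function(b) sum(b * v), start = c(0, 1),
                        control = scor_control(maximize = FALSE))
  expect_equal(fitm$beta, -v, tolerance = 1e-4)
  expect_equal(fitm$value, -1, tolerance = 1e-6)
})

test_that("every evaluated point is unit norm and the incumbent never falls", {
  set.seed(41)
  for (r in 1:5) {
    bd <- random_data(2, 3, n_range = 6:10)
    obj <- hum_objective(bd, "ehum")
    norms <- new.env(parent = emptyenv())
    norms$bad <- 0L
    wrapped <- function(b) {
      if (abs(sqrt(sum(b^2)) - 1) > 1e-8) norms$bad <- norms$bad + 1L
      obj(b)
    }
    fit <- scor_maximize(wrapped, start = random_unit(3), trace = TRUE)
    expect_identical(norms$bad, 0L)
    expect_true(all(diff(fit$trace$value) >= 0))
    expect_true(all(diff(fit$run_values) >= 0))
    expect_equal(fit$value, obj(fit$beta))
  }
})

test_that("step sizes decay geometrically within a run", {
  bd <- random_data(2, 2, n_range = 4:6)
  fit <- scor_maximize(hum_objective(bd, "ehum"), start = c(1, 1) / sqrt(2),
                       trace = TRUE)
  ctrl <- scor_control()
  run1 <- fit$trace[fit$trace$run == 1, ]
  expect_true(all(diff(run1$step) <= 1e-12))
  shrunk <- run1$step[-1][diff(run1$step) < 0]
  kept <- run1$step[-nrow(run1)][diff(run1$step) < 0]
  expect_equal(shrunk, kept / ctrl$rho)
})

test_that("separable two-group data reaches the attainable maximum", {
  g0 <- matrix(c(0, 0.2, 0.1, 0.15), 2, 2)
  g1 <- matrix(c(3, 3.3, 3.2, 2.9), 2, 2)
  bd <- biomarker_groups(list(g0, g1))
  fit <- fit_combination(bd, "scor", "ehum")
  expect_equal(fit$value, 1)
})

test_that("the search terminates and is deterministic", {
  set.seed(43)
  bd <- random_data(2, 3, n_range = 5:8)
  obj <- hum_objective(bd, "ehum")
  ctrl <- scor_control(max_runs = 400)
  f1 <- scor_maximize(obj, start = rep(1, 3) / sqrt(3), control = ctrl)
  f2 <- scor_maximize(obj, start = rep(1, 3) / sqrt(3), control = ctrl)
  expect_true(f1$converged)
  expect_lte(f1$runs, 400)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$evaluations, f2$evaluations)

  # an iteration cap of 1 per run still returns a valid point
  quick <- scor_maximize(obj, start = rep(1, 3) / sqrt(3),
                         control = scor_control(max_iter = 1, max_runs = 3))
  expect_equal(sum(quick$beta^2), 1, tolerance = 1e-8)
})

test_that("one-dimensional problems reduce to the two poles", {
  bd <- biomarker_groups(list(matrix(c(2, 3)), matrix(c(0, 1))))
  fit <- fit_combination(bd, "scor", "ehum")
  expect_equal(abs(fit$beta), 1)
  expect_equal(fit$value, 1)  # -1 orientation separates perfectly
  expect_equal(fit$beta, -1)
})

test_that("non-unit starting points are normalized with a warning", {
  expect_warning(
    fit <- scor_maximize(function(b) sum(b * c(1, 0)), start = c(2, 2)),
    "normalizing"
  )
  expect_equal(fit$value, 1, tolerance = 1e-6)
})

test_that("control validation and file round-trip work", {
  expect_error(scor_control(rho = 1), "rho")
  expect_error(scor_control(s_init = 1e-9), "s_init")
  cfg <- tempfile(fileext = ".json")
  writeLines('{"s_init": 1.5, "rho": 2, "lambda": 0.1}', cfg)
  ctrl <- scor_control_from_file(cfg)
  expect_equal(ctrl$s_init, 1.5)
  expect_equal(ctrl$lambda, 0.1)
  writeLines('{"bogus": 1}', cfg)
  expect_error(scor_control_from_file(cfg), "unknown")
  unlink(cfg)
})
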