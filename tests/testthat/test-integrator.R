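test_that("integrator preserves rest and constant fields", {
  m <- ei_model(table1)
  rest <- find_fixed_point(m, 0, c(0.1, 0.1))$state
  tr <- wc_integrate(m, rest, t_end = 500, J = 0)
  expect_lt(max(abs(sweep(tr$states, 2, rest))), 1e-5)
  # an identically zero vector field gives a constant trajectory
  null_model <- structure(list(name = "null", n = 2L, vars = c("a", "b"),
                               rhs = function(u, J) c(0, 0),
                               jac = function(u, J) matrix(0, 2, 2),
                               jac_J = function(u, J) c(0, 0),
                               params = table1, symmetric = FALSE),
                          class = "wc_model")
  tr0 <- wc_integrate(null_model, c(0.3, 0.7), t_end = 100, J = 1)
  expect_true(all(tr0$states[, 1] == 0.3 & tr0$states[, 2] == 0.7))
  expect_error(wc_integrate(m, c(1.5, 0.2), 100), "\\[0, 1\\]")
})

test_that("trajectories started in the unit hypercube stay there", {
  set.seed(3)
  m2 <- ei_model(table1); m3 <- eie_model(table1, Delta = 0)
  for (i in 1:5) {
    tr <- wc_integrate(m2, runif(2), t_end = 300, J = runif(1, 0, 2))
    expect_true(all(tr$states >= -1e-6 & tr$states <= 1 + 1e-6))
    tr <- wc_integrate(m3, runif(3), t_end = 300, J = runif(1, 0, 2))
    expect_true(all(tr$states >= -1e-6 & tr$states <= 1 + 1e-6))
  }
})

test_that("halving the error tolerances barely moves the solution", {
  m <- ei_model(table1)
  rest <- find_fixed_point(m, 0, c(0.1, 0.1))$state
  a <- wc_integrate(m, rest, 300, J = 1, atol = 1e-6, rtol = 1e-6)
  b <- wc_integrate(m, rest, 300, J = 1, atol = 5e-7, rtol = 5e-7)
  keep <- a$times >= 100
  expect_lt(max(abs(a$states[keep, 1] - b$states[keep, 1])), 1e-4)
})

test_that("oscillation metrics recover a known sinusoid and flag flat lines", {
  tt <- seq(0, 1000, by = 1)
  x <- 0.5 + 0.2 * sin(2 * pi * 12.5 / 1000 * tt)
  om <- oscillation_metrics(make_traj(tt, cbind(x, x)), transient = 100)
  expect_true(om$is_oscillating)
  expect_lt(abs(om$frequency - 12.5) / 12.5, 0.01)
  flat <- make_traj(tt, cbind(rep(0.3, length(tt)), rep(0.3, length(tt))))
  om0 <- oscillation_metrics(flat, transient = 100)
  expect_false(om0$is_oscillating)
  expect_true(is.na(om0$frequency))
  expect_error(oscillation_metrics(make_traj(tt, cbind(x, x)),
                                   transient = 999), "too short")
})

test_that("the E-I model oscillates near 20 Hz under constant drive", {
  m <- ei_model(table1)
  rest <- find_fixed_point(m, 0, c(0.1, 0.1))$state
  tr <- wc_integrate(m, rest, t_end = 1500, J = 1)
  om <- oscillation_metrics(tr, transient = 500)
  expect_true(om$is_oscillating)
  expect_gt(om$frequency, 15)
  expect_lt(om$frequency, 25)
  # envelope brackets the resting level, as in the bifurcation diagram
  expect_lt(om$amplitude_min[1], 0.12)
  expect_gt(om$amplitude_max[1], 0.12)
})

test_that("winner classification follows the larger oscillation and its mirror", {
  tt <- seq(0, 1000, by = 1)
  osc <- 0.5 + 0.4 * sin(2 * pi * 20 / 1000 * tt)
  flat <- rep(0.05, length(tt))
  tr <- make_traj(tt, cbind(osc, flat, flat), c("U_e1", "U_e2", "U_i"))
  expect_identical(winner(tr), "e1")
  tr_sw <- make_traj(tt, cbind(flat, osc, flat), c("U_e1", "U_e2", "U_i"))
  expect_identical(winner(tr_sw), "e2")
  # near-identical ranges are undecided, not silently assigned
  tr_tie <- make_traj(tt, cbind(osc, 0.5 + 0.41 * sin(2 * pi * 20 / 1000 * tt),
                                flat), c("U_e1", "U_e2", "U_i"))
  expect_identical(winner(tr_tie), "undecided")
  # flat trajectories fall back to comparing means
  tr_mean <- make_traj(tt, cbind(rep(0.4, length(tt)), rep(0.1, length(tt)),
                                 flat), c("U_e1", "U_e2", "U_i"))
  expect_identical(winner(tr_mean), "e1")
  expect_error(winner(make_traj(tt, cbind(osc, flat))), "3 state")
})

test_that("trial ensembles are deterministic and conserve counts", {
  a <- run_trials(table1, J = 2, Delta = 0, n_trials = 60, seed = 5)
  b <- run_trials(table1, J = 2, Delta = 0, n_trials = 60, seed = 5)
  expect_identical(a[c("n_e1", "n_e2", "n_undecided", "fraction_e1")],
                   b[c("n_e1", "n_e2", "n_undecided", "fraction_e1")])
  expect_identical(a$n_e1 + a$n_e2 + a$n_undecided, a$n_trials)
  expect_gte(a$fraction_e1, 0); expect_lte(a$fraction_e1, 100)
  # the normal-approximation 99% half-width matches its closed form
  phat <- a$n_e1 / a$n_trials
  expect_equal(a$ci_99, 100 * 2.576 * sqrt(phat * (1 - phat) / a$n_trials))
})

test_that("a ramped strong bias makes e1 win every trial", {
  ts <- run_trials(table1, J = 2, Delta = 0.2, n_trials = 40, seed = 2,
                   onset = "ramped")
  expect_identical(ts$n_e1, 40L)
  expect_identical(ts$n_e2, 0L)
})

test_that("false-positive fraction decreases with stimulus bias", {
  fp <- vapply(c(0, 0.03, 0.2), function(D)
    run_trials(table1, J = 2, Delta = D, n_trials = 300, seed = 11)$n_e2 / 300,
    numeric(1))
  expect_gt(fp[1], fp[2] + 0.1)   # ~50% vs ~25%, far beyond sampling noise
  expect_gt(fp[2], fp[3] + 0.1)   # ~25% vs 0%
  expect_identical(fp[3], 0)
})
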