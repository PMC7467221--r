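test_that("a decoupled branch reproduces its closed form with no special points", {
  p0 <- wc_params(w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0)
  m <- ei_model(p0)
  br <- continue_equilibria(m, 0, 1, u0 = c(0.1, 0.1))
  # U_e* = F(J - b_e), U_i* = F(-b_i) exactly
  expect_equal(br$states[, 1], firing_rate(br$J - p0$b_e), tolerance = 1e-8)
  expect_equal(br$states[, 2], rep(firing_rate(-p0$b_i), length(br$J)),
               tolerance = 1e-8)
  expect_identical(nrow(detect_hopf(br, m)), 0L)
  expect_identical(nrow(detect_special_points(br, m)), 0L)
  expect_true(all(br$stable))
})

test_that("a linear system with a known Hopf crossing is located to 1e-6", {
  # eigenvalues (J - 0.5) +/- i: analytic crossing at J = 0.5
  lin <- structure(list(
    name = "lin", n = 2L, vars = c("u1", "u2"),
    rhs = function(u, J) c((J - 0.5) * u[1] - u[2], u[1] + (J - 0.5) * u[2]),
    jac = function(u, J) matrix(c(J - 0.5, -1, 1, J - 0.5), 2, byrow = TRUE),
    jac_J = function(u, J) c(u[1], u[2]),
    params = table1, symmetric = FALSE), class = "wc_model")
  br <- continue_equilibria(lin, 0, 1, u0 = c(0, 0), max_step = 0.05)
  h <- detect_hopf(br, lin, tol = 1e-10)
  expect_identical(nrow(h), 1L)
  expect_lt(abs(h$J - 0.5), 1e-6)
})

test_that("branch states re-verify against dense pointwise root solves", {
  m <- ei_model(table1)
  br <- continue_equilibria(m, 0, 1, u0 = c(0.1, 0.1))
  # every stored state is an equilibrium to the advertised tolerance
  for (i in seq_along(br$J))
    expect_lt(max(abs(m$rhs(br$states[i, ], br$J[i]))), 1e-10)
  # independent per-J Newton solves on a dense grid stay on the branch
  for (J in seq(0.05, 0.95, by = 0.05)) {
    i <- which.min(abs(br$J - J))
    fp <- find_fixed_point(m, J, br$states[i, ])
    expect_lt(max(abs(m$rhs(fp$state, J))), 1e-10)
    # linear interpolation of the branch agrees with the direct solve
    interp <- vapply(seq_len(m$n), function(k)
      stats::approx(br$J, br$states[, k], xout = J)$y, numeric(1))
    expect_lt(max(abs(fp$state - interp)), 1e-3)
  }
})

test_that("the E-I equilibrium loses stability via a Hopf near J = 0.41", {
  m <- ei_model(table1)
  br <- continue_equilibria(m, 0, 1, u0 = c(0.1, 0.1))
  h <- detect_hopf(br, m)
  expect_identical(nrow(h), 1L)
  expect_lt(abs(h$J - 0.41), 0.01)
  expect_gt(h$omega, 0)          # genuinely complex pair
  # invariance under step halving
  br2 <- continue_equilibria(m, 0, 1, u0 = c(0.1, 0.1), max_step = 0.05)
  h2 <- detect_hopf(br2, m)
  expect_lt(abs(h$J - h2$J), 1e-4)
  # stability flips exactly once, at the Hopf
  flips <- which(diff(br$stable) != 0)
  expect_identical(length(flips), 1L)
  expect_true(br$J[flips] <= h$J && h$J <= br$J[flips + 1])
})

test_that("the ambiguous E-I-E model has a pitchfork at J = 1 and mirror branches", {
  m <- eie_model(table1, Delta = 0)
  br <- continue_equilibria(m, 0, 2, u0 = c(0.1, 0.1, 0.1))
  sp <- detect_special_points(br, m)
  bp <- sp[sp$kind == "BP", ]
  expect_identical(nrow(bp), 1L)
  expect_lt(abs(bp$J - 1.00), 0.02)
  expect_lt(abs(bp$U_e1 - bp$U_e2), 1e-8)   # on the symmetric branch
  # the two bifurcating branches are exact exchange images
  up <- branch_switch(m, bp[1, ], J_range = c(bp$J + 0.02, 2), direction = 1)
  dn <- branch_switch(m, bp[1, ], J_range = c(bp$J + 0.02, 2), direction = -1)
  expect_true(any(abs(up$states[, 1] - up$states[, 2]) > 1e-3))
  expect_lt(max(abs(up$states[, c(2, 1, 3)] - dn$states)), 1e-8)
  # asymmetric equilibria destabilize via a Hopf shortly above J = 1.4
  h <- detect_hopf(up, m)
  expect_identical(nrow(h), 1L)
  expect_lte(abs(h$J - 1.4), 0.05)
  expect_equal(round(h$J, 1), 1.4)
})

test_that("weak bias destroys the pitchfork and leaves a limit point near 1.32", {
  m <- eie_model(table1, Delta = 0.03)
  main <- continue_equilibria(m, 0, 2, u0 = c(0.1, 0.1, 0.1))
  expect_identical(nrow(detect_special_points(main, m)), 0L)  # imperfect
  h_main <- detect_hopf(main, m)
  expect_identical(nrow(h_main), 1L)
  expect_lt(abs(h_main$J - 1.34), 0.02)
  # the minor (e2-dominant) branch folds at the limit point
  eqs <- find_equilibria(m, J = 2, n_grid = 4)
  minor <- eqs[which.max(eqs[, 2] - eqs[, 1]), ]
  br <- continue_equilibria(m, 2, 1, u0 = minor, max_step = 0.05)
  sp <- detect_special_points(br, m)
  lp <- sp[sp$kind == "LP", ]
  expect_identical(nrow(lp), 1L)
  expect_lt(abs(lp$J - 1.32), 0.02)
  expect_lt(min(br$J), 1.33)   # the fold was actually rounded
  h_minor <- detect_hopf(br, m)
  expect_true(any(abs(h_minor$J - 1.56) < 0.02))
})

test_that("strong bias pushes the limit point out of range", {
  m <- eie_model(table1, Delta = 0.2)
  br <- continue_equilibria(m, 0, 2, u0 = c(0.1, 0.1, 0.1))
  sp <- detect_special_points(br, m)
  expect_identical(nrow(sp), 0L)
  h <- detect_hopf(br, m)
  expect_identical(nrow(h), 1L)
  expect_lt(abs(h$J - 0.84), 0.02)   # e1 oscillation onset
})

test_that("cycle envelope collapses below the Hopf and grows like sqrt(J - J_H)", {
  m <- ei_model(table1)
  env <- cycle_envelope(m, c(0.39, seq(0.42, 0.5, by = 0.02), 1),
                        t_end = 4000, transient = 3000)
  w <- env$u_max - env$u_min
  expect_lt(w[1], 1e-3)                       # no oscillation below onset
  expect_gt(w[length(w)], 0.5)                # full limit cycle at J = 1
  expect_true(env$u_min[nrow(env)] < 0.12 && 0.12 < env$u_max[nrow(env)])
  # supercritical normal form: squared width linear in J
  sub <- env$J >= 0.42 & env$J <= 0.5
  fit <- stats::lm(I(w[sub]^2) ~ env$J[sub])
  expect_gt(summary(fit)$r.squared, 0.95)
})
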