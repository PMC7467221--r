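dom <- wc_domain(4, 0.01)

test_that("domain construction validates its grid", {
  expect_identical(dom$n, 400L)
  expect_equal(dom$x[2] - dom$x[1], 0.01)
  expect_error(wc_domain(1, 0.003), "integer")
})

test_that("kernels are normalized, peaked at delta, and resolvable", {
  k0 <- make_kernel(0.05, 0, dom)
  expect_equal(sum(k0$weights) * dom$dx, 1, tolerance = 1e-12)
  # even symmetry about x = 0 on the periodic grid
  expect_equal(k0$weights[2:dom$n], rev(k0$weights[2:dom$n]),
               tolerance = 1e-12)
  ks <- make_kernel(0.05, 0.02, dom)
  expect_identical(which.max(ks$weights),
                   which.min(abs(dom$x - 0.02)))
  # the continuum normalization 1/(sigma sqrt(pi)) integrates to 1:
  # direct quadrature before renormalization
  for (sig in c(0.05, 0.15)) {
    xm <- ifelse(dom$x > 2, dom$x - 4, dom$x)
    raw <- exp(-(xm - 0.02)^2 / sig^2) / (sig * sqrt(pi))
    expect_equal(sum(raw) * dom$dx, 1, tolerance = 1e-6)
  }
  expect_error(make_kernel(0.015, 0, dom), "resolvable")
  expect_error(make_kernel(0.05, 3, dom), "L/2")
})

test_that("spectral convolution matches the direct sum and the closed form", {
  small <- wc_domain(1, 0.01)
  k <- make_kernel(0.05, 0.02, small)
  set.seed(1)
  u <- runif(small$n)
  expect_equal(circular_convolve(u, k),
               direct_convolve(u, k$weights, small$dx), tolerance = 1e-10)
  # a constant field maps to itself
  expect_equal(circular_convolve(rep(0.37, small$n), k),
               rep(0.37, small$n), tolerance = 1e-12)
  # a unit impulse returns the translated kernel
  imp <- rep(0, small$n); imp[11] <- 1 / small$dx
  expect_equal(circular_convolve(imp, k),
               k$weights[((seq_len(small$n) - 11) %% small$n) + 1],
               tolerance = 1e-9)
  # cosine input: Gaussian gain exp(-(pi f sigma)^2), phase shift 2 pi f delta
  f <- 3
  u <- cos(2 * pi * f * small$x)
  gain <- exp(-(pi * f * k$sigma)^2)
  expect_equal(circular_convolve(u, k),
               gain * cos(2 * pi * f * (small$x - k$delta)),
               tolerance = 1e-8)
  # the lateral input is the reflected-kernel convolution
  krefl <- make_kernel(0.05, -0.02, small)
  expect_equal(lateral_input(u, k), circular_convolve(u, krefl),
               tolerance = 1e-12)
})

test_that("Mexican hat combines the kernels and reports its dominant mode", {
  ke <- make_kernel(table1$sigma_e, 0, dom)
  ki <- make_kernel(table1$sigma_i, 0, dom)
  hat <- mexican_hat(table1, ke, ki)
  # dense evaluation oracle for the profile and its zero crossings
  ord <- order(ifelse(dom$x > 2, dom$x - 4, dom$x))
  oracle <- (table1$w_ee * ke$weights - table1$w_ei * ki$weights)[ord]
  expect_equal(hat$profile, oracle, tolerance = 1e-12)
  sign_flips <- which(diff(sign(hat$profile)) != 0)
  expect_identical(length(sign_flips), 2L)            # core flanked by surround
  expect_gt(hat$profile[which.min(abs(hat$x))], 0)    # excitatory core
  # dominant mode equals the argmax of the closed-form transform of the
  # difference of Gaussians on the discrete mode grid
  fgrid <- (1:(dom$n / 2 - 1)) / dom$L
  gf <- table1$w_ee * exp(-(pi * fgrid * table1$sigma_e)^2) -
    table1$w_ei * exp(-(pi * fgrid * table1$sigma_i)^2)
  expect_equal(hat$dominant_fx, fgrid[which.max(abs(gf))])
  # pure Gaussian (no inhibition): monotone spectrum, lowest mode dominates
  hat0 <- mexican_hat(wc_params(w_ei = 0), ke, ki)
  expect_equal(hat0$dominant_fx, 1 / dom$L)
})

test_that("the grating stimulus has the advertised range, mean and speed", {
  g0 <- grating_field(dom, f_x = 2.5, f_t = -15, alpha = 1, t = 0)
  expect_equal(g0[1], 1)                       # cos(0) = 1 at x = 0, t = 0
  expect_true(all(g0 >= 0 & g0 <= 1))
  expect_equal(mean(g0), 0.5, tolerance = 1e-12)
  # f_t = 0 freezes the pattern
  expect_equal(grating_field(dom, 2.5, 0, t = 123), g0, tolerance = 1e-12)
  # the pattern translates by f_t/f_x mm per ms (leftward for f_t < 0)
  dt_ms <- 10
  g1 <- grating_field(dom, 2.5, -15, t = dt_ms)
  shift_mm <- (-15 / 1000) / 2.5 * dt_ms
  shift_pts <- round(shift_mm / dom$dx)
  expect_equal(g1, g0[((seq_len(dom$n) - 1 - shift_pts) %% dom$n) + 1],
               tolerance = 1e-9)
  expect_error(grating_field(dom, f_x = 2.6, f_t = 0), "2.5")
})

test_that("uniform fields reduce exactly to the point models", {
  # E-I: field RK4 versus an independent point-model RK4 at the same step
  p <- table1
  f <- simulate_field("ei", p, dom, J = 1, t_end = 60, dt = 0.1, dt_out = 1,
                      init = list(rep(0.2, dom$n), rep(0.3, dom$n)))
  ref <- rk4_point(function(u) oracle_ei_rhs(u, p, 1), c(0.2, 0.3), 60, 0.1)
  ref <- ref[seq(10, 600, by = 10), ]
  expect_lt(max(abs(sweep(f$activity$U_e, 1, ref[, 1]))), 1e-9)
  expect_lt(max(abs(sweep(f$activity$U_i, 1, ref[, 2]))), 1e-9)
  # E-I-E with its opposed kernel shifts reduces just the same
  f3 <- simulate_field("eie", p, dom, J = 1.5, t_end = 60, dt = 0.1,
                       dt_out = 1,
                       init = list(rep(0.1, dom$n), rep(0.4, dom$n),
                                   rep(0.25, dom$n)))
  ref3 <- rk4_point(function(u) oracle_eie_rhs(u, p, 1.5, 0),
                    c(0.1, 0.4, 0.25), 60, 0.1)
  ref3 <- ref3[seq(10, 600, by = 10), ]
  for (k in 1:3)
    expect_lt(max(abs(sweep(f3$activity[[k]], 1, ref3[, k]))), 1e-9)
})

test_that("solutions are equivariant under grid translation", {
  shift <- 37L
  roll <- function(v) v[((seq_along(v) - 1 - shift) %% length(v)) + 1]
  set.seed(9)
  init <- list(0.12 + 1e-3 * runif(dom$n, -1, 1),
               0.17 + 1e-3 * runif(dom$n, -1, 1))
  a <- simulate_field("ei", table1, dom, J = 1, t_end = 150, dt_out = 10,
                      init = init)
  b <- simulate_field("ei", table1, dom, J = 1, t_end = 150, dt_out = 10,
                      init = lapply(init, roll))
  expect_lt(max(abs(b$activity$U_e - t(apply(a$activity$U_e, 1, roll)))),
            1e-9)
})

test_that("the spatial E-I-E model has mirror/exchange symmetry", {
  set.seed(13)
  init <- list(0.12 + 1e-3 * runif(dom$n, -1, 1),
               0.12 + 1e-3 * runif(dom$n, -1, 1),
               0.17 + 1e-3 * runif(dom$n, -1, 1))
  a <- simulate_field("eie", table1, dom, J = 1, t_end = 200, dt_out = 20,
                      init = init)
  # mirroring space and swapping the two excitatory layers maps solutions
  # to solutions (kernel shifts are opposite, the inhibitory kernel even)
  init_m <- list(mirror_field(init[[2]]), mirror_field(init[[1]]),
                 mirror_field(init[[3]]))
  b <- simulate_field("eie", table1, dom, J = 1, t_end = 200, dt_out = 20,
                      init = init_m)
  mirror_rows <- function(M) t(apply(M, 1, mirror_field))
  expect_lt(max(abs(b$activity$U_e1 - mirror_rows(a$activity$U_e2))), 1e-9)
  expect_lt(max(abs(b$activity$U_e2 - mirror_rows(a$activity$U_e1))), 1e-9)
  expect_lt(max(abs(b$activity$U_i - mirror_rows(a$activity$U_i))), 1e-9)
})

test_that("field values remain within the unit interval", {
  f <- simulate_field("ei", wc_params(delta = 0), dom, J = 1, t_end = 400,
                      seed = 2)
  expect_true(all(f$activity$U_e >= 0 & f$activity$U_e <= 1))
  expect_true(all(f$activity$U_i >= 0 & f$activity$U_i <= 1))
})

test_that("halving dx leaves the emergent pattern on the same spatial mode", {
  f1 <- simulate_field("ei", wc_params(delta = 0), wc_domain(4, 0.01),
                       t_end = 1200, seed = 1)
  f2 <- simulate_field("ei", wc_params(delta = 0, dx = 0.005),
                       wc_domain(4, 0.005), t_end = 1200, seed = 1)
  fx1 <- dominant_spatial_frequency(f1, transient = 400)
  fx2 <- dominant_spatial_frequency(f2, transient = 400)
  expect_lte(abs(fx1 - fx2), 0.25 + 1e-9)
})
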