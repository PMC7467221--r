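#' Periodic 1-D spatial domain
#'
#' A ring of cortical tissue of length `L` mm discretized at step `dx`.
#' `L/dx` must be an integer; `L` should be chosen so an integer number of
#' stimulus wavelengths fit (the default 4 mm holds exactly 10 wavelengths
#' of a 2.5 cycles/mm grating).
#'
#' @param L Domain length (mm).
#' @param dx Grid spacing (mm).
#' @return A `wc_domain` list: `L`, `dx`, `n` (grid points), `x`
#'   (coordinates, `0 <= x < L`).
#' @export
#' @examples
#' d <- wc_domain()
#' d$n
wc_domain <- function(L = 4, dx = 0.01) {
  n <- L / dx
  if (abs(n - round(n)) > 1e-9)
    stop("L/dx must be an integer (got ", n, ")")
  n <- as.integer(round(n))
  structure(list(L = L, dx = dx, n = n, x = (0:(n - 1)) * dx),
            class = "wc_domain")
}

#' @export
print.wc_domain <- function(x, ...) {
  cat(sprintf("periodic domain: L = %g mm, dx = %g mm, %d points\n",
              x$L, x$dx, x$n))
  invisible(x)
}

#' Discretized shifted-Gaussian coupling kernel
#'
#' Evaluates `K(x) = exp(-(x - delta)^2 / sigma^2) / (sigma sqrt(pi))` on
#' the periodic grid using the minimal-image distance, then renormalizes
#' the weights so that `sum(weights) * dx = 1` (a uniform field is mapped
#' to itself). The continuum kernel integrates to 1 by construction, so the
#' renormalization only absorbs discretization and wrap-around error.
#'
#' @param sigma Spatial spread (mm); must be resolvable, `sigma >= 2 dx`.
#' @param delta Spatial shift of the peak (mm), `|delta| < L/2`.
#' @param domain A [wc_domain()].
#' @return A `wc_kernel`: `weights` (length-n vector, peak at the grid
#'   point nearest `delta`), `wfft` (its FFT, cached for convolution),
#'   `sigma`, `delta`, `domain`.
#' @export
#' @examples
#' k <- make_kernel(0.05, 0.02, wc_domain())
#' sum(k$weights) * 0.01   # 1
make_kernel <- function(sigma, delta = 0, domain = wc_domain()) {
  if (sigma < 2 * domain$dx)
    stop("sigma = ", sigma, " not resolvable by dx = ", domain$dx,
         " (need sigma >= 2 dx)")
  if (abs(delta) >= domain$L / 2)
    stop("|delta| must be smaller than L/2")
  xm <- ifelse(domain$x > domain$L / 2, domain$x - domain$L, domain$x)
  w <- exp(-((xm - delta)^2) / sigma^2) / (sigma * sqrt(pi))
  w <- w / (sum(w) * domain$dx)
  structure(list(weights = w, wfft = stats::fft(w), sigma = sigma,
                 delta = delta, domain = domain),
            class = "wc_kernel")
}

#' Circular convolution of a field with a kernel
#'
#' Spectral (FFT) implementation of the periodic spatial summation
#' `V(x) = integral K(x - x') U(x') dx'`, i.e. plain convolution scaled by
#' `dx`. A constant field maps to the same constant for any normalized
#' kernel. For the reflected orientation used by the field models see
#' [lateral_input()].
#'
#' @param u Field values on the domain grid.
#' @param kernel A [make_kernel()] object.
#' @return The weighted activity V on the same grid.
#' @export
circular_convolve <- function(u, kernel) {
  n <- length(u)
  if (n != kernel$domain$n) stop("field and kernel grids differ")
  Re(stats::fft(stats::fft(u) * kernel$wfft, inverse = TRUE)) / n *
    kernel$domain$dx
}

#' Lateral synaptic input (reflected-kernel orientation)
#'
#' Circular cross-correlation `V(x) = integral K(x' - x) U(x') dx'`,
#' equivalent to convolving with the spatially reflected kernel. This is
#' the orientation under which a kernel with positive shift `delta` tunes
#' the medium to leftward-traveling waves (negative temporal frequency),
#' matching the direction convention of the drifting-grating stimulus; it
#' is fixed empirically by the direction-selectivity tests.
#'
#' @inheritParams circular_convolve
#' @return The weighted activity V on the same grid.
#' @export
lateral_input <- function(u, kernel) {
  n <- length(u)
  if (n != kernel$domain$n) stop("field and kernel grids differ")
  Re(stats::fft(stats::fft(u) * Conj(kernel$wfft), inverse = TRUE)) / n *
    kernel$domain$dx
}

#' Effective Mexican-hat coupling profile
#'
#' Combines the excitatory and inhibitory kernels into the net lateral
#' coupling `w_ee K_e(x) - w_ei K_i(x)` (short-range excitation,
#' longer-range inhibition) and reports the dominant spatial frequency of
#' the profile: the location of the maximum of its spatial Fourier
#' magnitude, excluding the zero mode.
#'
#' @param params A [wc_params()] object (weights `w_ee`, `w_ei`).
#' @param kernel_e,kernel_i Excitatory and inhibitory [make_kernel()]
#'   objects on the same domain.
#' @return A list: `profile` (per mm), `x` (minimal-image coordinates,
#'   for plotting), `dominant_fx` (cycles/mm).
#' @export
mexican_hat <- function(params, kernel_e, kernel_i) {
  params <- as_wc_params(params)
  d <- kernel_e$domain
  if (!identical(d$n, kernel_i$domain$n)) stop("kernels on different grids")
  prof <- params$w_ee * kernel_e$weights - params$w_ei * kernel_i$weights
  spec <- Mod(stats::fft(prof))
  half <- 2:(floor(d$n / 2))          # positive non-zero modes
  dominant <- (which.max(spec[half])) / d$L
  xm <- ifelse(d$x > d$L / 2, d$x - d$L, d$x)
  ord <- order(xm)
  list(profile = prof[ord], x = xm[ord], dominant_fx = dominant)
}

#' Drifting sinusoidal grating stimulus
#'
#' `J(x, t) = alpha/2 (cos(2 pi f_x x - 2 pi f_t t) + 1)`, valued in
#' `[0, alpha]`. Negative temporal frequency means leftward motion (phase
#' speed `f_t / f_x` mm/ms with `f_t` in cycles/ms). The spatial frequency
#' must be commensurate with the domain (integer number of wavelengths),
#' otherwise the periodic wrap would introduce a phase jump.
#'
#' @param domain A [wc_domain()].
#' @param f_x Spatial frequency (cycles/mm).
#' @param f_t Temporal frequency in Hz (converted internally to cycles/ms).
#' @param alpha Amplitude.
#' @param t Time (ms).
#' @return Stimulus values on the domain grid at time `t`.
#' @export
#' @examples
#' g <- grating_field(wc_domain(), f_x = 2.5, f_t = -15, t = 0)
#' range(g)
grating_field <- function(domain, f_x, f_t, alpha = 1, t = 0) {
  check_commensurate(f_x, domain)
  ft_ms <- f_t / 1000
  alpha / 2 * (cos(2 * pi * f_x * domain$x - 2 * pi * ft_ms * t) + 1)
}

check_commensurate <- function(f_x, domain) {
  k <- f_x * domain$L
  if (abs(k - round(k)) > 1e-9)
    stop("spatial frequency ", f_x, " cycles/mm is incommensurate with L = ",
         domain$L, " mm; nearest commensurate value is ",
         round(k) / domain$L)
  invisible(round(k))
}

#' Right-hand sides of the spatial models
#'
#' Field versions of the point-model vector fields: the pointwise sigmoid
#' is applied to spatially weighted activity computed by [lateral_input()]
#' with each population's kernel, and the stimulus drives the excitatory
#' population(s) only. With uniform fields and a uniform stimulus both
#' reduce exactly to the point-model equations at every grid point.
#'
#' @param U_e,U_i,U_e1,U_e2 Field vectors on the domain grid.
#' @param params A [wc_params()] object.
#' @param kernel_e,kernel_i,kernel_e1,kernel_e2 [make_kernel()] objects;
#'   in the E-I-E model the two excitatory kernels carry opposite shifts.
#' @param J_field Stimulus field on the grid (vector or scalar).
#' @return A list of field time derivatives, one element per population.
#' @export
spatial_ei_rhs <- function(U_e, U_i, params, kernel_e, kernel_i, J_field) {
  V_e <- lateral_input(U_e, kernel_e)
  V_i <- lateral_input(U_i, kernel_i)
  list(
    dU_e = (-U_e + firing_rate(params$w_ee * V_e - params$w_ei * V_i -
                                 params$b_e + J_field)) / params$tau_e,
    dU_i = (-U_i + firing_rate(params$w_ie * V_e - params$w_ii * V_i -
                                 params$b_i)) / params$tau_i)
}

#' @rdname spatial_ei_rhs
#' @export
spatial_eie_rhs <- function(U_e1, U_e2, U_i, params,
                            kernel_e1, kernel_e2, kernel_i, J_field) {
  V_e1 <- lateral_input(U_e1, kernel_e1)
  V_e2 <- lateral_input(U_e2, kernel_e2)
  V_i <- lateral_input(U_i, kernel_i)
  list(
    dU_e1 = (-U_e1 + firing_rate(params$w_ee * V_e1 - params$w_ei * V_i -
                                   params$b_e + J_field)) / params$tau_e,
    dU_e2 = (-U_e2 + firing_rate(params$w_ee * V_e2 - params$w_ei * V_i -
                                   params$b_e + J_field)) / params$tau_e,
    dU_i = (-U_i + firing_rate(params$w_ie * V_e1 + params$w_ie * V_e2 -
                                 params$w_ii * V_i - params$b_i)) /
      params$tau_i)
}

#' Simulate a spatial model
#'
#' Integrates the 1-D field equations with a fixed-step fourth-order
#' Runge-Kutta scheme (FFT-based lateral input each stage) and records the
#' fields on a uniform output grid. The initial condition is the
#' homogeneous resting state of the corresponding point model at J = 0
#' plus a seeded uniform perturbation of amplitude `perturb` per grid
#' point, emulating pattern formation from near-homogeneity.
#'
#' The stimulus is either spatially uniform of amplitude `J` or a drifting
#' grating (pass a `grating` list with `f_x`, `f_t` in Hz, and optionally
#' `alpha`). For the E-I model the excitatory kernel shift is
#' `params$delta`; for the E-I-E model layer e1 uses `+params$delta`
#' (leftward-tuned) and layer e2 the negated shift (rightward-tuned), and
#' the stimulus is applied identically to both excitatory layers.
#'
#' @param model `"ei"` or `"eie"`.
#' @param params A [wc_params()] object (`sigma_e`, `sigma_i`, `delta`
#'   control the kernels).
#' @param domain A [wc_domain()].
#' @param J Uniform stimulus amplitude (ignored when `grating` is given).
#' @param grating Optional list `list(f_x =, f_t =, alpha =)`.
#' @param t_end Simulated duration (ms).
#' @param dt Integration step (ms).
#' @param dt_out Output sampling step (ms).
#' @param seed Seed for the initial perturbation.
#' @param perturb Perturbation amplitude.
#' @param init Optional explicit initial condition: a list of field
#'   vectors, one per population (overrides the seeded default).
#' @return A `wc_field`: `times` (ms), `x` (mm), `activity` (named list of
#'   time-by-space matrices, one per population), and metadata including
#'   `dt_out`, `dx`, the stimulus and the seed.
#' @export
#' @examples
#' \donttest{
#' f <- simulate_field("ei", wc_params(delta = 0), t_end = 300, seed = 1)
#' dim(f$activity$U_e)
#' }
simulate_field <- function(model = c("ei", "eie"), params = wc_params(),
                           domain = wc_domain(), J = 1, grating = NULL,
                           t_end = 2000, dt = 0.1, dt_out = 1, seed = 1,
                           perturb = 1e-3, init = NULL) {
  model <- match.arg(model)
  params <- as_wc_params(params)
  n <- domain$n
  kernel_i <- make_kernel(params$sigma_i, 0, domain)
  if (model == "ei") {
    kernel_e <- make_kernel(params$sigma_e, params$delta, domain)
    point <- ei_model(params)
    pops <- c("U_e", "U_i")
  } else {
    kernel_e1 <- make_kernel(params$sigma_e, params$delta, domain)
    kernel_e2 <- make_kernel(params$sigma_e, -params$delta, domain)
    point <- eie_model(params, Delta = 0)
    pops <- c("U_e1", "U_e2", "U_i")
  }
  npop <- length(pops)

  stim <- if (is.null(grating)) {
    force(J)
    function(t) J
  } else {
    if (is.null(grating$alpha)) grating$alpha <- params$alpha
    check_commensurate(grating$f_x, domain)
    ft_ms <- grating$f_t / 1000
    phase0 <- 2 * pi * grating$f_x * domain$x
    function(t) grating$alpha / 2 * (cos(phase0 - 2 * pi * ft_ms * t) + 1)
  }

  if (is.null(init)) {
    rest <- find_fixed_point(point, J = 0,
                             guess = rep(c(0.1, 0.1), length.out = point$n))
    if (!rest$converged) stop("resting state did not converge")
    set.seed(seed)
    init <- lapply(seq_len(npop), function(k)
      rest$state[k] + perturb * stats::runif(n, -1, 1))
  }
  if (length(init) != npop || any(lengths(init) != n))
    stop("init must supply one length-", n, " field per population")
  U <- do.call(cbind, init)   # n x npop

  rhs <- if (model == "ei") {
    function(U, t) {
      d <- spatial_ei_rhs(U[, 1], U[, 2], params, kernel_e, kernel_i,
                          stim(t))
      cbind(d$dU_e, d$dU_i)
    }
  } else {
    function(U, t) {
      d <- spatial_eie_rhs(U[, 1], U[, 2], U[, 3], params,
                           kernel_e1, kernel_e2, kernel_i, stim(t))
      cbind(d$dU_e1, d$dU_e2, d$dU_i)
    }
  }

  n_steps <- round(t_end / dt)
  every <- round(dt_out / dt)
  if (abs(every - dt_out / dt) > 1e-9)
    stop("dt_out must be an integer multiple of dt")
  n_out <- n_steps %/% every
  activity <- lapply(seq_len(npop), function(k)
    matrix(NA_real_, nrow = n_out, ncol = n))
  names(activity) <- pops
  t <- 0
  for (step in seq_len(n_steps)) {
    k1 <- rhs(U, t)
    k2 <- rhs(U + dt / 2 * k1, t + dt / 2)
    k3 <- rhs(U + dt / 2 * k2, t + dt / 2)
    k4 <- rhs(U + dt * k3, t + dt)
    U <- U + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- step * dt
    if (step %% every == 0) {
      i <- step %/% every
      for (k in seq_len(npop)) activity[[k]][i, ] <- U[, k]
    }
  }
  structure(list(times = seq_len(n_out) * dt_out, x = domain$x,
                 activity = activity, model = model, params = params,
                 domain = domain, J = if (is.null(grating)) J else NULL,
                 grating = grating, dt = dt, dt_out = dt_out, seed = seed),
            class = "wc_field")
}

#' @export
print.wc_field <- function(x, ...) {
  stim <- if (is.null(x$grating)) sprintf("uniform J = %g", x$J)
          else sprintf("grating f_x = %g cycles/mm, f_t = %g Hz",
                       x$grating$f_x, x$grating$f_t)
  cat(sprintf("wc_field: spatial '%s' model, %d x %d (time x space), %s\n",
              x$model, length(x$times), length(x$x), stim))
  invisible(x)
}

#' @export
plot.wc_field <- function(x, pop = 1, ...) {
  A <- x$activity[[pop]]
  graphics::image(x$times, x$x, A, xlab = "time (ms)", ylab = "space (mm)",
                  col = grDevices::grey.colors(128, start = 0, end = 1), ...)
  invisible(x)
}
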