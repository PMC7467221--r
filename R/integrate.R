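#' Integrate a point model forward in time
#'
#' Adaptive-step integration with the Bogacki-Shampine 2(3) pair
#' (deSolve's "ode23"), absolute and relative tolerances 1e-6 by default,
#' resampled onto a uniform output grid. The stimulus is either applied at
#' full strength from t = 0 (`onset = "sudden"`) or ramped linearly over
#' `ramp_ms` and then held (`onset = "ramped"`).
#'
#' @param model A `wc_model` from [ei_model()] or [eie_model()].
#' @param state0 Initial state in `[0, 1]^n`.
#' @param t_end End time (ms).
#' @param J Stimulus baseline.
#' @param dt_out Output sampling step (ms).
#' @param atol,rtol Error tolerances of the adaptive stepper.
#' @param onset `"sudden"` or `"ramped"` stimulus onset.
#' @param ramp_ms Ramp duration when `onset = "ramped"`.
#' @return A `wc_trajectory`: list with `times` (ms), `states`
#'   (matrix, one column per state variable), and metadata.
#' @export
#' @examples
#' tr <- wc_integrate(ei_model(), c(0.12, 0.17), t_end = 200, J = 0)
#' range(tr$states[, "U_e"])
wc_integrate <- function(model, state0, t_end, J = 0, dt_out = 0.5,
                         atol = 1e-6, rtol = 1e-6,
                         onset = c("sudden", "ramped"), ramp_ms = 500) {
  onset <- match.arg(onset)
  if (any(state0 < 0) || any(state0 > 1))
    stop("initial state must lie in [0, 1]^n")
  Jt <- if (onset == "sudden") function(t) J
        else function(t) J * min(t / ramp_ms, 1)
  times <- seq(0, t_end, by = dt_out)
  func <- function(t, y, parms) list(model$rhs(y, Jt(t)))
  sol <- deSolve::ode(y = state0, times = times, func = func, parms = NULL,
                      method = "ode23", atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed near t = ", max(sol[, 1]), " ms")
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- model$vars
  structure(list(times = sol[, 1], states = states, model = model$name,
                 J = J, Delta = model$Delta, onset = onset,
                 params = model$params),
            class = "wc_trajectory")
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat(sprintf("wc_trajectory: model '%s', %d samples over %g ms, J = %g\n",
              x$model, length(x$times), max(x$times), x$J))
  invisible(x)
}

#' @export
plot.wc_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "firing rate", ...)
  graphics::legend("topright", colnames(x$states), col = seq_len(ncol(x$states)),
                   lty = 1, bty = "n")
  invisible(x)
}

# indices of strict interior local maxima of a numeric vector
local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1L

# refine a sampled peak location by quadratic interpolation
refine_peak_time <- function(times, x, i) {
  if (i <= 1L || i >= length(x)) return(times[i])
  d <- (x[i - 1] - x[i + 1]) / (2 * (x[i - 1] - 2 * x[i] + x[i + 1]))
  if (!is.finite(d) || abs(d) > 1) d <- 0
  times[i] + d * (times[2] - times[1])
}

#' Oscillation metrics of a trajectory
#'
#' Post-transient amplitude envelope per state variable and the oscillation
#' frequency of the excitatory variable estimated from the mean inter-peak
#' interval (peak times refined by quadratic interpolation). A variable is
#' deemed oscillating when its post-transient peak-to-trough range exceeds
#' `osc_threshold`.
#'
#' @param traj A `wc_trajectory`.
#' @param transient Initial window to discard (ms).
#' @param var Variable used for the frequency estimate (index or name);
#'   defaults to the first (excitatory) variable.
#' @param osc_threshold Minimum range counted as an oscillation.
#' @return A `wc_oscillation` list: `amplitude_min`, `amplitude_max`
#'   (named vectors), `frequency` (Hz, NA when not oscillating),
#'   `is_oscillating`.
#' @export
oscillation_metrics <- function(traj, transient = 500, var = 1,
                                osc_threshold = 0.01) {
  keep <- traj$times >= transient
  if (sum(keep) < 10)
    stop("post-transient window too short for oscillation metrics")
  S <- traj$states[keep, , drop = FALSE]
  tt <- traj$times[keep]
  amin <- apply(S, 2, min); amax <- apply(S, 2, max)
  x <- S[, var]
  osc <- (max(x) - min(x)) > osc_threshold
  freq <- NA_real_
  if (osc) {
    pk <- local_maxima(x)
    # ignore sub-threshold ripples
    pk <- pk[x[pk] > min(x) + 0.5 * (max(x) - min(x))]
    if (length(pk) >= 3) {
      tpk <- vapply(pk, function(i) refine_peak_time(tt, x, i), numeric(1))
      freq <- 1000 / mean(diff(tpk))   # ms -> Hz
    } else {
      warning("fewer than 3 peaks in the post-transient window")
    }
  }
  structure(list(amplitude_min = amin, amplitude_max = amax,
                 frequency = freq, is_oscillating = osc),
            class = "wc_oscillation")
}

#' @export
print.wc_oscillation <- function(x, ...) {
  if (x$is_oscillating)
    cat(sprintf("oscillating at %.2f Hz, envelope [%.3f, %.3f]\n",
                x$frequency, x$amplitude_min[1], x$amplitude_max[1]))
  else cat("not oscillating\n")
  invisible(x)
}

#' Winner of the E-I-E competition
#'
#' Classifies which excitatory population won a trial from its trajectory:
#' the population with the larger post-transient peak-to-trough range wins;
#' when neither population oscillates (both ranges below `osc_threshold`)
#' the post-transient means are compared instead. Outcomes closer than
#' `margin` (relative) are reported as `"undecided"` rather than silently
#' assigned.
#'
#' @param traj A `wc_trajectory` of an E-I-E model.
#' @param transient Initial window to discard (ms).
#' @param margin Relative margin below which the trial is undecided.
#' @param osc_threshold Range below which a variable counts as flat.
#' @return `"e1"`, `"e2"` or `"undecided"`.
#' @export
winner <- function(traj, transient = 500, margin = 0.1,
                   osc_threshold = 0.01) {
  if (ncol(traj$states) != 3)
    stop("winner() expects an E-I-E trajectory with 3 state variables")
  keep <- traj$times >= transient
  S <- traj$states[keep, , drop = FALSE]
  r1 <- max(S[, 1]) - min(S[, 1])
  r2 <- max(S[, 2]) - min(S[, 2])
  if (r1 < osc_threshold && r2 < osc_threshold) {
    r1 <- mean(S[, 1]); r2 <- mean(S[, 2])
  }
  if (r1 > (1 + margin) * r2) "e1"
  else if (r2 > (1 + margin) * r1) "e2"
  else "undecided"
}

# Classic fixed-step RK4 on a matrix of states, vectorized across rows
# (one row per trial). f(Y, t) returns dY/dt. Returns post-transient
# running min/max per column group via the supplied recorder.
rk4_ensemble <- function(Y, f, t_end, dt, record_from, recorder) {
  n_steps <- round(t_end / dt)
  t <- 0
  for (k in seq_len(n_steps)) {
    k1 <- f(Y, t)
    k2 <- f(Y + dt / 2 * k1, t + dt / 2)
    k3 <- f(Y + dt / 2 * k2, t + dt / 2)
    k4 <- f(Y + dt * k3, t + dt)
    Y <- Y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- k * dt
    if (t > record_from) recorder(Y)
  }
  Y
}

#' Seeded trial ensemble of the E-I-E competition
#'
#' Integrates `n_trials` independent trials of the point E-I-E model from
#' uniform random initial conditions on `[0, 1]^3` and tallies the winners.
#' All trials share one seeded random stream (the full initial-condition
#' block is drawn at once), so results are bit-identical for identical
#' `(seed, n_trials)`. Trials are integrated jointly with a vectorized
#' fixed-step fourth-order Runge-Kutta scheme; the winner of each trial is
#' the population with the larger post-transient peak-to-trough range (see
#' [winner()] for the margin convention).
#'
#' @param params A [wc_params()] object.
#' @param J Baseline stimulus amplitude.
#' @param Delta Stimulus bias (`J_e1 = J + Delta`, `J_e2 = J - Delta`).
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param onset `"sudden"` (full stimulus from t = 0) or `"ramped"`
#'   (linear ramp over `ramp_ms`, then hold).
#' @param t_end Trial duration (ms).
#' @param transient Window discarded before scoring (ms).
#' @param dt Fixed integration step (ms).
#' @param ramp_ms Ramp duration for `onset = "ramped"`.
#' @param margin Relative undecided margin.
#' @return A `wc_trials` list: counts `n_e1`, `n_e2`, `n_undecided`,
#'   `fraction_e1` (percent), `ci_99` (99% normal-approximation binomial
#'   half-width, percent), and the run configuration.
#' @export
#' @examples
#' run_trials(wc_params(), J = 2, Delta = 0.2, n_trials = 20, seed = 1)
run_trials <- function(params, J = 2, Delta = 0, n_trials = 1000, seed = 1,
                       onset = c("sudden", "ramped"), t_end = 1000,
                       transient = 500, dt = 0.1, ramp_ms = 500,
                       margin = 0.1) {
  params <- as_wc_params(params)
  onset <- match.arg(onset)
  stopifnot(n_trials >= 1)
  set.seed(seed)
  Y <- matrix(stats::runif(3 * n_trials), nrow = n_trials, ncol = 3)
  p <- params
  ramp <- if (onset == "ramped") function(t) min(t / ramp_ms, 1)
          else function(t) 1
  f <- function(Y, t) {
    r <- ramp(t)
    a1 <- p$w_ee * Y[, 1] - p$w_ei * Y[, 3] - p$b_e + (J + Delta) * r
    a2 <- p$w_ee * Y[, 2] - p$w_ei * Y[, 3] - p$b_e + (J - Delta) * r
    ai <- p$w_ie * Y[, 1] + p$w_ie * Y[, 2] - p$w_ii * Y[, 3] - p$b_i
    cbind((-Y[, 1] + firing_rate(a1)) / p$tau_e,
          (-Y[, 2] + firing_rate(a2)) / p$tau_e,
          (-Y[, 3] + firing_rate(ai)) / p$tau_i)
  }
  env <- new.env()
  env$mn1 <- rep(Inf, n_trials); env$mx1 <- rep(-Inf, n_trials)
  env$mn2 <- rep(Inf, n_trials); env$mx2 <- rep(-Inf, n_trials)
  recorder <- function(Y) {
    env$mn1 <- pmin(env$mn1, Y[, 1]); env$mx1 <- pmax(env$mx1, Y[, 1])
    env$mn2 <- pmin(env$mn2, Y[, 2]); env$mx2 <- pmax(env$mx2, Y[, 2])
  }
  rk4_ensemble(Y, f, t_end, dt, transient, recorder)
  r1 <- env$mx1 - env$mn1
  r2 <- env$mx2 - env$mn2
  w1 <- r1 > (1 + margin) * r2
  w2 <- r2 > (1 + margin) * r1
  n_e1 <- sum(w1); n_e2 <- sum(w2)
  n_und <- n_trials - n_e1 - n_e2
  frac <- 100 * n_e1 / n_trials
  phat <- n_e1 / n_trials
  ci <- 100 * 2.576 * sqrt(phat * (1 - phat) / n_trials)
  structure(list(n_trials = n_trials, n_e1 = n_e1, n_e2 = n_e2,
                 n_undecided = n_und, fraction_e1 = frac, ci_99 = ci,
                 J = J, Delta = Delta, onset = onset, seed = seed,
                 t_end = t_end, transient = transient, dt = dt),
            class = "wc_trials")
}

#' @export
print.wc_trials <- function(x, ...) {
  cat(sprintf(
    "E-I-E trial ensemble: n = %d, J = %g, Delta = %g, onset %s, seed %d\n",
    x$n_trials, x$J, x$Delta, x$onset, x$seed))
  cat(sprintf("  e1 wins: %d (%.2f%% +/- %.2f%%, 99%% CI)\n",
              x$n_e1, x$fraction_e1, x$ci_99))
  cat(sprintf("  e2 wins: %d (%.2f%%)   undecided: %d\n",
              x$n_e2, 100 * x$n_e2 / x$n_trials, x$n_undecided))
  invisible(x)
}

#' @export
as.data.frame.wc_trials <- function(x, ...) {
  data.frame(n_trials = x$n_trials, n_e1 = x$n_e1, n_e2 = x$n_e2,
             n_undecided = x$n_undecided, fraction_e1 = x$fraction_e1,
             ci_99 = x$ci_99, J = x$J, Delta = x$Delta, onset = x$onset,
             seed = x$seed)
}
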