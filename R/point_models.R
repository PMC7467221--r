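#' Sigmoidal firing-rate function
#'
#' The logistic response `F(v) = 1 / (1 + exp(-v))` mapping net synaptic
#' input to a normalized firing rate in (0, 1). The exponent is clamped to
#' +/-500 so extreme inputs saturate instead of overflowing.
#'
#' @param v Net input (dimensionless), any numeric vector.
#' @return Firing rate(s) in (0, 1).
#' @export
#' @examples
#' firing_rate(0)        # 0.5
#' firing_rate(log(3))   # 0.75
firing_rate <- function(v) {
  v <- pmin(pmax(v, -500), 500)
  1 / (1 + exp(-v))
}

#' Derivative of the sigmoidal firing-rate function
#'
#' Uses the identity `F'(v) = F(v) (1 - F(v))`, bounded above by 1/4.
#'
#' @param v Net input (dimensionless).
#' @return `F'(v)`.
#' @export
firing_rate_deriv <- function(v) {
  f <- firing_rate(v)
  f * (1 - f)
}

#' Vector field of the point E-I model
#'
#' Time derivatives of the two-population Wilson-Cowan model:
#' \deqn{\tau_e \dot U_e = -U_e + F(w_{ee} U_e - w_{ei} U_i - b_e + J)}
#' \deqn{\tau_i \dot U_i = -U_i + F(w_{ie} U_e - w_{ii} U_i - b_i)}
#' The stimulus J drives the excitatory population only.
#'
#' @param state Numeric vector `c(U_e, U_i)`.
#' @param params A [wc_params()] object.
#' @param J Stimulus amplitude (dimensionless scalar).
#' @return Numeric vector of derivatives (1/ms).
#' @export
ei_rhs <- function(state, params, J = 0) {
  u <- state
  c((-u[1] + firing_rate(params$w_ee * u[1] - params$w_ei * u[2] -
                           params$b_e + J)) / params$tau_e,
    (-u[2] + firing_rate(params$w_ie * u[1] - params$w_ii * u[2] -
                           params$b_i)) / params$tau_i)
}

#' Vector field of the point E-I-E opponency model
#'
#' Two excitatory populations e1 and e2 with no direct coupling compete
#' through a shared inhibitory pool:
#' \deqn{\tau_e \dot U_{e1} = -U_{e1} + F(w_{ee} U_{e1} - w_{ei} U_i - b_e + J + \Delta)}
#' \deqn{\tau_i \dot U_i = -U_i + F(w_{ie} U_{e1} + w_{ie} U_{e2} - w_{ii} U_i - b_i)}
#' \deqn{\tau_e \dot U_{e2} = -U_{e2} + F(w_{ee} U_{e2} - w_{ei} U_i - b_e + J - \Delta)}
#' The differential stimulus is `J_e1 = J + Delta`, `J_e2 = J - Delta`;
#' `Delta = 0` is the ambiguous case, for which the system is exactly
#' equivariant under the e1/e2 exchange.
#'
#' @param state Numeric vector `c(U_e1, U_e2, U_i)`.
#' @param params A [wc_params()] object.
#' @param J Baseline stimulus amplitude.
#' @param Delta Stimulus bias (any sign).
#' @return Numeric vector of derivatives (1/ms), same ordering as `state`.
#' @export
eie_rhs <- function(state, params, J = 0, Delta = 0) {
  u <- state
  c((-u[1] + firing_rate(params$w_ee * u[1] - params$w_ei * u[3] -
                           params$b_e + J + Delta)) / params$tau_e,
    (-u[2] + firing_rate(params$w_ee * u[2] - params$w_ei * u[3] -
                           params$b_e + J - Delta)) / params$tau_e,
    (-u[3] + firing_rate(params$w_ie * u[1] + params$w_ie * u[2] -
                           params$w_ii * u[3] - params$b_i)) / params$tau_i)
}

#' Analytic Jacobian of the point E-I model
#'
#' @inheritParams ei_rhs
#' @return A 2x2 matrix of partial derivatives (1/ms).
#' @export
ei_jacobian <- function(state, params, J = 0) {
  u <- state
  fe <- firing_rate_deriv(params$w_ee * u[1] - params$w_ei * u[2] -
                            params$b_e + J)
  fi <- firing_rate_deriv(params$w_ie * u[1] - params$w_ii * u[2] -
                            params$b_i)
  matrix(c((-1 + params$w_ee * fe) / params$tau_e,
           -params$w_ei * fe / params$tau_e,
           params$w_ie * fi / params$tau_i,
           (-1 - params$w_ii * fi) / params$tau_i),
         nrow = 2, byrow = TRUE)
}

#' Analytic Jacobian of the point E-I-E model
#'
#' @inheritParams eie_rhs
#' @return A 3x3 matrix of partial derivatives (1/ms), state ordering
#'   `(U_e1, U_e2, U_i)`.
#' @export
eie_jacobian <- function(state, params, J = 0, Delta = 0) {
  u <- state
  f1 <- firing_rate_deriv(params$w_ee * u[1] - params$w_ei * u[3] -
                            params$b_e + J + Delta)
  f2 <- firing_rate_deriv(params$w_ee * u[2] - params$w_ei * u[3] -
                            params$b_e + J - Delta)
  fi <- firing_rate_deriv(params$w_ie * u[1] + params$w_ie * u[2] -
                            params$w_ii * u[3] - params$b_i)
  te <- params$tau_e; ti <- params$tau_i
  matrix(c((-1 + params$w_ee * f1) / te, 0, -params$w_ei * f1 / te,
           0, (-1 + params$w_ee * f2) / te, -params$w_ei * f2 / te,
           params$w_ie * fi / ti, params$w_ie * fi / ti,
           (-1 - params$w_ii * fi) / ti),
         nrow = 3, byrow = TRUE)
}

#' Point-model objects
#'
#' Bundle a vector field, its analytic Jacobian and bookkeeping into a
#' `wc_model` object consumed by the integrator and the continuation code.
#' The stimulus baseline J is left free (it is the continuation parameter);
#' the E-I-E bias Delta is fixed inside the model object.
#'
#' @param params A [wc_params()] object.
#' @param Delta Stimulus bias of the E-I-E model.
#' @return A `wc_model` list with elements `name`, `n`, `vars`,
#'   `rhs(u, J)`, `jac(u, J)`, `params`, and for the E-I-E model `Delta`
#'   and `symmetric` (TRUE when `Delta == 0`).
#' @export
#' @examples
#' m <- ei_model(wc_params())
#' m$rhs(c(0.12, 0.17), J = 0)
ei_model <- function(params = wc_params()) {
  params <- as_wc_params(params)
  structure(list(
    name = "ei", n = 2L, vars = c("U_e", "U_i"),
    rhs = function(u, J) ei_rhs(u, params, J),
    jac = function(u, J) ei_jacobian(u, params, J),
    jac_J = function(u, J) {
      fe <- firing_rate_deriv(params$w_ee * u[1] - params$w_ei * u[2] -
                                params$b_e + J)
      c(fe / params$tau_e, 0)
    },
    params = params, symmetric = FALSE
  ), class = "wc_model")
}

#' @rdname ei_model
#' @export
eie_model <- function(params = wc_params(), Delta = 0) {
  params <- as_wc_params(params)
  structure(list(
    name = "eie", n = 3L, vars = c("U_e1", "U_e2", "U_i"),
    rhs = function(u, J) eie_rhs(u, params, J, Delta),
    jac = function(u, J) eie_jacobian(u, params, J, Delta),
    jac_J = function(u, J) {
      f1 <- firing_rate_deriv(params$w_ee * u[1] - params$w_ei * u[3] -
                                params$b_e + J + Delta)
      f2 <- firing_rate_deriv(params$w_ee * u[2] - params$w_ei * u[3] -
                                params$b_e + J - Delta)
      c(f1 / params$tau_e, f2 / params$tau_e, 0)
    },
    params = params, Delta = Delta, symmetric = (Delta == 0)
  ), class = "wc_model")
}

#' @export
print.wc_model <- function(x, ...) {
  cat(sprintf("Wilson-Cowan point model '%s' (%d states: %s)\n",
              x$name, x$n, paste(x$vars, collapse = ", ")))
  if (!is.null(x$Delta)) cat(sprintf("  stimulus bias Delta = %g\n", x$Delta))
  invisible(x)
}

#' Solve for an equilibrium of a point model
#'
#' Damped Newton iteration with the analytic Jacobian. A step is halved
#' (up to 40 times) whenever it fails to reduce the residual norm, which
#' keeps the iteration inside the unit hypercube basin in practice.
#'
#' @param model A `wc_model` from [ei_model()] or [eie_model()].
#' @param J Stimulus baseline at which to solve.
#' @param guess Initial state, inside `[0, 1]^n`.
#' @param tol Convergence tolerance on the residual max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A list with `state`, `residual`, `converged`, `iterations`.
#'   Non-convergence is reported, not silently accepted.
#' @export
#' @examples
#' fp <- find_fixed_point(ei_model(), J = 0, guess = c(0.1, 0.1))
#' round(fp$state, 2)   # c(0.12, 0.17)
find_fixed_point <- function(model, J = 0, guess = NULL,
                             tol = 1e-10, max_iter = 100) {
  u <- if (is.null(guess)) rep(0.25, model$n) else guess
  if (length(u) != model$n) stop("guess has wrong length")
  r <- model$rhs(u, J)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol)
      return(list(state = u, residual = max(abs(r)),
                  converged = TRUE, iterations = it - 1L))
    du <- tryCatch(solve(model$jac(u, J), r),
                   error = function(e) r)   # singular: fall back to residual
    s <- 1
    repeat {
      u_new <- u - s * du
      r_new <- model$rhs(u_new, J)
      if (max(abs(r_new)) < max(abs(r)) || s < 2^-40) break
      s <- s / 2
    }
    u <- u_new; r <- r_new
  }
  list(state = u, residual = max(abs(r)), converged = max(abs(r)) < tol,
       iterations = max_iter)
}

#' Locate all equilibria reachable from a grid of initial guesses
#'
#' Runs [find_fixed_point()] from a lattice of starting points in the unit
#' hypercube and deduplicates converged solutions. Used to enumerate the
#' coexisting equilibria of the E-I-E model past the pitchfork.
#'
#' @param model A `wc_model`.
#' @param J Stimulus baseline.
#' @param n_grid Number of lattice points per state dimension.
#' @param tol Residual tolerance passed to the Newton solver.
#' @return A matrix with one equilibrium per row (columns = state vars).
#' @export
find_equilibria <- function(model, J = 0, n_grid = 5, tol = 1e-10) {
  grid <- seq(0.05, 0.95, length.out = n_grid)
  pts <- as.matrix(expand.grid(rep(list(grid), model$n)))
  found <- matrix(numeric(0), ncol = model$n)
  for (i in seq_len(nrow(pts))) {
    fp <- find_fixed_point(model, J, pts[i, ], tol = tol)
    if (!fp$converged) next
    u <- fp$state
    if (any(u < -1e-6) || any(u > 1 + 1e-6)) next
    if (nrow(found) == 0 ||
        min(apply(found, 1, function(v) max(abs(v - u)))) > 1e-6)
      found <- rbind(found, u)
  }
  rownames(found) <- NULL
  colnames(found) <- model$vars
  found
}
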