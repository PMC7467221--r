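# Independent oracles used across the suite. These deliberately re-derive
# quantities through a different code path than the implementation under
# test (direct transcription of the model equations, O(n^2) summation,
# finite differences, closed forms).

table1 <- wc_params()

# second hand-written, symbol-by-symbol transcription of the E-I equations
oracle_ei_rhs <- function(u, p, J) {
  sig <- function(v) 1 / (1 + exp(-v))
  c((-u[1] + sig(p$w_ee * u[1] - p$w_ei * u[2] - p$b_e + J)) / p$tau_e,
    (-u[2] + sig(p$w_ie * u[1] - p$w_ii * u[2] - p$b_i)) / p$tau_i)
}

oracle_eie_rhs <- function(u, p, J, Delta) {
  sig <- function(v) 1 / (1 + exp(-v))
  c((-u[1] + sig(p$w_ee * u[1] - p$w_ei * u[3] - p$b_e + (J + Delta))) / p$tau_e,
    (-u[2] + sig(p$w_ee * u[2] - p$w_ei * u[3] - p$b_e + (J - Delta))) / p$tau_e,
    (-u[3] + sig(p$w_ie * u[1] + p$w_ie * u[2] - p$w_ii * u[3] - p$b_i)) / p$tau_i)
}

# central finite-difference Jacobian
fd_jacobian <- function(f, u, h = 1e-6) {
  n <- length(u)
  J <- matrix(0, length(f(u)), n)
  for (j in seq_len(n)) {
    up <- u; um <- u
    up[j] <- u[j] + h; um[j] <- u[j] - h
    J[, j] <- (f(up) - f(um)) / (2 * h)
  }
  J
}

# O(n^2) circular convolution, V_m = sum_j w[(m-j) mod n] u[j] dx
direct_convolve <- function(u, w, dx) {
  n <- length(u)
  vapply(seq_len(n), function(m) {
    idx <- ((m - seq_len(n)) %% n) + 1L
    sum(w[idx] * u) * dx
  }, numeric(1))
}

# reflect a periodic field about x = 0 (grid point 1 stays fixed)
mirror_field <- function(v) v[c(1L, length(v):2L)]

# assemble a synthetic wc_trajectory
make_traj <- function(times, states, vars = paste0("V", seq_len(ncol(states)))) {
  colnames(states) <- vars
  structure(list(times = times, states = states, model = "synthetic",
                 J = NA, Delta = NULL, onset = "sudden", params = table1),
            class = "wc_trajectory")
}

# assemble a synthetic wc_field from a list of time-by-space matrices
make_field <- function(activity, dt_out = 1, dx = 0.01) {
  nt <- nrow(activity[[1]]); nx <- ncol(activity[[1]])
  structure(list(times = seq_len(nt) * dt_out, x = (0:(nx - 1)) * dx,
                 activity = activity, model = "synthetic", params = table1,
                 domain = wc_domain(nx * dx, dx), J = NULL, grating = NULL,
                 dt = dt_out, dt_out = dt_out, seed = 0),
            class = "wc_field")
}

# in-test fixed-step RK4 for a point model (homogeneous-reduction oracle)
rk4_point <- function(rhs, u0, t_end, dt) {
  n_steps <- round(t_end / dt)
  out <- matrix(NA_real_, n_steps, length(u0))
  u <- u0
  for (k in seq_len(n_steps)) {
    k1 <- rhs(u); k2 <- rhs(u + dt / 2 * k1)
    k3 <- rhs(u + dt / 2 * k2); k4 <- rhs(u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k, ] <- u
  }
  out
}
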