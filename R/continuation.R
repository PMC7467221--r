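# Equilibrium continuation in the stimulus parameter J.
#
# Pseudo-arclength predictor-corrector: secant predictor, Newton corrector
# on the bordered system [rhs(u, J); tangent . (z - z_pred)] = 0 in the
# extended variable z = (u, J), so folds in J are traversed. Eigenvalues of
# the analytic state Jacobian are recorded at every accepted point and
# tracked by minimal-distance matching between consecutive steps.

# greedy minimal-distance matching of eigenvalue sets (n <= 3 here)
match_eigs <- function(prev, cur) {
  n <- length(cur)
  out <- complex(n)
  used <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(cur - prev[i])
    d[used] <- Inf
    j <- which.min(d)
    out[i] <- cur[j]
    used[j] <- TRUE
  }
  out
}

# one bordered-Newton correction toward the branch
correct_point <- function(model, z_pred, tangent, tol = 1e-10, max_iter = 12) {
  n <- model$n
  z <- z_pred
  for (it in seq_len(max_iter)) {
    u <- z[1:n]; J <- z[n + 1]
    r <- c(model$rhs(u, J), sum(tangent * (z - z_pred)))
    if (max(abs(r)) < tol) return(list(z = z, ok = TRUE))
    A <- rbind(cbind(model$jac(u, J), model$jac_J(u, J)), tangent)
    dz <- tryCatch(solve(A, r), error = function(e) NULL)
    if (is.null(dz)) return(list(z = z, ok = FALSE))
    z <- z - dz
  }
  list(z = z, ok = max(abs(c(model$rhs(z[1:n], z[n + 1])))) < tol)
}

#' Trace an equilibrium branch of a point model
#'
#' Continues an equilibrium from `J_start` toward `J_end` by
#' pseudo-arclength continuation (secant predictor, bordered Newton
#' corrector), so limit points where the branch folds back in J are
#' traversed rather than terminal. The step is halved on corrector failure
#' and grown again after successes; every accepted state satisfies
#' `max|rhs| < tol`.
#'
#' @param model A `wc_model`.
#' @param J_start,J_end Continuation range. `J_end` may be on the far side
#'   of a fold; continuation stops when J leaves `[min, max]` of the range
#'   or `max_points` is reached.
#' @param u0 Starting equilibrium guess at `J_start` (Newton-refined).
#' @param max_step Maximum arclength step (also the natural J resolution).
#' @param min_step Step underflow bound; reaching it terminates the branch
#'   with a warning.
#' @param max_points Cap on accepted points.
#' @param tol Equilibrium residual tolerance.
#' @return A `wc_branch`: `J` (vector), `states` (matrix), `eig` (complex
#'   matrix, continuity-ordered), `stable` (logical), plus metadata.
#' @export
#' @examples
#' br <- continue_equilibria(ei_model(), 0, 1, u0 = c(0.1, 0.1))
#' detect_hopf(br, ei_model())
continue_equilibria <- function(model, J_start, J_end, u0 = NULL,
                                max_step = 0.1, min_step = 1e-8,
                                max_points = 2000, tol = 1e-10) {
  n <- model$n
  fp <- find_fixed_point(model, J_start, u0, tol = tol)
  if (!fp$converged)
    stop("initial equilibrium did not converge (residual ",
         signif(fp$residual, 3), ")")
  dir <- sign(J_end - J_start)
  if (dir == 0) stop("J_start and J_end coincide")
  Jlo <- min(J_start, J_end) - 1e-12
  Jhi <- max(J_start, J_end) + 1e-12

  zs <- matrix(NA_real_, nrow = max_points, ncol = n + 1)
  zs[1, ] <- c(fp$state, J_start)
  # second point by natural continuation
  h0 <- max_step / 10
  fp2 <- find_fixed_point(model, J_start + dir * h0, fp$state, tol = tol)
  if (!fp2$converged) stop("second continuation point did not converge")
  zs[2, ] <- c(fp2$state, J_start + dir * h0)

  npts <- 2L
  h <- max_step / 2
  while (npts < max_points) {
    tangent <- zs[npts, ] - zs[npts - 1, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    ok <- FALSE
    while (h >= min_step) {
      z_pred <- zs[npts, ] + h * tangent
      res <- correct_point(model, z_pred, tangent, tol = tol)
      # reject corrections that wander further than the step itself:
      # those are jumps onto a different branch near a singular point
      if (res$ok && sqrt(sum((res$z - z_pred)^2)) <= h) { ok <- TRUE; break }
      h <- h / 2
    }
    if (!ok) {
      warning("continuation step underflow at J = ", zs[npts, n + 1],
              "; branch terminated")
      break
    }
    npts <- npts + 1L
    zs[npts, ] <- res$z
    h <- min(h * 1.3, max_step)
    Jcur <- res$z[n + 1]
    if (Jcur < Jlo || Jcur > Jhi) break
  }
  zs <- zs[seq_len(npts), , drop = FALSE]
  # clamp the final point exactly onto the range boundary it just crossed
  # (a small overshoot, not a fold excursion)
  Jlast <- zs[npts, n + 1]
  J_exit <- if (Jlast > Jhi) max(J_start, J_end) else
            if (Jlast < Jlo) min(J_start, J_end) else NA
  if (!is.na(J_exit) && abs(Jlast - J_exit) <= max_step) {
    fpe <- find_fixed_point(model, J_exit, zs[npts, 1:n], tol = tol)
    if (fpe$converged) zs[npts, ] <- c(fpe$state, J_exit)
  }

  eig <- matrix(NA_complex_, nrow = npts, ncol = n)
  for (i in seq_len(npts)) {
    ev <- eigen(model$jac(zs[i, 1:n], zs[i, n + 1]), only.values = TRUE)$values
    ev <- as.complex(ev)
    eig[i, ] <- if (i == 1) ev[order(Re(ev), decreasing = TRUE)]
                else match_eigs(eig[i - 1, ], ev)
  }
  states <- zs[, 1:n, drop = FALSE]
  colnames(states) <- model$vars
  structure(list(J = zs[, n + 1], states = states, eig = eig,
                 stable = apply(eig, 1, function(e) all(Re(e) < 0)),
                 model = model$name, Delta = model$Delta,
                 max_step = max_step, tol = tol),
            class = "wc_branch")
}

#' @export
print.wc_branch <- function(x, ...) {
  cat(sprintf(
    "wc_branch: model '%s', %d points, J in [%.4g, %.4g], %d stable\n",
    x$model, length(x$J), min(x$J), max(x$J), sum(x$stable)))
  invisible(x)
}

#' @export
plot.wc_branch <- function(x, var = 1, ...) {
  graphics::plot(x$J, x$states[, var], type = "n", xlab = "J",
                 ylab = colnames(x$states)[var], ...)
  st <- x$stable
  graphics::lines(x$J[st], x$states[st, var], lwd = 2)
  graphics::lines(x$J[!st], x$states[!st, var], lty = 2)
  invisible(x)
}

# equilibrium at a given J seeded from a nearby state (plain Newton)
eq_at <- function(model, J, seed, tol = 1e-12) {
  fp <- find_fixed_point(model, J, seed, tol = tol)
  if (!fp$converged) stop("equilibrium refinement failed at J = ", J)
  fp$state
}

# Hopf test function: largest real part among the complex eigenvalues
hopf_test <- function(model, u, J, imag_tol = 1e-9) {
  ev <- eigen(model$jac(u, J), only.values = TRUE)$values
  ev <- as.complex(ev)
  cx <- ev[abs(Im(ev)) > imag_tol]
  if (!length(cx)) return(NA_real_)
  max(Re(cx))
}

# real-eigenvalue test function: the real eigenvalue nearest zero
real_test <- function(model, u, J, imag_tol = 1e-9) {
  ev <- eigen(model$jac(u, J), only.values = TRUE)$values
  ev <- as.complex(ev)
  re <- Re(ev[abs(Im(ev)) <= imag_tol])
  if (!length(re)) return(NA_real_)
  re[which.min(abs(re))]
}

# bisect a test-function sign change in J along a branch segment,
# tracking the equilibrium by reseeded Newton solves
bisect_on_branch <- function(model, test, J_a, u_a, J_b, u_b,
                             tol = 1e-8, max_iter = 100) {
  f_a <- test(model, u_a, J_a)
  f_b <- test(model, u_b, J_b)
  if (!is.finite(f_a) || !is.finite(f_b) || sign(f_a) == sign(f_b))
    return(NULL)
  for (i in seq_len(max_iter)) {
    J_m <- (J_a + J_b) / 2
    u_m <- eq_at(model, J_m, (u_a + u_b) / 2)
    f_m <- test(model, u_m, J_m)
    if (!is.finite(f_m)) return(NULL)
    if (abs(f_m) < tol || (J_b - J_a) < 1e-13)
      return(list(J = J_m, state = u_m, residual = f_m))
    if (sign(f_m) == sign(f_a)) { J_a <- J_m; u_a <- u_m; f_a <- f_m }
    else { J_b <- J_m; u_b <- u_m; f_b <- f_m }
  }
  list(J = (J_a + J_b) / 2, state = u_m, residual = f_m)
}

#' Detect Hopf bifurcations along a branch
#'
#' Brackets sign changes of the real part of the leading complex-conjugate
#' eigenvalue pair between consecutive branch points and bisects each to
#' `|Re(lambda)| < tol`. Real-eigenvalue crossings are excluded (those are
#' limit or branch points).
#'
#' @param branch A `wc_branch`.
#' @param model The `wc_model` the branch was computed from.
#' @param tol Bisection tolerance on `Re(lambda)` (1/ms).
#' @return A data frame of special points (`kind = "H"`): columns `kind`,
#'   `J`, one column per state variable, `omega` (|Im lambda|, 1/ms) and
#'   `freq_hz`. Zero rows when no Hopf is present.
#' @export
detect_hopf <- function(branch, model, tol = 1e-8) {
  npts <- length(branch$J)
  tf <- vapply(seq_len(npts), function(i)
    hopf_test(model, branch$states[i, ], branch$J[i]), numeric(1))
  out <- list()
  for (i in seq_len(npts - 1)) {
    if (!is.finite(tf[i]) || !is.finite(tf[i + 1])) next
    if (sign(tf[i]) == sign(tf[i + 1])) next
    # genuine parameter crossing only (skip fold turnarounds)
    if (branch$J[i] == branch$J[i + 1]) next
    ord <- order(c(branch$J[i], branch$J[i + 1]))
    Js <- c(branch$J[i], branch$J[i + 1])[ord]
    us <- list(branch$states[i, ], branch$states[i + 1, ])[ord]
    hit <- bisect_on_branch(model, hopf_test, Js[1], us[[1]], Js[2], us[[2]],
                            tol = tol)
    if (is.null(hit)) next
    ev <- eigen(model$jac(hit$state, hit$J), only.values = TRUE)$values
    ev <- as.complex(ev)
    omega <- max(abs(Im(ev)))
    out[[length(out) + 1]] <-
      c(J = hit$J, stats::setNames(hit$state, model$vars),
        omega = omega, freq_hz = omega / (2 * pi) * 1000)
  }
  if (!length(out))
    return(data.frame(kind = character(0), J = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  dedupe_points(cbind(kind = "H", df))
}

# drop repeated detections of the same point (same kind, J within 1e-5)
dedupe_points <- function(df) {
  if (nrow(df) < 2) return(df)
  keep <- rep(TRUE, nrow(df))
  for (i in 2:nrow(df))
    for (j in seq_len(i - 1))
      if (keep[j] && df$kind[i] == df$kind[j] &&
          abs(df$J[i] - df$J[j]) < 1e-5) keep[i] <- FALSE
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Newton on the extended fold system [rhs(u, J); det(jac(u, J))] = 0
refine_fold <- function(model, u, J, tol = 1e-10, max_iter = 60) {
  n <- model$n
  G <- function(z) c(model$rhs(z[1:n], z[n + 1]),
                     det(model$jac(z[1:n], z[n + 1])))
  z <- c(u, J)
  for (it in seq_len(max_iter)) {
    g <- G(z)
    if (max(abs(g)) < tol) break
    A <- matrix(0, n + 1, n + 1)
    for (j in seq_len(n + 1)) {        # central finite differences
      hj <- 1e-7 * max(1, abs(z[j]))
      zp <- z; zm <- z
      zp[j] <- z[j] + hj; zm[j] <- z[j] - hj
      A[, j] <- (G(zp) - G(zm)) / (2 * hj)
    }
    dz <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    z <- z - dz
  }
  if (max(abs(G(z))) > 1e-8) return(NULL)
  list(J = z[n + 1], state = z[1:n])
}

#' Detect limit points and branch points along a branch
#'
#' Scans the branch for zero crossings of a real eigenvalue. A crossing at
#' which the branch folds back in J (the sign of consecutive J increments
#' flips) is classified as a limit point (LP) and refined by Newton on the
#' extended fold system `[rhs; det(jacobian)] = 0`; a crossing that the
#' branch passes through with J monotone is a branch point (BP, the
#' pitchfork of the exchange-symmetric E-I-E model) and is refined by
#' bisection along the branch. For a biased E-I-E model (`Delta != 0`) the
#' pitchfork is destroyed ("imperfect" bifurcation) and no BP is reported.
#'
#' @param branch A `wc_branch`.
#' @param model The `wc_model` the branch was computed from.
#' @param tol Refinement tolerance.
#' @return A data frame with columns `kind` ("LP"/"BP"), `J` and the state
#'   variables. Zero rows when no such point lies on the branch.
#' @export
detect_special_points <- function(branch, model, tol = 1e-8) {
  npts <- length(branch$J)
  tf <- vapply(seq_len(npts), function(i)
    real_test(model, branch$states[i, ], branch$J[i]), numeric(1))
  dJ <- diff(branch$J)
  out <- list()
  for (i in seq_len(npts - 1)) {
    if (!is.finite(tf[i]) || !is.finite(tf[i + 1])) next
    if (sign(tf[i]) == sign(tf[i + 1])) next
    fold <- FALSE
    for (k in max(1, i - 2):min(npts - 2, i + 1))
      if (dJ[k] * dJ[k + 1] < 0) fold <- TRUE
    if (fold) {
      hit <- refine_fold(model, branch$states[i, ], branch$J[i], tol = tol)
      if (is.null(hit)) next
      out[[length(out) + 1]] <-
        c(kind = "LP", J = hit$J, stats::setNames(hit$state, model$vars))
    } else {
      ord <- order(c(branch$J[i], branch$J[i + 1]))
      Js <- c(branch$J[i], branch$J[i + 1])[ord]
      us <- list(branch$states[i, ], branch$states[i + 1, ])[ord]
      hit <- bisect_on_branch(model, real_test, Js[1], us[[1]],
                              Js[2], us[[2]], tol = tol)
      if (is.null(hit)) next
      out[[length(out) + 1]] <-
        c(kind = "BP", J = hit$J, stats::setNames(hit$state, model$vars))
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), J = numeric(0)))
  df <- do.call(rbind, lapply(out, function(r)
    data.frame(kind = r[["kind"]], t(vapply(r[-1], as.numeric, numeric(1))))))
  rownames(df) <- NULL
  dedupe_points(df)
}

#' Switch to the bifurcating branch at a pitchfork
#'
#' Perturbs the branch-point state along the null eigenvector of the
#' Jacobian and Newton-solves at a slightly larger J, landing on one of the
#' two asymmetric branches emanating from the pitchfork; the sign of
#' `direction` selects the mirror branch. The new branch is then continued
#' over `J_range`.
#'
#' @param model A `wc_model` (exchange-symmetric E-I-E).
#' @param bp One row of the [detect_special_points()] output with
#'   `kind == "BP"` (or a list with `J` and the state variables).
#' @param J_range Range over which to continue the bifurcating branch.
#' @param direction +1 or -1, selecting the branch.
#' @param dJ Offset from the branch point at which to land.
#' @param eps Perturbation amplitudes along the null eigenvector, tried in
#'   order until the Newton solve lands off the symmetric branch (near a
#'   pitchfork the bifurcating equilibria sit at distance ~ sqrt(dJ), so a
#'   range of scales is attempted).
#' @param ... Passed to [continue_equilibria()].
#' @return A `wc_branch` along the asymmetric branch.
#' @export
branch_switch <- function(model, bp, J_range = NULL, direction = 1,
                          dJ = 0.02, eps = c(0.01, 0.03, 0.1, 0.2), ...) {
  u_bp <- as.numeric(bp[model$vars])
  J_bp <- as.numeric(bp["J"])
  A <- model$jac(u_bp, J_bp)
  ev <- eigen(A)
  k <- which.min(abs(Re(ev$values)))
  nullvec <- Re(ev$vectors[, k])
  nullvec <- nullvec / sqrt(sum(nullvec^2))
  u_sym <- eq_at(model, J_bp + dJ, u_bp)
  fp <- NULL
  for (e in eps) {
    guess <- pmin(pmax(u_bp + direction * e * nullvec, 0), 1)
    cand <- find_fixed_point(model, J_bp + dJ, guess)
    if (cand$converged && max(abs(cand$state - u_sym)) > 1e-6) {
      fp <- cand
      break
    }
  }
  if (is.null(fp))
    stop("failed to converge onto the bifurcating branch at J = ", J_bp + dJ)
  if (is.null(J_range)) J_range <- c(J_bp + dJ, J_bp + 1)
  continue_equilibria(model, J_range[1], J_range[2], u0 = fp$state, ...)
}

#' Limit-cycle envelope along a stimulus sweep
#'
#' For each J, integrates the model from the (possibly unstable)
#' equilibrium perturbed by `perturb` on the first variable, discards the
#' transient, and records the min/max of the excitatory variable. Below the
#' Hopf point the envelope collapses onto the equilibrium; above it the
#' width traces the limit-cycle amplitude (growing like sqrt(J - J_H) near
#' a supercritical Hopf).
#'
#' @param model A `wc_model`.
#' @param J_grid Stimulus values to sweep.
#' @param t_end,transient Integration and discard windows (ms).
#' @param perturb Perturbation applied to the first state variable.
#' @param var Variable whose envelope is recorded.
#' @param dt_out Output sampling (ms).
#' @return A data frame with columns `J`, `u_eq`, `u_min`, `u_max`.
#' @export
cycle_envelope <- function(model, J_grid, t_end = 2000, transient = 1000,
                           perturb = 0.01, var = 1, dt_out = 0.5) {
  seed_state <- NULL
  out <- lapply(J_grid, function(J) {
    fp <- find_fixed_point(model, J, seed_state)
    seed_state <<- fp$state
    u0 <- pmin(pmax(fp$state + perturb * (seq_len(model$n) == var), 0), 1)
    tr <- wc_integrate(model, u0, t_end = t_end, J = J, dt_out = dt_out)
    keep <- tr$times >= transient
    x <- tr$states[keep, var]
    data.frame(J = J, u_eq = fp$state[var], u_min = min(x), u_max = max(x))
  })
  do.call(rbind, out)
}
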