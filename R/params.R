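#' Model parameters for the Wilson-Cowan motion models
#'
#' Constructs the full scalar parameter set shared by the point and spatial
#' models: coupling weights, firing thresholds, time constants, Gaussian
#' kernel spreads and shift, stimulus amplitude and spatial step. Defaults
#' reproduce the reference configuration in which the excitatory/inhibitory
#' pair is quiescent at rest and oscillates near 20 Hz under constant
#' stimulation.
#'
#' The time constants deserve a note: the reference configuration is only
#' dynamically consistent (Hopf onset near J = 0.41, ~20 Hz limit cycle at
#' J = 1) with `tau_e = 5`, `tau_i = 10`; the swapped assignment produces a
#' non-oscillating medium. The defaults encode the consistent assignment.
#'
#' @param w_ee,w_ei,w_ie,w_ii Non-negative dimensionless coupling weights.
#'   `w_ei` is the weight of the connection *to* e *from* i.
#' @param b_e,b_i Dimensionless firing thresholds.
#' @param tau_e,tau_i Time constants of excitation and inhibition (ms).
#' @param sigma_e,sigma_i Spatial spreads of the excitatory and inhibitory
#'   lateral coupling (mm).
#' @param delta Spatial shift of the excitatory coupling profile (mm).
#'   Positive values tune the medium to leftward-traveling waves.
#' @param alpha Grating stimulus amplitude (dimensionless).
#' @param dx Spatial discretization step (mm).
#'
#' @return An object of class `wc_params` (a validated named list).
#' @seealso [ei_model()], [eie_model()], [simulate_field()]
#' @export
#' @examples
#' p <- wc_params()
#' p$w_ee
wc_params <- function(w_ee = 12, w_ei = 10, w_ie = 10, w_ii = 1,
                      b_e = 1.75, b_i = 2.6,
                      tau_e = 5, tau_i = 10,
                      sigma_e = 0.05, sigma_i = 0.15, delta = 0.02,
                      alpha = 1, dx = 0.01) {
  p <- list(w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
            b_e = b_e, b_i = b_i, tau_e = tau_e, tau_i = tau_i,
            sigma_e = sigma_e, sigma_i = sigma_i, delta = delta,
            alpha = alpha, dx = dx)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    p[[nm]] <- as.numeric(v)
  }
  if (any(c(w_ee, w_ei, w_ie, w_ii) < 0))
    stop("coupling weights must be non-negative")
  if (tau_e <= 0 || tau_i <= 0) stop("time constants must be positive")
  if (sigma_e <= 0 || sigma_i <= 0) stop("kernel spreads must be positive")
  if (dx <= 0) stop("dx must be positive")
  structure(p, class = "wc_params")
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Wilson-Cowan model parameters\n")
  cat(sprintf("  weights: w_ee=%g w_ei=%g w_ie=%g w_ii=%g\n",
              x$w_ee, x$w_ei, x$w_ie, x$w_ii))
  cat(sprintf("  thresholds: b_e=%g b_i=%g\n", x$b_e, x$b_i))
  cat(sprintf("  time constants (ms): tau_e=%g tau_i=%g\n", x$tau_e, x$tau_i))
  cat(sprintf("  kernels (mm): sigma_e=%g sigma_i=%g delta=%g dx=%g\n",
              x$sigma_e, x$sigma_i, x$delta, x$dx))
  cat(sprintf("  stimulus amplitude: alpha=%g\n", x$alpha))
  invisible(x)
}

# coerce a plain list of overrides onto the defaults
as_wc_params <- function(x) {
  if (inherits(x, "wc_params")) return(x)
  if (is.null(x)) return(wc_params())
  if (!is.list(x)) stop("parameter overrides must be a named list")
  defaults <- formals(wc_params)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  do.call(wc_params, x)
}
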