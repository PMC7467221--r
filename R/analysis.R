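# Quantitative readouts of field simulations: dominant spatiotemporal
# frequencies with direction sign, response ranges, and tuning curves.

# map an FFT bin index (1-based) to a signed frequency given n samples at
# spacing d (frequency units: cycles per unit of d)
fft_freq <- function(idx, n, d) {
  k <- idx - 1L
  k <- ifelse(k > n / 2, k - n, k)
  k / (n * d)
}

#' Dominant spatiotemporal frequency of a field simulation
#'
#' Two-dimensional discrete Fourier transform of the mean-subtracted
#' post-transient activity of one population. The peak is the
#' maximum-magnitude mode excluding the zero-frequency row (temporal DC)
#' and column (spatial DC). The signed temporal frequency follows the
#' grating convention: a plane wave `cos(2 pi f_x x - 2 pi f_t t)` with
#' `f_t < 0` moves leftward (toward decreasing x). Commensurate plane
#' waves are recovered exactly.
#'
#' @param field A `wc_field` from [simulate_field()].
#' @param transient Initial window to discard (ms).
#' @param pop Population to analyse (index or name).
#' @param min_power_frac Warn when the peak (with its conjugate) carries
#'   less than this fraction of total power.
#' @return A `wc_spectral_peak` list: `f_x` (cycles/mm, >= 0), `f_t` (Hz,
#'   signed, negative = leftward), `power_fraction`.
#' @export
dominant_frequencies <- function(field, transient = 500, pop = 1,
                                 min_power_frac = 0.05) {
  keep <- field$times > transient
  if (sum(keep) < 16)
    stop("post-transient window too short for spectral analysis")
  A <- field$activity[[pop]][keep, , drop = FALSE]
  A <- A - mean(A)
  S <- stats::fft(A)
  P <- Mod(S)^2
  nt <- nrow(A); nx <- ncol(A)
  P[1, ] <- 0   # temporal DC row
  P[, 1] <- 0   # spatial DC column
  i <- which(P == max(P), arr.ind = TRUE)[1, ]
  nu_t <- as.numeric(fft_freq(i[1], nt, field$dt_out))     # cycles/ms
  nu_x <- as.numeric(fft_freq(i[2], nx, field$domain$dx))  # cycles/mm
  # standardize to the representative with positive spatial frequency;
  # exp(2 pi i (nu_x x + nu_t t)) travels at -nu_t/nu_x, so f_t = -nu_t
  if (nu_x < 0 || (nu_x == 0 && nu_t < 0)) {
    nu_x <- -nu_x; nu_t <- -nu_t
  }
  frac <- 2 * max(P) / sum(P)
  if (frac < min_power_frac)
    warning("no clear spectral peak (power fraction ",
            signif(frac, 2), ")")
  structure(list(f_x = nu_x, f_t = -nu_t * 1000, power_fraction = frac),
            class = "wc_spectral_peak")
}

#' @export
print.wc_spectral_peak <- function(x, ...) {
  cat(sprintf(
    "dominant mode: f_x = %g cycles/mm, f_t = %+.4g Hz (%s), power %.1f%%\n",
    x$f_x, x$f_t,
    if (x$f_t < 0) "leftward" else if (x$f_t > 0) "rightward" else "static",
    100 * x$power_fraction))
  invisible(x)
}

#' Dominant spatial frequency of a field simulation
#'
#' Marginal spatial power spectrum of the post-transient activity: the 2-D
#' spectrum summed over all temporal frequencies including the temporal DC
#' row, so a time-stationary (Turing) pattern is measured as well as an
#' oscillating one. Returns the positive spatial mode carrying maximal
#' power (spatial DC excluded).
#'
#' @inheritParams dominant_frequencies
#' @return Spatial frequency (cycles/mm).
#' @export
dominant_spatial_frequency <- function(field, transient = 500, pop = 1) {
  keep <- field$times > transient
  A <- field$activity[[pop]][keep, , drop = FALSE]
  A <- A - mean(A)
  P <- Mod(stats::fft(A))^2
  nx <- ncol(A)
  marg <- colSums(P)
  half <- 2:(floor(nx / 2))   # positive non-DC spatial modes
  (which.max(marg[half])) / (nx * field$domain$dx)
}

#' Post-transient response ranges of a field simulation
#'
#' Extrema of each population over the full post-transient space-time
#' window, plus (for two excitatory layers) the range of the point-wise
#' difference `U_e1 - U_e2` on the aligned grid.
#'
#' @param field A `wc_field`.
#' @param transient Initial window to discard (ms).
#' @return A list with one `c(min, max)` per population, and `diff_range`
#'   for the E-I-E model.
#' @export
response_range <- function(field, transient = 500) {
  keep <- field$times > transient
  out <- lapply(field$activity, function(A)
    range(A[keep, , drop = FALSE]))
  if (all(c("U_e1", "U_e2") %in% names(field$activity))) {
    D <- field$activity$U_e1[keep, , drop = FALSE] -
      field$activity$U_e2[keep, , drop = FALSE]
    out$diff_range <- range(D)
  }
  out
}

tuning_run <- function(params, domain, f_x, f_t, alpha, t_end, dt, seed) {
  f <- simulate_field("eie", params, domain,
                      grating = list(f_x = f_x, f_t = f_t, alpha = alpha),
                      t_end = t_end, dt = dt, dt_out = 1, seed = seed)
  keep <- f$times > t_end / 2   # maximal response over the final half
  c(max_e1 = max(f$activity$U_e1[keep, ]),
    max_e2 = max(f$activity$U_e2[keep, ]))
}

#' Tuning curves of the spatial E-I-E model
#'
#' Sweeps one frequency of the drifting-grating stimulus while holding the
#' other fixed, running one field simulation per sweep value with an
#' identical seed and duration, and records the maximal post-transient
#' response of each excitatory layer (space-time maximum over the final
#' half of the simulation). Spatial frequencies are snapped to the nearest
#' value commensurate with the domain (multiples of `1/L`).
#'
#' @param params A [wc_params()] object.
#' @param f_t,f_x The swept grid (Hz / cycles per mm) and, respectively,
#'   the fixed complementary frequency.
#' @param domain A [wc_domain()].
#' @param alpha Grating amplitude.
#' @param t_end Duration of each simulation (ms).
#' @param dt Integration step (ms).
#' @param seed Perturbation seed shared by all sweep values.
#' @return A `wc_tuning` data frame with columns `f` (the swept value),
#'   `max_e1`, `max_e2`; attributes `axis` ("temporal"/"spatial") and
#'   `fixed` record the sweep geometry.
#' @export
temporal_tuning_curve <- function(params = wc_params(),
                                  f_t = seq(-40, 40, by = 2), f_x = 2.5,
                                  domain = wc_domain(), alpha = 1,
                                  t_end = 2000, dt = 0.1, seed = 1) {
  check_commensurate(f_x, domain)
  rows <- vapply(f_t, function(ft)
    tuning_run(params, domain, f_x, ft, alpha, t_end, dt, seed),
    numeric(2))
  out <- data.frame(f = f_t, max_e1 = rows[1, ], max_e2 = rows[2, ])
  structure(out, axis = "temporal", fixed = f_x,
            class = c("wc_tuning", "data.frame"))
}

#' @rdname temporal_tuning_curve
#' @export
spatial_tuning_curve <- function(params = wc_params(),
                                 f_x = seq(0.25, 15, by = 0.25), f_t = 15,
                                 domain = wc_domain(), alpha = 1,
                                 t_end = 2000, dt = 0.1, seed = 1) {
  fx_snap <- unique(round(f_x * domain$L) / domain$L)
  fx_snap <- fx_snap[fx_snap > 0]
  if (!isTRUE(all.equal(sort(fx_snap), sort(unique(f_x[f_x > 0])))))
    message("spatial frequencies snapped to multiples of 1/L = ",
            1 / domain$L)
  rows <- vapply(fx_snap, function(fx)
    tuning_run(params, domain, fx, f_t, alpha, t_end, dt, seed),
    numeric(2))
  out <- data.frame(f = fx_snap, max_e1 = rows[1, ], max_e2 = rows[2, ])
  structure(out, axis = "spatial", fixed = f_t,
            class = c("wc_tuning", "data.frame"))
}

#' @export
plot.wc_tuning <- function(x, ...) {
  xl <- if (attr(x, "axis") == "temporal") "f_t (Hz)" else "f_x (cycles/mm)"
  graphics::matplot(x$f, cbind(x$max_e1, x$max_e2), type = "b", pch = c(1, 2),
                    lty = c(2, 1), xlab = xl, ylab = "maximal response", ...)
  graphics::legend("topright", c("U_e1", "U_e2"), pch = c(1, 2),
                   lty = c(2, 1), col = 1:2, bty = "n")
  invisible(x)
}

#' Half-maximum band edges of a tuning curve
#'
#' Finds where a response curve crosses `level` times its global maximum,
#' by linear interpolation between sweep points. Used to read off the
#' temporal (Hz) and spatial (cycles/mm) response bands.
#'
#' @param f Swept frequency grid (must be sorted increasing).
#' @param response Response values on the grid.
#' @param level Fraction of the global maximum defining the band.
#' @return `c(lower, upper)`: the outermost crossings bracketing the
#'   global maximum (NA when the response never falls below the level on
#'   that side).
#' @export
band_edges <- function(f, response, level = 0.5) {
  stopifnot(length(f) == length(response), !is.unsorted(f))
  thr <- level * max(response)
  above <- response >= thr
  i_max <- which.max(response)
  cross <- function(i, j) {  # linear interpolation between grid points
    f[i] + (thr - response[i]) * (f[j] - f[i]) / (response[j] - response[i])
  }
  lower <- NA_real_
  if (i_max > 1)
    for (i in seq(i_max, 2, by = -1))
      if (!above[i - 1]) { lower <- cross(i - 1, i); break }
  upper <- NA_real_
  if (i_max < length(f))
    for (i in seq(i_max, length(f) - 1))
      if (!above[i + 1]) { upper <- cross(i + 1, i); break }
  c(lower = lower, upper = upper)
}
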