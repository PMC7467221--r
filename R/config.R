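# Experiment configuration, presets, provenance and fixture generation.

config_schema <- c("task", "preset", "params", "domain", "stimulus",
                   "duration", "transient", "dt", "dt_out", "seed",
                   "n_trials", "J", "Delta", "onset", "sweep", "out")

#' Load an experiment configuration
#'
#' Reads a YAML experiment description, validates it against the known key
#' set (unknown keys are an error, named in the message), and merges the
#' `table1` parameter preset (the package's reference parameter values,
#' bundled as `inst/extdata/table1.yaml`) with any `params` overrides.
#'
#' @param path Path to a YAML file, or the preset name `"table1"`.
#' @return A `wc_config` list with a fully resolved `params` element and a
#'   reproducibility `hash`.
#' @export
#' @examples
#' cfg <- load_config("table1")
#' cfg$params$w_ee
load_config <- function(path) {
  if (identical(path, "table1"))
    path <- system.file("extdata", "table1.yaml", package = "corticalwaves")
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_schema)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  preset <- raw$preset
  if (!is.null(preset) && !identical(preset, "table1"))
    stop("unknown preset '", preset, "'")
  cfg <- raw
  cfg$params <- as_wc_params(raw$params)
  if (is.null(cfg$task)) cfg$task <- "simulate-point"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "wc_config")
}

#' Deterministic hash of a configuration
#'
#' Canonicalizes the configuration (keys sorted recursively, numbers
#' deparsed at full precision) and returns its MD5, so that identical
#' configurations map to identical hashes across sessions.
#'
#' @param cfg A configuration list.
#' @return A hex string.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, character(1)),
                        sep = ":", collapse = ","), "}")
    } else paste(deparse(x), collapse = "")
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a configured experiment
#'
#' Dispatches a `wc_config` to the appropriate module: point or field
#' simulation, equilibrium continuation with special-point detection,
#' winner-take-all trial ensemble, tuning-curve sweep, or spectral
#' analysis of a fresh field simulation. When `cfg$out` is set, results
#' are written as columnar text next to a small provenance record.
#'
#' @param cfg A `wc_config` from [load_config()], or a path/preset name.
#' @return A `wc_run_record`: `result` (the module's native object),
#'   `config_hash`, `version`, `paths` of any files written.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  p <- cfg$params
  dom <- if (is.null(cfg$domain)) wc_domain()
         else wc_domain(cfg$domain$L %||% 4, cfg$domain$dx %||% p$dx)
  dur <- cfg$duration %||% 2000
  seed <- cfg$seed %||% 1L
  result <- switch(
    cfg$task,
    "simulate-point" = {
      model <- if (!is.null(cfg$Delta)) eie_model(p, cfg$Delta) else ei_model(p)
      rest <- find_fixed_point(model, J = 0,
                               guess = rep(0.1, model$n))$state
      wc_integrate(model, rest, t_end = dur, J = cfg$J %||% 1,
                   onset = cfg$onset %||% "sudden")
    },
    "simulate-field" = {
      g <- cfg$stimulus
      if (!is.null(g) && identical(g$type, "grating"))
        simulate_field(if (isTRUE(cfg$Delta == 0) || is.null(cfg$Delta))
                         "eie" else "eie", p, dom,
                       grating = list(f_x = g$f_x, f_t = g$f_t,
                                      alpha = g$alpha %||% p$alpha),
                       t_end = dur, seed = seed)
      else
        simulate_field("ei", p, dom, J = cfg$J %||% 1, t_end = dur,
                       seed = seed)
    },
    "continue" = {
      model <- if (!is.null(cfg$Delta)) eie_model(p, cfg$Delta) else ei_model(p)
      br <- continue_equilibria(model, 0, cfg$J %||% 2,
                                u0 = rep(0.1, model$n))
      list(branch = br,
           hopf = detect_hopf(br, model),
           special = detect_special_points(br, model))
    },
    "trials" = run_trials(p, J = cfg$J %||% 2, Delta = cfg$Delta %||% 0,
                          n_trials = cfg$n_trials %||% 1000, seed = seed,
                          onset = cfg$onset %||% "sudden"),
    "tuning" = {
      sw <- cfg$sweep %||% list()
      axis <- sw$axis %||% "temporal"
      grid <- seq(sw$from %||% -40, sw$to %||% 40, by = sw$by %||% 2)
      if (identical(axis, "temporal"))
        temporal_tuning_curve(p, f_t = grid, f_x = sw$fixed %||% 2.5,
                              domain = dom, t_end = dur, seed = seed)
      else
        spatial_tuning_curve(p, f_x = grid[grid > 0],
                             f_t = sw$fixed %||% 15,
                             domain = dom, t_end = dur, seed = seed)
    },
    "spectrum" = {
      g <- cfg$stimulus
      f <- if (!is.null(g) && identical(g$type, "grating"))
        simulate_field("eie", p, dom,
                       grating = list(f_x = g$f_x, f_t = g$f_t,
                                      alpha = g$alpha %||% p$alpha),
                       t_end = dur, seed = seed)
      else simulate_field("ei", p, dom, J = cfg$J %||% 1, t_end = dur,
                          seed = seed)
      dominant_frequencies(f, transient = cfg$transient %||% 500)
    },
    stop("unknown task '", cfg$task, "'")
  )
  paths <- character(0)
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    paths <- write_result(result, cfg, cfg$out)
  }
  structure(list(result = result, config_hash = cfg$hash %||% config_hash(cfg),
                 version = as.character(utils::packageVersion("corticalwaves")),
                 task = cfg$task, seed = seed, paths = paths),
            class = "wc_run_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_result <- function(result, cfg, dir) {
  stamp <- c(sprintf("# corticalwaves %s",
                     as.character(utils::packageVersion("corticalwaves"))),
             sprintf("# task: %s  seed: %s  config: %s",
                     cfg$task, cfg$seed %||% 1,
                     cfg$hash %||% config_hash(cfg)))
  save_tsv <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = "\t",
                                        row.names = FALSE, quote = FALSE))
    path
  }
  if (inherits(result, "wc_trajectory"))
    save_tsv(data.frame(time = result$times, result$states),
             "trajectory.tsv")
  else if (inherits(result, "wc_trials"))
    save_tsv(as.data.frame(result), "trials.tsv")
  else if (inherits(result, "wc_tuning"))
    save_tsv(as.data.frame(result), "tuning.tsv")
  else if (inherits(result, "wc_field"))
    save_tsv(data.frame(time = result$times,
                        result$activity[[1]][, seq(1, ncol(result$activity[[1]]),
                                                   by = 10)]),
             "field_downsampled.tsv")
  else if (is.list(result) && !is.null(result$branch)) {
    b <- result$branch
    p1 <- save_tsv(data.frame(J = b$J, b$states,
                              re1 = Re(b$eig[, 1]), im1 = Im(b$eig[, 1]),
                              stable = b$stable), "branch.tsv")
    sp <- rbind(if (nrow(result$hopf)) result$hopf[, c("kind", "J")],
                if (nrow(result$special)) result$special[, c("kind", "J")])
    p2 <- save_tsv(sp %||% data.frame(kind = character(0), J = numeric(0)),
                   "special_points.tsv")
    c(p1, p2)
  } else if (inherits(result, "wc_spectral_peak"))
    save_tsv(data.frame(f_x = result$f_x, f_t = result$f_t,
                        power_fraction = result$power_fraction),
             "spectrum.tsv")
  else character(0)
}

#' @export
print.wc_run_record <- function(x, ...) {
  cat(sprintf("wc_run_record: task '%s' (seed %s), package %s\n",
              x$task, x$seed, x$version))
  cat("  config hash:", x$config_hash, "\n")
  if (length(x$paths)) cat("  wrote:", paste(x$paths, collapse = ", "), "\n")
  invisible(x)
}

#' Generate the synthetic fixtures used by the test suite
#'
#' Builds small, fully deterministic in-memory objects: a commensurate
#' plane-wave field with exactly known spatial and temporal frequencies, a
#' toy kernel, and a short resting-state trajectory. Regeneration with the
#' same seed is bit-identical; nothing is read from disk or the network.
#'
#' @param seed Integer seed.
#' @param f_x,f_t Plane-wave frequencies (cycles/mm, Hz); both must be
#'   commensurate with the fixture grids.
#' @return A list: `plane_wave` (a minimal `wc_field`), `toy_kernel`,
#'   `trajectory`.
#' @export
generate_fixtures <- function(seed = 1, f_x = 2.5, f_t = -15) {
  dom <- wc_domain(L = 4, dx = 0.01)
  check_commensurate(f_x, dom)
  nt <- 1000L                        # 1 ms sampling: f_t resolution 1 Hz
  tt <- seq_len(nt)
  A <- outer(tt, dom$x, function(t, x)
    0.5 + 0.4 * cos(2 * pi * (f_x * x - (f_t / 1000) * t)))
  plane_wave <- structure(
    list(times = tt, x = dom$x, activity = list(U_e = A), model = "ei",
         params = wc_params(), domain = dom, J = NULL,
         grating = list(f_x = f_x, f_t = f_t, alpha = 1),
         dt = 1, dt_out = 1, seed = seed),
    class = "wc_field")
  set.seed(seed)
  traj <- wc_integrate(ei_model(), c(0.12, 0.17), t_end = 100, J = 0)
  list(plane_wave = plane_wave,
       toy_kernel = make_kernel(0.05, 0.02, dom),
       trajectory = traj)
}
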