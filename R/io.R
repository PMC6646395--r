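#' Load a simulation configuration from YAML
#'
#' Reads a nested-key YAML file, fills every unspecified field with the
#' package default and validates all invariants (threshold ordering, pulse
#' geometry, population size). Recognised top-level blocks: `network`,
#' `controller`, `pulse`, `simulation`.
#'
#' @param path Path to a YAML config file.
#' @return A validated [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  take <- function(block, fn) {
    args <- y[[block]]
    if (is.null(args)) args <- list()
    # YAML 1.1 reads a bare `N:` key as a boolean; map it back
    names(args)[names(args) == "FALSE"] <- "N"
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown field(s) in `%s`: %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    args
  }
  net_args <- take("network", network_config)
  ctrl_args <- take("controller", controller_config)
  pulse_args <- take("pulse", pulse_train_config)
  sim_args <- take("simulation", simulation_config)
  # pulse_train_config itself warns when the gap exceeds the
  # charge-balanced limit
  pulse <- do.call(pulse_train_config, pulse_args)
  do.call(simulation_config, c(
    list(network = do.call(network_config, net_args),
         controller = do.call(controller_config, ctrl_args),
         pulse = pulse),
    sim_args))
}

#' Dump a configuration to YAML
#'
#' Writes the fully resolved configuration (all defaults filled) so reruns
#' are traceable; `load_config(dump_config(cfg))` reproduces `cfg`.
#'
#' @param cfg A [simulation_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  y <- list(
    network = unclass(cfg$network)[
      setdiff(names(cfg$network), c("stn", "gpe"))],
    controller = unclass(cfg$controller),
    pulse = unclass(cfg$pulse)[setdiff(names(cfg$pulse), "period")],
    simulation = unclass(cfg)[
      setdiff(names(cfg), c("network", "controller", "pulse"))]
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write run results to disk
#'
#' Time series as CSV, summary as JSON, plus a manifest (resolved config,
#' package version, seeds) so every output is traceable to its run.
#'
#' @param sim A `stngpe_sim` object.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem. Default "run".
#' @param downsample Keep every k-th series row. Default 1.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(sim, dir, stem = "run", downsample = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  se <- sim$series[seq(1, nrow(sim$series), by = downsample), ]
  paths <- c(
    series = file.path(dir, paste0(stem, "_series.csv")),
    summary = file.path(dir, paste0(stem, "_summary.json")),
    manifest = file.path(dir, paste0(stem, "_manifest.json"))
  )
  utils::write.csv(se, paths[["series"]], row.names = FALSE)
  jsonlite::write_json(as.list(sim$summary), paths[["summary"]],
                       auto_unbox = TRUE, digits = NA)
  cfg <- sim$config
  manifest <- list(
    package = "stngpe",
    version = as.character(utils::packageVersion("stngpe")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = cfg$controller$mode,
    seeds = list(network = cfg$network$seed, ic = cfg$ic_seed),
    t_total = cfg$t_total, t_stim_on = cfg$t_stim_on, dt = cfg$dt,
    controller = unclass(cfg$controller),
    pulse = unclass(cfg$pulse),
    files = as.list(paths)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Export the lattice as an edge list CSV
#'
#' @param N Cells per population.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(N, path) {
  utils::write.csv(build_lattice(N), path, row.names = FALSE)
  invisible(path)
}

#' Test and demonstration fixtures
#'
#' Small deterministic inputs: `"tiny-network"` is an N = 20 configuration
#' that integrates in seconds; `"synthetic-lfp"` is a noisy beta-band
#' sinusoid for filter and gate tests; `"synthetic-bursts"` is a smoothed
#' trace with planted burst intervals and known ground truth.
#'
#' @param kind One of `"tiny-network"`, `"synthetic-lfp"`,
#'   `"synthetic-bursts"`.
#' @param seed Integer seed.
#' @return For `"tiny-network"`, a [simulation_config()]; for the synthetic
#'   signals, a list with the trace tibble and its ground truth.
#' @export
make_fixture <- function(kind = c("tiny-network", "synthetic-lfp",
                                  "synthetic-bursts"), seed = 1L) {
  kind <- match.arg(kind)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  if (kind == "tiny-network") {
    return(simulation_config(
      network = network_config(N = 20, seed = seed),
      controller = controller_config("cDBS", K = 0),
      t_total = 3000, t_stim_on = 2000, t_skip = 500,
      ic_seed = seed))
  }
  if (kind == "synthetic-lfp") {
    dt <- 1
    t <- seq(0, 20000, by = dt)
    period <- 103
    amp <- 0.02 * (1 + 0.5 * sin(2 * pi * t / 5000))
    x <- amp * sin(2 * pi * t / period) + 0.001 * stats::rnorm(length(t))
    return(list(trace = tibble::tibble(t = t, value = x),
                dt = dt, period = period))
  }
  # synthetic-bursts: baseline with trapezoidal bumps at known intervals
  dt <- 10
  t <- seq(0, 200000, by = dt)
  base <- 0.1
  value <- rep(base, length(t))
  onsets <- c(30, 80, 140) * 1000
  lengths <- c(5, 12, 3) * 1000
  for (k in seq_along(onsets)) {
    ramp <- 1000
    seg <- t >= onsets[k] - ramp & t <= onsets[k] + lengths[k] + ramp
    prof <- pmin(1, pmin((t[seg] - (onsets[k] - ramp)) / ramp,
                         ((onsets[k] + lengths[k] + ramp) - t[seg]) / ramp))
    value[seg] <- base + 0.5 * prof
  }
  list(trace = tibble::tibble(t = t, value = value), dt = dt,
       onsets_ms = onsets, lengths_ms = lengths)
}
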