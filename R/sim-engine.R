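#' Simulation configuration
#'
#' Assembles network, controller, pulse-train and integration settings for
#' one closed-loop run. Time is in ms throughout.
#'
#' @param network A [network_config()].
#' @param controller A [controller_config()].
#' @param pulse A [pulse_train_config()].
#' @param t_total Total simulated time (ms). Default 40000.
#' @param t_stim_on Stimulation onset (ms). Default 20000.
#' @param t_skip Transient skipped after stimulation onset before summary
#'   averaging (ms). Default 5000.
#' @param dt Integration step (ms). Default 0.05.
#' @param rec_dt Recording step of the time series (ms). Default 1.
#' @param filter_T Centre period of the LFP filter (ms). The default (500)
#'   is the calibrated mean period of the stimulation-free LFP rhythm of
#'   the default network, re-derivable with [lfp_envelope_period()] on a
#'   stimulation-free run.
#' @param ic_seed Seed for the randomized initial conditions.
#' @param ic_mode Initial-state preparation, `"synchronized"` (default) or
#'   `"dispersed"`; see [initial_state()].
#' @param spike_threshold Spike-detection voltage (mV). Default -10.
#' @param spike_lockout Spike-detection refractory lockout (ms). Default 2.
#' @param isi_gap Burst-grouping inter-spike gap (ms). Default 25.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(network = network_config(),
                              controller = controller_config(),
                              pulse = pulse_train_config(),
                              t_total = 40000, t_stim_on = 20000,
                              t_skip = 5000,
                              dt = 0.05, rec_dt = 1,
                              filter_T = 500,
                              ic_seed = 42L, ic_mode = "synchronized",
                              spike_threshold = -10, spike_lockout = 2,
                              isi_gap = 25) {
  stopifnot(inherits(network, "network_config"),
            inherits(controller, "controller_config"),
            inherits(pulse, "pulse_train_config"))
  if (t_total <= t_stim_on + t_skip) {
    stop("t_total must exceed t_stim_on + t_skip", call. = FALSE)
  }
  if (dt <= 0 || rec_dt < dt) stop("require dt > 0 and rec_dt >= dt",
                                   call. = FALSE)
  structure(list(network = network, controller = controller, pulse = pulse,
                 t_total = t_total, t_stim_on = t_stim_on, t_skip = t_skip,
                 dt = dt, rec_dt = rec_dt, filter_T = filter_T,
                 ic_seed = as.integer(ic_seed), ic_mode = ic_mode,
                 spike_threshold = spike_threshold,
                 spike_lockout = spike_lockout, isi_gap = isi_gap),
            class = "simulation_config")
}

#' Randomized initial network state
#'
#' Per-cell initial conditions, seeded and reproducible. Two preparations
#' are available: `"synchronized"` (the default) draws membrane potentials
#' from a narrow band around rest so the run starts inside the established
#' synchronized pathological state that the stimulation protocols act on;
#' `"dispersed"` draws potentials uniformly over \[-80, -40\] mV and
#' calcium over \[0.05, 0.3\]; the synchronized preparation also narrows
#' the calcium band to \[0.15, 0.25\] so the slow variables start
#' coherent. Gating variables start at their voltage steady states and
#' synaptic variables near their subthreshold fixed point.
#'
#' @param cfg A [simulation_config()] (or [network_config()]).
#' @param seed Integer seed; defaults to the config's `ic_seed`.
#' @param mode `"synchronized"` or `"dispersed"`.
#' @return Numeric state vector in engine layout (12 blocks of length N).
#' @export
initial_state <- function(cfg, seed = NULL, mode = NULL) {
  net <- if (inherits(cfg, "simulation_config")) cfg$network else cfg
  if (is.null(seed)) {
    seed <- if (inherits(cfg, "simulation_config")) cfg$ic_seed else 42L
  }
  if (is.null(mode)) {
    mode <- if (inherits(cfg, "simulation_config")) cfg$ic_mode else "synchronized"
  }
  mode <- match.arg(mode, c("synchronized", "dispersed"))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  N <- net$N
  pop_init <- function(p) {
    v <- if (mode == "synchronized") stats::runif(N, -63, -61)
         else stats::runif(N, -80, -40)
    Ca <- if (mode == "synchronized") stats::runif(N, 0.15, 0.25)
          else stats::runif(N, 0.05, 0.3)
    n <- sigmoid_activation(v, p$theta_n, p$sigma_n)
    h <- sigmoid_activation(v, p$theta_h, p$sigma_h)
    r <- sigmoid_activation(v, p$theta_r, p$sigma_r)
    H <- sigmoid_activation(v - net$theta_g, net$theta_gH, net$sigma_gH)
    s <- pmin(0.05, net$alpha * H / (net$alpha * H + net$beta))
    c(v, Ca, n, h, r, s)
  }
  c(pop_init(net$stn), pop_init(net$gpe))
}

#' Integrate the closed-loop network
#'
#' Fixed-step RK4 integration of the full STN-GPe network with the selected
#' stimulation controller, the online resonant LFP filter (advanced by its
#' exact per-step propagator), the feedback delay buffer and the hysteresis
#' gate. Fully reproducible for fixed seeds.
#'
#' @param cfg A [simulation_config()].
#' @param state Optional initial state vector (defaults to
#'   [initial_state()] with `cfg$ic_seed`).
#' @return An object of class `stngpe_sim` with elements
#'   \describe{
#'     \item{series}{tibble `t, lfp, x, R, gate, S, A` on the recording grid}
#'     \item{spikes}{list of per-STN-neuron spike-time vectors (ms)}
#'     \item{summary}{one-row tibble of post-transient summary scalars}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulate_network <- function(cfg, state = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  het <- sample_heterogeneity(cfg$network)
  if (is.null(state)) state <- initial_state(cfg)
  fs <- lfp_filter(T_ms = cfg$filter_T)
  pr <- filter_propagator(fs, cfg$dt)
  rec_stride <- as.integer(round(cfg$rec_dt / cfg$dt))
  raw <- simulate_network_cpp(
    net_cfg = unclass(cfg$network),
    stn_par = unclass(cfg$network$stn), gpe_par = unclass(cfg$network$gpe),
    Iapp_stn = het$I_app_stn, eps_gpe = het$eps_gpe,
    y0 = state,
    ctrl_cfg = unclass(cfg$controller),
    pulse_cfg = unclass(cfg$pulse),
    filt_cfg = list(E = pr$E, B = pr$B, k_f = fs$k_f, u = fs$u,
                    udot = fs$udot),
    sim_cfg = list(dt = cfg$dt, t_total = cfg$t_total,
                   t_stim_on = cfg$t_stim_on, rec_stride = rec_stride,
                   spike_threshold = cfg$spike_threshold,
                   spike_lockout = cfg$spike_lockout))
  R <- order_parameter_trace(raw$spikes, raw$t, isi_gap = cfg$isi_gap)
  series <- tibble::tibble(t = raw$t, lfp = raw$lfp, x = raw$x, R = R,
                           gate = raw$gate, S = raw$S, A = raw$A)
  out <- structure(list(series = series, spikes = raw$spikes,
                        spikes_gpe = raw$spikes_gpe,
                        summary = NULL, config = cfg,
                        final_state = raw$state),
                   class = "stngpe_sim")
  out$summary <- summarize_run(out)
  out
}

#' Post-transient summary of a run
#'
#' Time-averaged order parameter (with its fluctuation sd), stimulation-on
#' fraction, administered stimulation and mean raw-LFP inter-peak period,
#' computed over the analysis window.
#'
#' @param sim A `stngpe_sim` object.
#' @param window Numeric `c(from, to)` in ms; default
#'   `[t_stim_on + t_skip, t_total]`.
#' @return One-row tibble with `R_mean`, `R_sd`, `T_on`, `S_abs_mean`,
#'   `lfp_period`, `window_from`, `window_to`.
#' @export
summarize_run <- function(sim, window = NULL) {
  cfg <- sim$config
  if (is.null(window)) {
    window <- c(cfg$t_stim_on + cfg$t_skip, cfg$t_total)
  }
  se <- sim$series
  idx <- which(se$t >= window[1] & se$t <= window[2])
  if (length(idx) == 0) stop("empty analysis window", call. = FALSE)
  Rw <- se$R[idx]
  tibble::tibble(
    mode = cfg$controller$mode,
    K = cfg$controller$K,
    R_mean = mean(Rw, na.rm = TRUE),
    R_sd = stats::sd(Rw, na.rm = TRUE),
    T_on = stimulation_time_fraction(se$gate[idx]),
    S_abs_mean = administered_stimulation(se$S[idx]),
    lfp_period = lfp_envelope_period(se$lfp[idx], cfg$rec_dt),
    window_from = window[1], window_to = window[2]
  )
}

#' @export
print.stngpe_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<stngpe_sim: %s, K = %g, N = %d, %g s simulated>\n",
              cfg$controller$mode, cfg$controller$K, cfg$network$N,
              cfg$t_total / 1000))
  print(x$summary)
  invisible(x)
}

#' Protocol averaging over ramp schedules
#'
#' Runs [simulate_network()] for `n_ramp_runs` ramp durations evenly spaced
#' over `ramp_range`, each with a distinct initial-condition seed, and
#' averages the post-transient summaries, mirroring the study protocol of
#' averaging each operating point over slightly different linear ramp-up
#' intervals.
#'
#' @param cfg A [simulation_config()]; its controller's `T_ramp` is
#'   replaced run by run.
#' @param n_ramp_runs Number of runs (>= 2). Default 3.
#' @param ramp_range Range (ms) over which ramp durations are spread.
#'   Default `c(0, 2000)`.
#' @return An object of class `stngpe_protocol`: list with `runs` (tibble
#'   of per-run summaries) and `summary` (one-row tibble of means and sds).
#' @export
run_protocol <- function(cfg, n_ramp_runs = 3, ramp_range = c(0, 2000)) {
  if (n_ramp_runs < 2) stop("n_ramp_runs must be >= 2", call. = FALSE)
  ramps <- seq(ramp_range[1], ramp_range[2], length.out = n_ramp_runs)
  runs <- purrr::map2_dfr(ramps, seq_along(ramps), function(tr, k) {
    ctrl <- cfg$controller
    ctrl$T_ramp <- tr
    cfg_k <- cfg
    cfg_k$controller <- ctrl
    cfg_k$ic_seed <- cfg$ic_seed + 7919L * k
    sm <- simulate_network(cfg_k)$summary
    dplyr::mutate(sm, T_ramp = tr, ic_seed = cfg_k$ic_seed, .before = 1)
  })
  summary <- tibble::tibble(
    mode = cfg$controller$mode, K = cfg$controller$K,
    GW = cfg$pulse$GW, tau = cfg$controller$tau,
    Th_on = cfg$controller$Th_on, Th_off = cfg$controller$Th_off,
    n_runs = nrow(runs),
    R_mean = mean(runs$R_mean), R_sd = stats::sd(runs$R_mean),
    T_on = mean(runs$T_on), T_on_sd = stats::sd(runs$T_on),
    S_abs_mean = mean(runs$S_abs_mean), S_abs_sd = stats::sd(runs$S_abs_mean)
  )
  structure(list(runs = runs, summary = summary, config = cfg),
            class = "stngpe_protocol")
}

#' @export
print.stngpe_protocol <- function(x, ...) {
  cat(sprintf("<stngpe_protocol: %s, %d ramp runs>\n",
              x$summary$mode, x$summary$n_runs))
  print(x$summary)
  invisible(x)
}

#' Parameter sweep
#'
#' Runs one [run_protocol()] per row of a parameter grid and collects the
#' averaged summaries in long format. If `file` is given, completed grid
#' points are loaded from it and skipped, making long sweeps resumable.
#'
#' @param cfg Base [simulation_config()].
#' @param grid Data frame whose columns may include `K`, `GW`, `tau`,
#'   `Th_on`, `Th_off`; one protocol per row.
#' @param n_ramp_runs Ramp runs per grid point. Default 3.
#' @param file Optional CSV path for resumable progress.
#' @return Tibble: the grid columns plus the protocol summary columns, and
#'   a logical `feasible` flag (FALSE where the gap exceeds the monophasic
#'   limit, in which case the point is skipped).
#' @export
sweep_protocol <- function(cfg, grid, n_ramp_runs = 3, file = NULL) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  done <- NULL
  if (!is.null(file) && file.exists(file)) {
    done <- utils::read.csv(file)
  }
  keys <- intersect(names(grid), c("K", "GW", "tau", "Th_on", "Th_off"))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(done) && nrow(done) > 0) {
      hit <- rep(TRUE, nrow(done))
      for (k in keys) hit <- hit & abs(done[[k]] - g[[k]]) < 1e-12
      if (any(hit)) {
        out[[i]] <- tibble::as_tibble(done[which(hit)[1], ])
        next
      }
    }
    cfg_i <- cfg
    ctrl <- cfg_i$controller
    for (k in intersect(keys, c("K", "tau", "Th_on", "Th_off"))) {
      ctrl[[k]] <- g[[k]]
    }
    cfg_i$controller <- ctrl
    if ("GW" %in% keys) {
      # infeasible geometries are flagged below rather than warned about
      cfg_i$pulse <- suppressWarnings(
        pulse_train_config(F_hz = cfg$pulse$F_hz, PW = cfg$pulse$PW,
                           GW = g$GW, ratio = cfg$pulse$ratio))
    }
    feasible <- cfg_i$pulse$GW <= monophasic_gap_threshold(
      cfg_i$pulse$F_hz, cfg_i$pulse$PW)
    if (!feasible) {
      row <- dplyr::mutate(g, feasible = FALSE)
    } else {
      pr <- run_protocol(cfg_i, n_ramp_runs = n_ramp_runs)
      row <- dplyr::bind_cols(
        g, dplyr::select(pr$summary, -dplyr::any_of(names(g))),
        tibble::tibble(feasible = TRUE))
    }
    out[[i]] <- row
    if (!is.null(file)) {
      res <- dplyr::bind_rows(out)
      utils::write.csv(res, file, row.names = FALSE)
    }
  }
  dplyr::bind_rows(out)
}
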