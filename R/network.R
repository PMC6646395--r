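#' Network configuration
#'
#' Describes the reciprocally coupled STN-GPe ring: population size, lattice
#' coupling, synaptic kinetics and per-cell heterogeneity. Both populations
#' live on 1-D lattices of `N` cells with periodic boundaries; each STN cell
#' excites the GPe cell at the same site, and each GPe cell inhibits the
#' three STN cells centred on its site.
#'
#' @param N Cells per population (>= 3). Default 200.
#' @param g_stn_gpe Excitatory STN->GPe weight (nS/um^2). Default 0.4.
#' @param g_gpe_stn Inhibitory GPe->STN weight (nS/um^2). Default 1.38.
#' @param v_stn_gpe,v_gpe_stn Synaptic reversal potentials (mV); defaults
#'   0 (excitatory) and -100 (inhibitory).
#' @param alpha,beta Rise and decay rates (ms^-1) of the excitatory
#'   STN->GPe synaptic variables (fast, spike-locked).
#' @param alpha_gpe,beta_gpe Rise and decay rates (ms^-1) of the
#'   inhibitory GPe->STN synaptic variables (slow decay, as in the
#'   underlying pallidal model).
#' @param theta_g Presynaptic voltage offset (mV) of the synaptic
#'   activation, applied before the logistic `H_inf`.
#' @param theta_gH,sigma_gH Midpoint and slope (mV) of `H_inf`.
#' @param I_app_mean,I_app_sd Gaussian heterogeneity of the STN applied
#'   current (pA/um^2). Defaults 10 and 0.015.
#' @param eps_mean,eps_sd Gaussian heterogeneity of the GPe calcium rate
#'   (ms^-1). Defaults 0.0055 and 2e-5.
#' @param stn,gpe Base cell parameter sets ([stn_params()], [gpe_params()]).
#' @param fan_offsets Integer ring offsets of the three STN targets of each
#'   GPe cell (the receiving STN cell `j` listens to GPe cells
#'   `j + fan_offsets`). `NULL` (the default) places the three targets
#'   symmetrically around the ring at `c(-round(N/3), 0, round(N/3))`,
#'   which supports the globally synchronized pathological state; pass
#'   `c(-1, 0, 1)` for a strictly centred local neighbourhood.
#' @param seed Integer seed for heterogeneity sampling.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 200,
                           g_stn_gpe = 0.4, g_gpe_stn = 1.38,
                           v_stn_gpe = 0, v_gpe_stn = -100,
                           alpha = 5, beta = 2,
                           alpha_gpe = 2, beta_gpe = 0.15,
                           theta_g = 30, theta_gH = -39, sigma_gH = 2,
                           I_app_mean = 10, I_app_sd = 0.015,
                           eps_mean = 0.0055, eps_sd = 2e-5,
                           stn = stn_params(), gpe = gpe_params(),
                           fan_offsets = NULL,
                           seed = 1L) {
  if (N < 3) stop("N must be >= 3 (GPe fan-out of 3)", call. = FALSE)
  if (I_app_sd < 0 || eps_sd < 0) stop("sd values must be >= 0", call. = FALSE)
  if (g_stn_gpe < 0 || g_gpe_stn < 0) stop("weights must be >= 0", call. = FALSE)
  if (is.null(fan_offsets)) fan_offsets <- c(-round(N / 3), 0, round(N / 3))
  if (length(fan_offsets) != 3) stop("fan_offsets must have length 3", call. = FALSE)
  structure(list(
    N = as.integer(N),
    g_stn_gpe = g_stn_gpe, g_gpe_stn = g_gpe_stn,
    v_stn_gpe = v_stn_gpe, v_gpe_stn = v_gpe_stn,
    alpha = alpha, beta = beta,
    alpha_gpe = alpha_gpe, beta_gpe = beta_gpe,
    theta_g = theta_g, theta_gH = theta_gH, sigma_gH = sigma_gH,
    I_app_mean = I_app_mean, I_app_sd = I_app_sd,
    eps_mean = eps_mean, eps_sd = eps_sd,
    stn = stn, gpe = gpe, fan_offsets = as.integer(fan_offsets),
    seed = as.integer(seed)
  ), class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config: N = %d + %d>\n", x$N, x$N))
  cat(sprintf("  coupling  STN->GPe %g, GPe->STN %g nS/um^2\n",
              x$g_stn_gpe, x$g_gpe_stn))
  cat(sprintf("  heterogeneity  I_app ~ N(%g, %g^2), eps ~ N(%g, %g^2)\n",
              x$I_app_mean, x$I_app_sd, x$eps_mean, x$eps_sd))
  invisible(x)
}

#' Build the periodic STN-GPe lattice
#'
#' STN cell `j` targets GPe cell `j`; GPe cell `j` targets the centred STN
#' neighbourhood `{j-1, j, j+1}` modulo `N`. Indices are 1-based.
#'
#' @param N Cells per population (>= 3).
#' @param fan_offsets Ring offsets of each GPe cell's three STN targets
#'   relative to its own index. Default `c(-1, 0, 1)`.
#' @return A tibble edge list with columns `src_pop`, `src`, `tgt_pop`,
#'   `tgt`, one row per synapse (`N` excitatory + `3N` inhibitory edges).
#' @export
build_lattice <- function(N, fan_offsets = c(-1L, 0L, 1L)) {
  if (N < 3) stop("N must be >= 3", call. = FALSE)
  N <- as.integer(N)
  j <- seq_len(N)
  wrap <- function(i) ((i - 1L) %% N) + 1L
  dplyr::bind_rows(
    tibble::tibble(src_pop = "STN", src = j, tgt_pop = "GPe", tgt = j),
    tibble::tibble(
      src_pop = "GPe",
      src = rep(j, each = 3L),
      tgt_pop = "STN",
      tgt = wrap(rep(j, each = 3L) - rep(as.integer(fan_offsets), times = N))
    )
  )
}

#' Synaptic current
#'
#' `I_syn = g * (v_post - v_rev) * sum(s_pre)` (pA/um^2).
#'
#' @param v_post Postsynaptic membrane potential (mV).
#' @param s_presum Sum of presynaptic gating variables (>= 0).
#' @param g Synaptic weight (nS/um^2).
#' @param v_rev Synaptic reversal potential (mV).
#' @export
synaptic_current <- function(v_post, s_presum, g, v_rev) {
  if (any(s_presum < 0)) stop("s_presum must be >= 0", call. = FALSE)
  g * (v_post - v_rev) * s_presum
}

#' Synaptic variable dynamics
#'
#' `s' = alpha * H_inf(v_pre - theta_g) * (1 - s) - beta * s` with
#' `H_inf(x) = 1/(1 + exp(-(x - theta_gH)/sigma_gH))`.
#'
#' @param s Synaptic gating value in \[0, 1\].
#' @param v_pre Presynaptic membrane potential (mV).
#' @param cfg A [network_config()].
#' @param pop Presynaptic population: `"STN"` synapses use the fast
#'   excitatory kinetics, `"GPe"` the slow inhibitory ones.
#' @return `ds/dt` (ms^-1).
#' @export
synapse_rhs <- function(s, v_pre, cfg, pop = c("STN", "GPe")) {
  pop <- match.arg(pop)
  a <- if (pop == "STN") cfg$alpha else cfg$alpha_gpe
  b <- if (pop == "STN") cfg$beta else cfg$beta_gpe
  H <- sigmoid_activation(v_pre - cfg$theta_g, cfg$theta_gH, cfg$sigma_gH)
  a * H * (1 - s) - b * s
}

#' Sample per-cell heterogeneity
#'
#' Draws the Gaussian per-cell applied currents of the STN population and
#' the Gaussian per-cell calcium rates of the GPe population. Reproducible
#' for a fixed seed; the sampler does not disturb the caller's RNG state.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with numeric vectors `I_app_stn` and `eps_gpe`, length
#'   `cfg$N` each.
#' @export
sample_heterogeneity <- function(cfg, seed = cfg$seed) {
  if (cfg$I_app_sd < 0 || cfg$eps_sd < 0) stop("negative sd", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  list(
    I_app_stn = stats::rnorm(cfg$N, cfg$I_app_mean, cfg$I_app_sd),
    eps_gpe = stats::rnorm(cfg$N, cfg$eps_mean, cfg$eps_sd)
  )
}

# Save/restore .Random.seed around a seeded draw; returns the restore closure.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}
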