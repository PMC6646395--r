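#' Logistic steady-state activation
#'
#' Steady-state (in)activation curve `X_inf(v) = 1 / (1 + exp(-(v - theta)/sigma))`
#' used for every gating variable of the model. A positive `sigma` gives an
#' activation curve (increasing in `v`), a negative `sigma` an inactivation
#' curve.
#'
#' @param v Membrane potential (mV). Vectorised.
#' @param theta Half-activation voltage (mV).
#' @param sigma Slope factor (mV); must be nonzero.
#' @return Activation value(s) in (0, 1).
#' @examples
#' sigmoid_activation(-20, theta = -30, sigma = 10) # 1/(1 + exp(-1))
#' @export
sigmoid_activation <- function(v, theta, sigma) {
  if (!is.numeric(sigma) || any(sigma == 0)) {
    stop("`sigma` must be nonzero", call. = FALSE)
  }
  1 / (1 + exp(-(v - theta) / sigma))
}

#' Voltage-dependent gating time constant
#'
#' `tau_X(v) = tau0 + tau1 / (1 + exp(-(v - theta_tau)/sigma_tau))` (ms).
#' With `tau1 = 0` the time constant is voltage independent, which is how the
#' pallidal `r` gate is parameterised.
#'
#' @param v Membrane potential (mV). Vectorised.
#' @param tau0,tau1 Base and voltage-dependent increments (ms); both
#'   asymptotes `tau0` and `tau0 + tau1` must be positive.
#' @param theta_tau,sigma_tau Midpoint (mV) and slope (mV) of the logistic.
#' @return Time constant(s) in ms.
#' @export
voltage_time_constant <- function(v, tau0, tau1, theta_tau, sigma_tau) {
  if (tau0 <= 0 || tau0 + tau1 <= 0) {
    stop("time-constant asymptotes must be positive", call. = FALSE)
  }
  if (tau1 == 0) {
    return(rep_len(tau0, length(v)))
  }
  if (sigma_tau == 0) stop("`sigma_tau` must be nonzero", call. = FALSE)
  tau0 + tau1 / (1 + exp(-(v - theta_tau) / sigma_tau))
}

#' Low-threshold calcium inactivation coupling
#'
#' `b_inf(r) = 1/(1 + exp((r - theta_b)/sigma_b)) - 1/(1 + exp(-theta_b/sigma_b))`.
#' The constant second term makes `b_inf(0) = 0` exactly.
#'
#' @param r Value of the `r` gating variable. Vectorised.
#' @param theta_b,sigma_b Midpoint and slope (unitless); `sigma_b` nonzero.
#' @return Unitless coupling value.
#' @export
b_inf <- function(r, theta_b, sigma_b) {
  if (sigma_b == 0) stop("`sigma_b` must be nonzero", call. = FALSE)
  1 / (1 + exp((r - theta_b) / sigma_b)) - 1 / (1 + exp(-theta_b / sigma_b))
}

# Adopted single-compartment parameter sets for the subthalamic (STN) and
# pallidal (GPe) cell models (Terman-Rubin family). The reciprocally coupled
# network built from these cells is the standard pacemaker model of
# parkinsonian STN-GPe bursting. Every constant can be overridden.

#' Default STN cell parameters
#'
#' Named list of single-cell constants for the subthalamic neuron model:
#' conductances and reversals (nS/um^2, mV), calcium kinetics, gating
#' midpoints/slopes, voltage-dependent time constants and rate scales.
#' These are the published constants of the Terman-Rubin subthalamic cell,
#' shipped as the package's documented default set; the applied current
#' `I_app` defaults to the population mean used by the network model
#' (10 pA/um^2) and is resampled per cell by [sample_heterogeneity()].
#'
#' @param ... Named overrides for any constant, e.g. `stn_params(g_T = 0)`.
#' @return An object of class `cell_params`.
#' @export
stn_params <- function(...) {
  p <- list(
    pop = "STN", C_m = 1,
    g_L = 2.8, g_K = 45, g_Na = 37.5, g_T = 1.2, g_Ca = 0.5, g_AHP = 9,
    v_L = -65, v_K = -80, v_Na = 55, v_Ca = 140,
    eps = 3.75e-5, k_Ca = 22.5, k_1 = 15,
    I_app = 10,
    theta_n = -32, sigma_n = 8,
    theta_h = -39, sigma_h = -3.1,
    theta_r = -67, sigma_r = -2,
    theta_m = -30, sigma_m = 15,
    theta_s = -39, sigma_s = 8,
    theta_a = -63, sigma_a = 7.8,
    tau0_n = 1, tau1_n = 100, theta_tau_n = -80, sigma_tau_n = -26,
    tau0_h = 1, tau1_h = 500, theta_tau_h = -57, sigma_tau_h = -3,
    tau0_r = 7.1, tau1_r = 17.5, theta_tau_r = -68, sigma_tau_r = -2.2,
    phi_n = 0.75, phi_h = 0.75, phi_r = 0.5,
    theta_b = 0.25, sigma_b = -0.07
  )
  modify_params(p, ...)
}

#' Default GPe cell parameters
#'
#' Named list of single-cell constants for the external-pallidal neuron
#' model (see [stn_params()] for conventions). The pallidal `r` gate has a
#' constant time constant (`tau1_r = 0`) and the low-threshold calcium
#' current uses `r` directly rather than [b_inf()]. The calcium rate `eps`
#' defaults to the network model's population mean (0.0055 ms^-1) and is
#' resampled per cell by [sample_heterogeneity()]; the bias current `I_app`
#' places the cell in the bursting regime that supports the synchronized
#' low-beta network rhythm.
#'
#' @inheritParams stn_params
#' @return An object of class `cell_params`.
#' @export
gpe_params <- function(...) {
  p <- list(
    pop = "GPe", C_m = 1,
    g_L = 0.2, g_K = 30, g_Na = 120, g_T = 0.5, g_Ca = 0.1, g_AHP = 40,
    v_L = -55, v_K = -80, v_Na = 55, v_Ca = 120,
    eps = 0.0055, k_Ca = 1.5, k_1 = 30,
    I_app = 0.5,
    theta_n = -50, sigma_n = 14,
    theta_h = -58, sigma_h = -12,
    theta_r = -70, sigma_r = -2,
    theta_m = -37, sigma_m = 10,
    theta_s = -35, sigma_s = 2,
    theta_a = -57, sigma_a = 2,
    tau0_n = 0.05, tau1_n = 0.27, theta_tau_n = -40, sigma_tau_n = -12,
    tau0_h = 0.05, tau1_h = 0.27, theta_tau_h = -40, sigma_tau_h = -12,
    tau0_r = 30, tau1_r = 0, theta_tau_r = 0, sigma_tau_r = 1,
    phi_n = 0.05, phi_h = 0.05, phi_r = 1,
    theta_b = 0.4, sigma_b = -0.1
  )
  modify_params(p, ...)
}

modify_params <- function(p, ...) {
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown cell parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

validate_cell_params <- function(p) {
  if (!p$pop %in% c("STN", "GPe")) stop("unknown population tag", call. = FALSE)
  g <- unlist(p[c("g_L", "g_K", "g_Na", "g_T", "g_Ca", "g_AHP")])
  if (any(g < 0)) stop("conductances must be >= 0", call. = FALSE)
  if (p$C_m <= 0) stop("C_m must be > 0", call. = FALSE)
  sig <- unlist(p[grep("^sigma_", names(p))])
  if (any(sig == 0)) stop("sigma parameters must be nonzero", call. = FALSE)
  invisible(p)
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params: %s>\n", x$pop))
  flds <- x[setdiff(names(x), "pop")]
  cat(paste(sprintf("  %-12s %g", names(flds), unlist(flds)), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Initial neuron state
#'
#' @param v Membrane potential (mV).
#' @param Ca Intracellular calcium (model units, >= 0).
#' @param n,h,r Gating variables in \[0, 1\].
#' @return An object of class `neuron_state` (named numeric vector).
#' @export
neuron_state <- function(v = -62, Ca = 0.2, n = 0.1, h = 0.5, r = 0.1) {
  st <- c(v = v, Ca = Ca, n = n, h = h, r = r)
  if (any(!is.finite(st))) stop("non-finite state", call. = FALSE)
  if (Ca < 0 || any(c(n, h, r) < 0) || any(c(n, h, r) > 1)) {
    stop("Ca must be >= 0 and gating variables in [0, 1]", call. = FALSE)
  }
  structure(st, class = c("neuron_state", "numeric"))
}

#' Membrane currents of one model neuron
#'
#' Evaluates the six intrinsic currents (leak, delayed-rectifier potassium,
#' sodium, low-threshold calcium, high-threshold calcium,
#' calcium-activated afterhyperpolarisation) at a given state. The
#' low-threshold calcium current differs between populations:
#' `I_T = g_T a_inf^3 b_inf(r)^2 (v - v_Ca)` for STN and
#' `I_T = g_T a_inf^3 r (v - v_Ca)` for GPe.
#'
#' @param state A [neuron_state()].
#' @param params A [stn_params()] or [gpe_params()] object.
#' @return A tibble with one row per current (`current`, `value` in pA/um^2).
#' @export
membrane_currents <- function(state, params) {
  validate_cell_params(params)
  v <- state[["v"]]; Ca <- state[["Ca"]]
  n <- state[["n"]]; h <- state[["h"]]; r <- state[["r"]]
  m_inf <- sigmoid_activation(v, params$theta_m, params$sigma_m)
  s_inf <- sigmoid_activation(v, params$theta_s, params$sigma_s)
  a_inf <- sigmoid_activation(v, params$theta_a, params$sigma_a)
  I_L <- params$g_L * (v - params$v_L)
  I_K <- params$g_K * n^4 * (v - params$v_K)
  I_Na <- params$g_Na * m_inf^3 * h * (v - params$v_Na)
  I_Ca <- params$g_Ca * s_inf^2 * (v - params$v_Ca)
  I_AHP <- params$g_AHP * (v - params$v_K) * Ca / (Ca + params$k_1)
  I_T <- if (params$pop == "STN") {
    params$g_T * a_inf^3 * b_inf(r, params$theta_b, params$sigma_b)^2 *
      (v - params$v_Ca)
  } else {
    params$g_T * a_inf^3 * r * (v - params$v_Ca)
  }
  tibble::tibble(
    current = c("I_L", "I_K", "I_Na", "I_T", "I_Ca", "I_AHP"),
    value = c(I_L, I_K, I_Na, I_T, I_Ca, I_AHP)
  )
}

#' Single-cell right-hand side
#'
#' Time derivatives of the five-dimensional cell model:
#' `C_m v' = -I_L - I_K - I_Na - I_T - I_Ca - I_AHP - I_syn + I_app + I_stim`,
#' `Ca' = eps (-I_Ca - I_T - k_Ca Ca)`, and first-order gating kinetics
#' `X' = phi_X (X_inf(v) - X) / tau_X(v)` for `X` in `{n, h, r}`.
#'
#' @inheritParams membrane_currents
#' @param I_syn Synaptic current (pA/um^2).
#' @param I_stim Stimulation current (pA/um^2).
#' @return Named numeric vector `(v, Ca, n, h, r)` of derivatives.
#' @export
cell_rhs <- function(state, params, I_syn = 0, I_stim = 0) {
  if (any(!is.finite(unclass(state)))) stop("non-finite state", call. = FALSE)
  cur <- membrane_currents(state, params)
  I <- stats::setNames(cur$value, cur$current)
  v <- state[["v"]]; Ca <- state[["Ca"]]
  vdot <- (-I[["I_L"]] - I[["I_K"]] - I[["I_Na"]] - I[["I_T"]] -
             I[["I_Ca"]] - I[["I_AHP"]] - I_syn + params$I_app + I_stim) /
    params$C_m
  Cadot <- params$eps * (-I[["I_Ca"]] - I[["I_T"]] - params$k_Ca * Ca)
  gd <- function(X, nm) {
    Xinf <- sigmoid_activation(v, params[[paste0("theta_", nm)]],
                               params[[paste0("sigma_", nm)]])
    tau <- voltage_time_constant(v, params[[paste0("tau0_", nm)]],
                                 params[[paste0("tau1_", nm)]],
                                 params[[paste0("theta_tau_", nm)]],
                                 params[[paste0("sigma_tau_", nm)]])
    params[[paste0("phi_", nm)]] * (Xinf - X) / tau
  }
  c(v = unname(vdot), Ca = unname(Cadot),
    n = gd(state[["n"]], "n"), h = gd(state[["h"]], "h"),
    r = gd(state[["r"]], "r"))
}

#' Dump the full default parameter sets
#'
#' One row per constant and population, for audit and for the command-line
#' `dump-defaults` front-end.
#'
#' @return A tibble with columns `population`, `parameter`, `value`.
#' @export
dump_default_params <- function() {
  one <- function(p) {
    flds <- p[setdiff(names(p), "pop")]
    tibble::tibble(population = p$pop, parameter = names(flds),
                   value = unname(unlist(flds)))
  }
  dplyr::bind_rows(one(stn_params()), one(gpe_params()))
}
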