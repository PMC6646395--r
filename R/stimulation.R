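#' Charge-balanced biphasic pulse-train geometry
#'
#' Defines the high-frequency train of asymmetric charge-balanced pulses.
#' Each pulse starts with a short cathodic phase of width `PW` and relative
#' amplitude -`ratio`, an optional zero-current interphase gap `GW`, and a
#' long anodic recharging phase of width `ratio * PW` and relative
#' amplitude 1, so the two phases carry equal and opposite charge.
#'
#' @param F_hz Pulse rate (Hz). Default 130.
#' @param PW First-phase (cathodic) width (ms). Default 0.2.
#' @param GW Interphase gap width (ms, >= 0). Default 0.
#' @param ratio Phase-duration ratio (second phase lasts `ratio * PW`).
#'   Default 10.
#' @return An object of class `pulse_train_config`.
#' @export
pulse_train_config <- function(F_hz = 130, PW = 0.2, GW = 0, ratio = 10) {
  if (F_hz <= 0 || PW <= 0 || GW < 0 || ratio <= 0) {
    stop("require F_hz > 0, PW > 0, GW >= 0, ratio > 0", call. = FALSE)
  }
  period <- 1000 / F_hz
  if (PW + GW + ratio * PW > period) {
    warning(sprintf(
      "gap GW = %g ms exceeds the charge-balanced limit %.2f ms at F = %g Hz",
      GW, max(0, period - (ratio + 1) * PW), F_hz))
  }
  structure(list(F_hz = F_hz, PW = PW, GW = GW, ratio = ratio,
                 period = period),
            class = "pulse_train_config")
}

#' Maximal charge-balanced interphase gap
#'
#' Largest gap width for which the full recharging phase still fits into
#' the inter-pulse interval: `1000/F - (ratio + 1) * PW` ms. For the default
#' geometry (130 Hz, 0.2 ms, 1:10) this is 5.49 ms.
#'
#' @inheritParams pulse_train_config
#' @return Gap limit in ms (0 with a warning if the geometry is infeasible).
#' @export
max_charge_balanced_gap <- function(F_hz, PW, ratio = 10) {
  if (F_hz <= 0 || PW <= 0) stop("require F_hz > 0 and PW > 0", call. = FALSE)
  g <- 1000 / F_hz - (ratio + 1) * PW
  if (g < 0) {
    warning("pulse geometry infeasible: phases do not fit the period")
    g <- 0
  }
  g
}

#' Gap width at which pulses become monophasic
#'
#' For gaps larger than `1000/F - PW` ms the recharging phase no longer fits
#' at all and the emitted pulse is purely cathodic (7.49 ms for the default
#' geometry).
#'
#' @inheritParams pulse_train_config
#' @return Gap threshold in ms.
#' @export
monophasic_gap_threshold <- function(F_hz, PW) {
  if (F_hz <= 0 || PW <= 0) stop("require F_hz > 0 and PW > 0", call. = FALSE)
  1000 / F_hz - PW
}

#' Unit pulse waveform
#'
#' Piecewise-constant value of one biphasic pulse at offset `t_offset` after
#' the pulse onset: -`ratio` during the cathodic phase, 0 during the gap,
#' +1 during the recharging phase (truncated at the inter-pulse interval),
#' 0 otherwise.
#'
#' @param t_offset Time since pulse onset (ms), in `[0, 1000/F)`. Vectorised.
#' @param cfg A [pulse_train_config()].
#' @return Waveform value(s) in `{-ratio, 0, 1}`.
#' @export
pulse_shape <- function(t_offset, cfg) {
  if (any(t_offset < 0) || any(t_offset >= cfg$period)) {
    stop("t_offset must lie in [0, 1000/F)", call. = FALSE)
  }
  p1 <- cfg$PW
  p2 <- cfg$PW + cfg$GW
  p3 <- (cfg$ratio + 1) * cfg$PW + cfg$GW
  out <- numeric(length(t_offset))
  out[t_offset < p1] <- -cfg$ratio
  out[t_offset >= p2 & t_offset < p3] <- 1
  out
}

#' Stimulation current of one pulse
#'
#' `I_stim(t) = A(t_n) * pulse_shape(t - t_n)`: the modulating amplitude is
#' sampled once at the pulse onset `t_n` and held for the whole pulse.
#'
#' @param t Time (ms). Vectorised.
#' @param amplitude Amplitude `A(t_n)` frozen at the current pulse onset.
#' @param cfg A [pulse_train_config()].
#' @param t_onset Onset time `t_n` of the current pulse (ms). Default 0.
#' @return Stimulation current (pA/um^2).
#' @export
stimulation_current <- function(t, amplitude, cfg, t_onset = 0) {
  amplitude * pulse_shape(t - t_onset, cfg)
}

#' Linear delayed-feedback amplitude
#'
#' `S(t) = K * (x(t - tau) - x(t))` computed from a sampled history of the
#' filtered LFP. The history is zero-padded before its first sample.
#'
#' @param x_history Numeric vector of filtered-LFP samples on a uniform
#'   grid, most recent sample last.
#' @param dt Sampling step of the history (ms).
#' @param K Feedback gain (dimensionless, >= 0).
#' @param tau Feedback delay (ms, >= 0); looked up as the nearest sample.
#' @return `S(t)` evaluated at the time of the last history sample.
#' @export
ldf_amplitude <- function(x_history, dt, K, tau) {
  if (K < 0 || tau < 0) stop("require K >= 0 and tau >= 0", call. = FALSE)
  n <- length(x_history)
  if (n == 0) stop("empty history", call. = FALSE)
  lag <- as.integer(round(tau / dt))
  x_now <- x_history[n]
  x_del <- if (lag >= n) 0 else x_history[n - lag]
  K * (x_del - x_now)
}

#' Controller configuration
#'
#' Stimulation mode and closed-loop parameters. Modes: `"cDBS"` (continuous
#' pulse train at constant intensity `K`), `"aDBS"` (the same train gated
#' on/off by LFP thresholds), `"cpLDF"` (train amplitude modulated by the
#' delayed-feedback signal `S(t) = K (x(t - tau) - x(t))`) and `"apLDF"`
#' (gated delayed feedback).
#'
#' @param mode One of `"cDBS"`, `"aDBS"`, `"cpLDF"`, `"apLDF"`.
#' @param K Stimulation intensity / feedback gain (>= 0).
#' @param tau Feedback delay (ms), LDF modes only. Default 60.
#' @param Th_on,Th_off Hysteresis thresholds on local maxima of the filtered
#'   LFP (adaptive modes); require `Th_on >= Th_off`.
#' @param T_ramp Ramp-up duration (ms) over which the effective intensity
#'   grows linearly from 0 to `K` after stimulation onset; in \[0, 2000\].
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(mode = c("cDBS", "aDBS", "cpLDF", "apLDF"),
                              K = 2, tau = 60,
                              Th_on = 0.016, Th_off = 0.008,
                              T_ramp = 0) {
  mode <- match.arg(mode)
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (Th_on < Th_off) stop("require Th_on >= Th_off", call. = FALSE)
  if (T_ramp < 0 || T_ramp > 2000) stop("T_ramp must be in [0, 2000] ms",
                                        call. = FALSE)
  structure(list(mode = mode, K = K, tau = tau,
                 Th_on = Th_on, Th_off = Th_off, T_ramp = T_ramp),
            class = "controller_config")
}

#' On/off gate update at a filtered-LFP local maximum
#'
#' The demand-controlled gate toggles only when a local maximum of the
#' filtered LFP is detected: off -> on when the maximum exceeds `Th_on`,
#' on -> off when it falls below `Th_off`; otherwise the state is kept
#' (hysteresis for `Th_on > Th_off`).
#'
#' @param on Logical, current gate state.
#' @param local_max_value Value of the detected local maximum.
#' @param Th_on,Th_off Thresholds with `Th_on >= Th_off`.
#' @return Logical, updated gate state.
#' @export
gate_update <- function(on, local_max_value, Th_on, Th_off) {
  if (Th_on < Th_off) stop("require Th_on >= Th_off", call. = FALSE)
  if (!on && local_max_value > Th_on) return(TRUE)
  if (on && local_max_value < Th_off) return(FALSE)
  on
}

#' Linear ramp factor
#'
#' Multiplier that ramps the stimulation intensity linearly from 0 to 1
#' over `T_ramp` ms after stimulation onset; identically 1 for
#' `T_ramp = 0`.
#'
#' @param t_since_onset Time since stimulation onset (ms, >= 0). Vectorised.
#' @param T_ramp Ramp duration (ms).
#' @export
ramp_factor <- function(t_since_onset, T_ramp) {
  if (any(t_since_onset < 0)) stop("t_since_onset must be >= 0", call. = FALSE)
  if (T_ramp <= 0) return(rep_len(1, length(t_since_onset)))
  pmin(1, t_since_onset / T_ramp)
}
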