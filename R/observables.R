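#' Raw LFP from STN synaptic variables
#'
#' The model LFP is the population mean of the STN synaptic gating
#' variables, `LFP(t) = mean(s_j)`.
#'
#' @param s_stn Numeric vector of STN synaptic variables.
#' @return LFP value (unitless).
#' @export
compute_lfp <- function(s_stn) {
  if (length(s_stn) == 0) stop("empty synaptic vector", call. = FALSE)
  mean(s_stn)
}

#' Resonant LFP filter
#'
#' Online second-order filter `u'' + alpha_d u' + omega^2 u = k_f LFP(t)`,
#' a damped oscillator tuned to the mean LFP frequency. Its output is
#' `x = u'`, which at resonance has zero phase shift relative to the input
#' and, for `k_f = alpha_d`, unit gain. The default centre period is the
#' stimulation-free mean LFP period of the synchronized network, T = 103 ms.
#'
#' @param T_ms Centre period (ms); `omega = 2*pi/T_ms`. Default 103.
#' @param alpha_d Damping rate (ms^-1). Default 0.008.
#' @param k_f Input scaling (ms^-2 per LFP unit). Default 0.008.
#' @param u,udot Initial filter state. Default 0.
#' @return An object of class `filter_state` with the state and constants.
#' @export
lfp_filter <- function(T_ms = 103, alpha_d = 0.008, k_f = 0.008,
                       u = 0, udot = 0) {
  if (T_ms <= 0 || alpha_d <= 0) stop("require T_ms > 0, alpha_d > 0",
                                      call. = FALSE)
  structure(list(T_ms = T_ms, omega = 2 * pi / T_ms,
                 alpha_d = alpha_d, k_f = k_f, u = u, udot = udot),
            class = "filter_state")
}

# Exact one-step propagator of the damped oscillator under a zero-order-hold
# input: state (u, udot) advances by expm(A dt) with A = [[0,1],[-w^2,-a]],
# plus the particular solution for constant input. Unconditionally stable.
filter_propagator <- function(fs, dt) {
  a <- fs$alpha_d; w2 <- fs$omega^2
  disc <- a^2 / 4 - w2
  # underdamped for all sensible settings (alpha_d/2 << omega)
  wd <- sqrt(abs(disc))
  e <- exp(-a / 2 * dt)
  if (disc < 0) {
    cwd <- cos(wd * dt); swd <- sin(wd * dt)
    E11 <- e * (cwd + a / (2 * wd) * swd)
    E12 <- e * swd / wd
    E21 <- -w2 * e * swd / wd
    E22 <- e * (cwd - a / (2 * wd) * swd)
  } else {
    cwd <- cosh(wd * dt); swd <- sinh(wd * dt)
    E11 <- e * (cwd + a / (2 * wd) * swd)
    E12 <- e * swd / wd
    E21 <- -w2 * e * swd / wd
    E22 <- e * (cwd - a / (2 * wd) * swd)
  }
  E <- matrix(c(E11, E21, E12, E22), 2, 2)
  # particular response to unit constant input: x_p = A^-1 (E - I) b, b = (0,1)
  Ainv <- matrix(c(-a / w2, 1, -1 / w2, 0), 2, 2) # inverse of [[0,1],[-w2,-a]]
  B <- Ainv %*% (E - diag(2)) %*% c(0, 1)
  list(E = E, B = as.numeric(B))
}

#' Advance the LFP filter by one step
#'
#' Exact zero-order-hold update of the damped-oscillator filter over `dt`
#' with the input held at `lfp`.
#'
#' @param fs A [lfp_filter()] state.
#' @param lfp Raw LFP input over the step.
#' @param dt Step (ms); must be well below the filter period.
#' @return Updated `filter_state`; the filtered output is `$udot`.
#' @export
filter_step <- function(fs, lfp, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  pr <- filter_propagator(fs, dt)
  st <- pr$E %*% c(fs$u, fs$udot) + pr$B * (fs$k_f * lfp)
  fs$u <- st[1]; fs$udot <- st[2]
  fs
}

#' Run the LFP filter over a sampled trace
#'
#' Convenience wrapper around the exact per-step propagator for a whole
#' uniformly sampled input signal.
#'
#' @param lfp Numeric vector of raw LFP samples.
#' @param dt Sampling step (ms).
#' @param fs A [lfp_filter()] state (initial condition).
#' @return Numeric vector of filtered-LFP samples `x = udot`, same length.
#' @export
filter_trace <- function(lfp, dt, fs = lfp_filter()) {
  pr <- filter_propagator(fs, dt)
  filter_trace_cpp(lfp, pr$E, pr$B, fs$k_f, fs$u, fs$udot)
}

#' Detect burst onsets from a spike train
#'
#' A spike opens a burst iff it is the first spike of the train or follows
#' its predecessor by more than `isi_gap` ms.
#'
#' @param spike_times Sorted numeric vector of spike times (ms).
#' @param isi_gap Inter-spike gap (ms) separating bursts. Default 25.
#' @return Numeric vector of burst-onset times.
#' @export
detect_burst_onsets <- function(spike_times, isi_gap = 25) {
  if (length(spike_times) == 0) return(numeric(0))
  if (is.unsorted(spike_times)) stop("spike times must be sorted", call. = FALSE)
  opens <- c(TRUE, diff(spike_times) > isi_gap)
  spike_times[opens]
}

#' Burst-phase of one neuron
#'
#' Piecewise-linear phase anchored at the burst onsets: `psi(t_n) = 2*pi*n`
#' and linear interpolation in between. Undefined (NA) outside
#' `[first onset, last onset]`.
#'
#' @param onsets Sorted numeric vector of burst-onset times (ms).
#' @param t Query time(s) (ms). Vectorised.
#' @return Phase(s) in radians, NA where undefined.
#' @export
neuron_phase <- function(onsets, t) {
  if (length(onsets) < 2) return(rep(NA_real_, length(t)))
  out <- stats::approx(onsets, 2 * pi * (seq_along(onsets) - 1), xout = t,
                       method = "linear", rule = 1)$y
  out
}

#' Kuramoto order parameter
#'
#' `R = |mean(exp(i*psi))|` over the supplied phases; NA phases (neurons
#' whose burst phase is undefined at that time) are dropped.
#'
#' @param phases Numeric vector of phases (radians).
#' @return `R` in \[0, 1\]; NA if no phase is defined.
#' @export
order_parameter <- function(phases) {
  if (length(phases) == 0) stop("empty phase vector", call. = FALSE)
  phases <- phases[!is.na(phases)]
  if (length(phases) == 0) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Order-parameter trace from a spike raster
#'
#' Computes per-neuron burst onsets, the piecewise-linear burst phases and
#' the Kuramoto order parameter on a uniform time grid.
#'
#' @param spikes List of per-neuron sorted spike-time vectors (ms).
#' @param times Numeric vector of query times (ms).
#' @param isi_gap Burst-grouping gap (ms). Default 25.
#' @return Numeric vector `R(t)` over `times` (NA where no neuron has a
#'   defined phase).
#' @export
order_parameter_trace <- function(spikes, times, isi_gap = 25) {
  re <- numeric(length(times)); im <- numeric(length(times))
  cnt <- integer(length(times))
  for (sp in spikes) {
    on <- detect_burst_onsets(sp, isi_gap)
    ps <- neuron_phase(on, times)
    ok <- !is.na(ps)
    re[ok] <- re[ok] + cos(ps[ok])
    im[ok] <- im[ok] + sin(ps[ok])
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- rep(NA_real_, length(times))
  nz <- cnt > 0L
  out[nz] <- sqrt(re[nz]^2 + im[nz]^2) / cnt[nz]
  out
}

#' Fraction of stimulation-on time
#'
#' Share of samples in the analysis window during which the adaptive gate
#' was on. Continuous modes give 1 after the ramp.
#'
#' @param gate Logical/0-1 vector of gate samples.
#' @param window Optional integer index range (two values) into `gate`;
#'   default is the full trace.
#' @return `T_on` in \[0, 1\].
#' @export
stimulation_time_fraction <- function(gate, window = NULL) {
  if (!is.null(window)) gate <- gate[window[1]:window[2]]
  if (length(gate) == 0) stop("empty window", call. = FALSE)
  mean(as.numeric(gate))
}

#' Administered stimulation
#'
#' Time-averaged absolute modulation signal `<|S|>` over the analysis
#' window. For the gated high-frequency modes `S(t) = K` while on and 0
#' while off, so `<|S|> = K * T_on` exactly.
#'
#' @param S Numeric vector of modulation-signal samples (0 while the gate
#'   is off).
#' @param window Optional integer index range (two values) into `S`.
#' @return `<|S|>` (same units as `S`).
#' @export
administered_stimulation <- function(S, window = NULL) {
  if (!is.null(window)) S <- S[window[1]:window[2]]
  if (length(S) == 0) return(0)
  mean(abs(S))
}

#' Mean inter-peak period of a trace
#'
#' Estimates the mean oscillation period as the average spacing of local
#' maxima of the (optionally lightly smoothed) signal; used to calibrate
#' the filter centre frequency from a stimulation-free run.
#'
#' @param x Numeric signal samples.
#' @param dt Sampling step (ms).
#' @param smooth_ms Width (ms) of the centred moving average applied before
#'   peak detection. Default 10.
#' @param min_period Minimal admissible spacing between counted peaks (ms);
#'   closer peaks are pruned greedily. Guards against intra-burst ripples.
#'   Default 20.
#' @return Mean period (ms), or NA with fewer than two peaks.
#' @export
mean_peak_period <- function(x, dt, smooth_ms = 10, min_period = 20) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  w <- max(1L, as.integer(round(smooth_ms / dt)))
  if (w > 1L && n > w) {
    x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  }
  ok <- which(!is.na(x))
  x <- x[ok]
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(pk) < 2) return(NA_real_)
  tt <- ok[pk] * dt
  keep <- tt[1]
  for (t in tt[-1]) if (t - keep[length(keep)] >= min_period) keep <- c(keep, t)
  if (length(keep) < 2) return(NA_real_)
  mean(diff(keep))
}

#' Mean LFP envelope period via autocorrelation
#'
#' Estimates the period of the collective LFP rhythm as the lag of the
#' first autocorrelation peak of the lightly smoothed raw LFP. Used to
#' calibrate the centre frequency of the resonant filter from a
#' stimulation-free run.
#'
#' @param lfp Numeric vector of raw LFP samples.
#' @param dt Sampling step (ms).
#' @param smooth_ms Moving-average width (ms) applied before the
#'   autocorrelation, suppressing intra-burst ripple. Default 50.
#' @param max_lag_ms Largest lag searched (ms). Default 2000.
#' @param min_corr Minimal autocorrelation for an acceptable peak.
#'   Default 0.1.
#' @return Estimated period (ms), or NA if no acceptable peak exists.
#' @export
lfp_envelope_period <- function(lfp, dt, smooth_ms = 50, max_lag_ms = 2000,
                                min_corr = 0.1) {
  w <- max(1L, as.integer(round(smooth_ms / dt)))
  if (w > 1L && length(lfp) > w) {
    sm <- as.numeric(stats::filter(lfp, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- mean(lfp)
  } else {
    sm <- lfp
  }
  lag_max <- min(length(sm) - 2, as.integer(round(max_lag_ms / dt)))
  if (lag_max < 3) return(NA_real_)
  a <- stats::acf(sm, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  n <- length(a)
  pk <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  pk <- pk[a[pk] > min_corr]
  if (!length(pk)) return(NA_real_)
  (pk[1] - 1) * dt
}
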