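#' Ground-truth generative parameters for one PFNa cell
#'
#' Parameters of the forward model from which synthetic membrane-potential
#' traces and imaging matrices are generated, and which the fitting module
#' recovers. The subthreshold mean is
#' `Vm = a0 + aH cos(H) + aW cos(W + s 45)` with `H` the heading relative to
#' the cell's preferred direction, `W` the egocentric airflow direction
#' (term active only during puffs) and `s = +1` for left-bridge, `-1` for
#' right-bridge cells. Sodium spikes occur at Poisson rate
#' `[bH cos(H) + bW cos(W + s 45)]+^2` and, below the calcium-spike
#' threshold, a 2-6 Hz oscillation is present whose band power is
#' `c0 + [cH cos(H) + cW cos(W + s 45)]-^2` (negative rectification).
#'
#' The two spike thresholds (`theta_na`, `theta_ca`) and the gain and noise
#' defaults are package choices, documented in the methods vignette; they are
#' not measured values.
#'
#' @param side `"left"` or `"right"` bridge population.
#' @param preferred_heading Preferred heading in degrees.
#' @param a0,aH,aW Vm model parameters (mV); `aH, aW >= 0`.
#' @param bH,bW Sodium-spike rate amplitudes (sqrt(spikes/s)); non-negative.
#' @param c0,cH,cW Oscillation band-power parameters (mV^2); `cH, cW >= 0`.
#' @param theta_na,theta_ca Sodium / calcium spike thresholds (mV),
#'   `theta_ca <= theta_na`.
#' @param vm_noise_sd Colored Vm noise SD (mV).
#' @param osc_freq Calcium-spike oscillation frequency in Hz, within `[2, 6]`.
#' @param ca_tau Calcium-indicator decay time constant (s).
#' @param frame_rate Imaging frame rate (Hz).
#' @param imaging_noise_sd Gaussian imaging noise SD (signal units).
#' @param k_na,k_ca Calcium-drive gains of the sodium- and calcium-spike
#'   pathways; their ratio `k_na / k_ca` is the matched decoder conversion
#'   factor (defaults give 0.2).
#' @return A one-row tibble of class `ground_truth_params`.
#' @export
ground_truth_params <- function(side = "right", preferred_heading = 0,
                                a0 = -64, aH = 7, aW = 5,
                                bH = 4, bW = 3,
                                c0 = 0.5, cH = 2, cW = 1.5,
                                theta_na = -57, theta_ca = -70,
                                vm_noise_sd = 1.5, osc_freq = 4,
                                ca_tau = 1.0, frame_rate = 8,
                                imaging_noise_sd = 0.05,
                                k_na = 1, k_ca = 5) {
  side <- match.arg(side, c("left", "right"))
  if (any(c(aH, aW, bH, bW, cH, cW) < 0)) {
    rlang::abort("aH, aW, bH, bW, cH, cW must be non-negative.")
  }
  if (theta_ca > theta_na) rlang::abort("`theta_ca` must be <= `theta_na`.")
  if (osc_freq < 2 || osc_freq > 6) rlang::abort("`osc_freq` must lie in [2, 6] Hz.")
  out <- tibble::tibble(
    side = side, preferred_heading = wrap_deg(preferred_heading),
    a0 = a0, aH = aH, aW = aW, bH = bH, bW = bW,
    c0 = c0, cH = cH, cW = cW,
    theta_na = theta_na, theta_ca = theta_ca,
    vm_noise_sd = vm_noise_sd, osc_freq = osc_freq, ca_tau = ca_tau,
    frame_rate = frame_rate, imaging_noise_sd = imaging_noise_sd,
    k_na = k_na, k_ca = k_ca
  )
  class(out) <- c("ground_truth_params", class(out))
  out
}

# +45 for left-bridge cells, -45 for right-bridge cells
airflow_shift_deg <- function(side) ifelse(side == "left", 45, -45)

#' Forward-model response surfaces
#'
#' Evaluate the three generative response models on (H, W) in degrees:
#' the sum-of-sinusoids membrane potential, the positively rectified
#' quadratic sodium-spike rate, and the negatively rectified quadratic
#' oscillation band power. `H` is heading relative to the preferred
#' direction; `W` the egocentric airflow direction. With `airflow_on =
#' FALSE` the airflow term is zero (no puff).
#'
#' @param H,W Angles in degrees (recycled against each other).
#' @param params A [ground_truth_params()] row (or anything with the needed
#'   columns).
#' @param airflow_on Logical (scalar or vector): is a puff active?
#' @return Numeric vector of responses.
#' @name model_surfaces
NULL

#' @rdname model_surfaces
#' @export
vm_model <- function(H, W, params, airflow_on = TRUE) {
  s <- airflow_shift_deg(params$side)
  params$a0 + params$aH * cos(deg2rad(H)) +
    params$aW * cos(deg2rad(W + s)) * as.numeric(airflow_on)
}

#' @rdname model_surfaces
#' @export
rate_model <- function(H, W, params, airflow_on = TRUE) {
  s <- airflow_shift_deg(params$side)
  u <- params$bH * cos(deg2rad(H)) +
    params$bW * cos(deg2rad(W + s)) * as.numeric(airflow_on)
  pmax(u, 0)^2
}

#' @rdname model_surfaces
#' @export
osc_model <- function(H, W, params, airflow_on = TRUE) {
  s <- airflow_shift_deg(params$side)
  u <- params$cH * cos(deg2rad(H)) +
    params$cW * cos(deg2rad(W + s)) * as.numeric(airflow_on)
  params$c0 + pmin(u, 0)^2
}

# per-sample egocentric airflow direction (NA outside puffs) and puff
# indicator, on an arbitrary time grid
airflow_at <- function(t, trials) {
  W <- rep(NA_real_, length(t))
  on <- logical(length(t))
  if (!is.null(trials) && nrow(trials) > 0) {
    ord <- order(trials$onset_time)
    onset <- trials$onset_time[ord]
    idx <- findInterval(t, onset)
    inside <- idx >= 1 &
      t < onset[pmax(idx, 1)] + trials$duration[ord][pmax(idx, 1)]
    W[inside] <- trials$airflow_direction[ord][idx[inside]]
    on[inside] <- TRUE
  }
  list(W = W, on = on)
}

#' Simulate a 10 kHz membrane-potential trace from the forward model
#'
#' Generates the subthreshold mean from the sum-of-sinusoids model, inserts
#' sodium spikes (2 ms biphasic somatic waveforms, ~3 mV) at Poisson times
#' with the rectified-quadratic rate, adds the hyperpolarization-gated
#' oscillation at `osc_freq` whose variance equals the oscillation model's
#' band power, and adds colored (AR(1), ~20 ms) noise of SD `vm_noise_sd`.
#'
#' @param truth A [ground_truth_params()] row.
#' @param behavior A heading trajectory from [make_heading_trajectory()]
#'   (uniform grid starting at 0 s).
#' @param trials Protocol tibble from [make_protocol()]; every trial window
#'   must lie inside the behavior trace.
#' @param seed Integer seed.
#' @param fs Output sampling rate (default 10000 Hz).
#' @return An [ephys_trace()] with the trial annotations attached and the
#'   true spike times stored as attribute `"true_spike_times"`.
#' @export
simulate_vm_trace <- function(truth, behavior, trials = NULL, seed = 1,
                              fs = 10000) {
  stopifnot(is.data.frame(behavior), all(c("t", "heading") %in% names(behavior)))
  duration <- nrow(behavior) / behavior_fs(behavior)
  if (!is.null(trials) && nrow(trials) > 0 &&
      max(trials$onset_time + trials$duration) > duration) {
    rlang::abort("every trial window must lie inside the behavior trace.")
  }
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  # sample-and-hold the 80 Hz heading onto the 10 kHz grid
  idx <- pmin(floor(t * behavior_fs(behavior)) + 1, nrow(behavior))
  H <- circ_diff(behavior$heading[idx], truth$preferred_heading)
  air <- airflow_at(t, trials)
  Wv <- ifelse(air$on, air$W, 0)

  mean_vm <- vm_model(H, Wv, truth, airflow_on = air$on)

  local_seed(seed, {
    # sodium spikes: Poisson thinning on the 10 kHz grid
    rate <- rate_model(H, Wv, truth, airflow_on = air$on)
    spike_idx <- which(stats::runif(n) < rate / fs)
    vm <- mean_vm
    if (length(spike_idx) > 0) {
      template <- sodium_spike_template(fs)
      for (k in spike_idx) {
        j <- k:min(k + length(template) - 1, n)
        vm[j] <- vm[j] + template[seq_along(j)]
      }
    }
    # hyperpolarization-gated oscillation with model band power
    p <- osc_model(H, Wv, truth, airflow_on = air$on)
    gate <- as.numeric(mean_vm < truth$theta_ca)
    if (any(gate > 0)) {
      env <- smooth_gate(gate, fs, ramp_s = 0.1)
      phi0 <- stats::runif(1, 0, 2 * pi)
      vm <- vm + env * sqrt(2 * p) * sin(2 * pi * truth$osc_freq * t + phi0)
    }
    # colored noise: AR(1) with ~20 ms correlation time
    if (truth$vm_noise_sd > 0) {
      rho <- exp(-1 / (0.02 * fs))
      eps <- stats::rnorm(n)
      noise <- as.numeric(stats::filter(eps, rho, method = "recursive"))
      noise <- noise * truth$vm_noise_sd / stats::sd(noise)
      vm <- vm + noise
    }
    out <- ephys_trace(vm, fs = fs, trials = trials)
    attr(out, "true_spike_times") <- (spike_idx - 1) / fs
    out
  })
}

behavior_fs <- function(behavior) {
  if (nrow(behavior) < 2) return(80)
  1 / (behavior$t[2] - behavior$t[1])
}

# 2 ms biphasic somatic spike waveform, ~3 mV peak
sodium_spike_template <- function(fs) {
  n_half <- max(round(0.001 * fs), 1)
  c(3 * sin(pi * seq_len(n_half) / n_half),
    -1 * sin(pi * seq_len(n_half) / n_half))
}

# moving-average smoothing of a 0/1 gate -> on/off envelope with soft ramps
# (cumsum running mean; O(n) for the multi-million-sample 10 kHz traces)
smooth_gate <- function(gate, fs, ramp_s = 0.1) {
  k <- max(as.integer(round(ramp_s * fs)), 1L)
  half <- k %/% 2L
  cs <- cumsum(c(0, gate))
  n <- length(gate)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
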