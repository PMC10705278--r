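#' Condition a raw membrane-potential trace
#'
#' Downsamples the native 10 kHz trace to 1 kHz (block averaging) and applies
#' a 40 ms running-median filter, which removes the brief sodium-spike
#' waveforms and leaves the subthreshold membrane potential.
#'
#' @param trace An [ephys_trace()] at its native rate.
#' @param out_fs Output rate (default 1000 Hz).
#' @param kernel_s Median-filter kernel width in seconds (default 0.04).
#' @return A 1 kHz [ephys_trace()] carrying the same annotations.
#' @export
condition_vm <- function(trace, out_fs = 1000, kernel_s = 0.04) {
  stopifnot(inherits(trace, "ephys_trace"))
  dec <- trace$fs / out_fs
  if (dec >= 1) {
    dec <- as.integer(round(dec))
    n <- (length(trace$vm) %/% dec) * dec
    vm <- colMeans(matrix(trace$vm[seq_len(n)], nrow = dec))
  } else {
    vm <- trace$vm
    out_fs <- trace$fs
  }
  k <- as.integer(round(kernel_s * out_fs))
  if (k %% 2 == 0) k <- k + 1L
  if (length(vm) < k) rlang::abort("trace shorter than one median-filter kernel.")
  vm <- as.numeric(stats::runmed(vm, k, endrule = "median"))
  ephys_trace(vm, fs = out_fs, t0 = trace$t0, trials = trace$trials)
}

# squared magnitude response of the 150-1000 Hz bandpass built from an
# order-4 analog Bessel low-pass prototype (8 poles after the bandpass
# transform), evaluated at frequencies f (Hz)
bessel_bp_mag2 <- function(f, f_lo = 150, f_hi = 1000) {
  # reverse Bessel polynomial theta_4(s) = s^4 + 10 s^3 + 45 s^2 + 105 s + 105,
  # frequency-normalized so |H| = 1/sqrt(2) at s = i
  poles <- polyroot(c(105, 105, 45, 10, 1))
  w3db <- 2.1139  # -3 dB frequency of the order-4 prototype
  poles <- poles * w3db
  w0 <- 2 * pi * sqrt(f_lo * f_hi)
  bw <- 2 * pi * (f_hi - f_lo)
  s <- 2i * pi * f
  # low-pass prototype evaluated at the band-pass-transformed variable
  u <- (s^2 + w0^2) / (bw * s)
  u[s == 0] <- Inf
  h <- rep(1 + 0i, length(f))
  for (p in poles) h <- h * (-p) / (u - p)
  m2 <- Mod(h)^2
  m2[!is.finite(m2)] <- 0
  m2
}

# zero-phase band-pass: multiply the FFT by the squared Bessel magnitude
# response (equivalent to forward-backward filtering, with no edge
# transients); used for spike-band isolation
bessel_bandpass <- function(x, fs, f_lo = 150, f_hi = 1000) {
  n <- length(x)
  nf <- stats::nextn(n, 2)
  X <- stats::fft(c(x - mean(x), rep(0, nf - n)))
  f <- c(seq(0, nf / 2), seq(-nf / 2 + 1, -1)) * fs / nf
  H2 <- bessel_bp_mag2(abs(f), f_lo, f_hi)
  Re(stats::fft(X * H2, inverse = TRUE))[seq_len(n)] / nf
}

#' Detect sodium spikes in a raw trace
#'
#' Band-pass filters the native-rate trace in the 150-1000 Hz spike band
#' (zero-phase application of an 8-pole Bessel band-pass response), finds
#' upward crossings of a high threshold, and rejects events closer than
#' 6.66 ms to the previously kept event.
#'
#' The threshold is set per trace as `threshold_k` robust standard
#' deviations (1.4826 MAD) of the band-passed trace unless an absolute
#' `threshold` is given.
#'
#' @param trace An [ephys_trace()] at its native rate.
#' @param threshold_k Threshold in robust SDs of the band-passed trace
#'   (default 4).
#' @param threshold Optional absolute threshold (mV on the filtered trace),
#'   overriding `threshold_k`.
#' @param refractory_s Minimum inter-event interval (default 0.00666 s).
#' @param band Numeric length-2 pass band in Hz.
#' @return Tibble with one column `spike_time` (s), strictly increasing; the
#'   threshold used is stored in attribute `"threshold"`.
#' @export
detect_sodium_spikes <- function(trace, threshold_k = 4, threshold = NULL,
                                 refractory_s = 1 / 150,
                                 band = c(150, 1000)) {
  stopifnot(inherits(trace, "ephys_trace"))
  bp <- bessel_bandpass(trace$vm, trace$fs, band[1], band[2])
  if (is.null(threshold)) {
    threshold <- threshold_k * stats::mad(bp)
  }
  up <- which(bp[-1] > threshold & bp[-length(bp)] <= threshold) + 1L
  keep <- numeric(0)
  if (length(up) > 0) {
    refr <- refractory_s * trace$fs
    last <- -Inf
    keep <- up[vapply(up, function(i) {
      ok <- (i - last) >= refr
      if (ok) last <<- i
      ok
    }, logical(1))]
  }
  out <- tibble::tibble(spike_time = trace$t0 + (keep - 1) / trace$fs)
  attr(out, "threshold") <- threshold
  out
}

#' Spike rate by Hann-window convolution
#'
#' Converts spike times to a continuous rate by convolving the spike point
#' process with a unit-area, 1-second-wide Hann window.
#'
#' @param spikes Tibble with a `spike_time` column (or a numeric vector).
#' @param t_grid Uniform output time grid (s).
#' @param width_s Kernel width in seconds (default 1).
#' @return Tibble `t`, `rate` (spikes/s).
#' @export
spike_rate <- function(spikes, t_grid, width_s = 1) {
  st <- if (is.data.frame(spikes)) spikes$spike_time else as.numeric(spikes)
  dt <- t_grid[2] - t_grid[1]
  counts <- numeric(length(t_grid))
  if (length(st) > 0) {
    b <- as.integer(round((st - t_grid[1]) / dt)) + 1L
    b <- b[b >= 1 & b <= length(t_grid)]
    counts <- tabulate(b, nbins = length(t_grid))
  }
  L <- as.integer(round(width_s / dt)) + 1L
  if (L %% 2 == 0) L <- L + 1L
  h <- signal::hanning(L)
  h <- h / (sum(h) * dt)           # unit area in time -> output in spikes/s
  r <- as.numeric(stats::filter(counts, h, sides = 2))
  r[is.na(r)] <- 0
  tibble::tibble(t = t_grid, rate = r)
}

# Hann-tapered sliding power spectra; returns window-center times, the
# frequency axis and the power matrix (windows x freqs, one-sided density)
sliding_psd <- function(x, fs, window_s, step_s) {
  L <- as.integer(round(window_s * fs))
  step <- max(as.integer(round(step_s * fs)), 1L)
  if (length(x) < L) rlang::abort("trace shorter than one spectral window.")
  w <- signal::hanning(L)
  starts <- seq(1, length(x) - L + 1, by = step)
  freqs <- (0:(L %/% 2)) * fs / L
  P <- matrix(0, length(starts), length(freqs))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + L - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_along(freqs)]
    p <- (Mod(X)^2) * 2 / (fs * sum(w^2))
    p[1] <- p[1] / 2
    if (L %% 2 == 0) p[length(p)] <- p[length(p)] / 2
    P[i, ] <- p
  }
  list(t = (starts - 1) / fs + L / (2 * fs), freq = freqs, power = P)
}

#' Band power of the 2-6 Hz calcium-spike oscillation
#'
#' Downsamples the trace to 100 Hz and computes a sliding Hann-tapered power
#' spectrum (4 s windows stepped by 20 ms); the band power of each window is
#' the mean spectral power over 2-6 Hz, timestamped at the window center.
#'
#' @param trace An [ephys_trace()] (any rate >= 100 Hz).
#' @param band Frequency band in Hz (default `c(2, 6)`).
#' @param window_s,step_s Spectrogram window and step (default 4 s, 0.02 s).
#' @return Tibble `t` (s, window centers), `band_power` (mV^2/Hz units,
#'   non-negative).
#' @export
band_power_2_6 <- function(trace, band = c(2, 6), window_s = 4, step_s = 0.02) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace_duration(trace) < window_s) {
    rlang::abort("trace must be at least one spectral window long.")
  }
  x <- downsample_to(trace$vm, trace$fs, 100)
  spec <- sliding_psd(x, 100, window_s, step_s)
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  tibble::tibble(t = trace$t0 + spec$t,
                 band_power = rowMeans(spec$power[, sel, drop = FALSE]))
}

downsample_to <- function(x, fs, out_fs) {
  dec <- as.integer(round(fs / out_fs))
  if (dec <= 1) return(x)
  n <- (length(x) %/% dec) * dec
  colMeans(matrix(x[seq_len(n)], nrow = dec))
}

#' Oscillation power during a current-injection pulse
#'
#' Conditions the trace for pulse-edge artifacts before measuring 2-6 Hz
#' power: the 600 ms segments starting 550 ms before pulse onset and 50 ms
#' before pulse offset are replaced by linear ramps between their endpoint
#' samples, removing the step transients; power is then computed with 2 s
#' windows stepped by 10 ms and summarized as the mean over windows fully
#' contained in the pulse.
#'
#' @param trace An [ephys_trace()].
#' @param pulse_start,pulse_end Pulse window in seconds (>= segment length).
#' @param segment_s Interpolated segment length (default 0.6 s).
#' @param pre_s,end_s Segment start offsets relative to the pulse edges
#'   (defaults 0.55 s before onset, 0.05 s before offset).
#' @return Scalar band power (same units as [band_power_2_6()]).
#' @export
pulse_conditioned_power <- function(trace, pulse_start, pulse_end,
                                    segment_s = 0.6, pre_s = 0.55,
                                    end_s = 0.05) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (pulse_end - pulse_start < segment_s) {
    rlang::abort("pulse shorter than the interpolation-segment geometry.")
  }
  vm <- trace$vm
  fs <- trace$fs
  ramp <- function(vm, t_from) {
    i0 <- as.integer(round((t_from - trace$t0) * fs)) + 1L
    i1 <- i0 + as.integer(round(segment_s * fs)) - 1L
    if (i0 < 1 || i1 > length(vm)) {
      rlang::abort("insufficient flanking data around the pulse.")
    }
    vm[i0:i1] <- seq(vm[i0], vm[i1], length.out = i1 - i0 + 1)
    vm
  }
  vm <- ramp(vm, pulse_start - pre_s)
  vm <- ramp(vm, pulse_end - end_s)
  cond <- ephys_trace(vm, fs = fs, t0 = trace$t0)
  pw <- band_power_2_6(cond, window_s = 2, step_s = 0.01)
  inside <- pw$t - 1 >= pulse_start - 1e-6 & pw$t + 1 <= pulse_end + 1e-6
  if (!any(inside)) rlang::abort("no spectral window fully inside the pulse.")
  mean(pw$band_power[inside])
}

#' Baseline membrane potential of a cell
#'
#' The baseline Vm is defined as the minimum over populated bins of the
#' cell's heading tuning curve (PFNa cells lack a classical resting
#' potential because calcium spikes and synaptic drive persist when
#' hyperpolarized).
#'
#' @param heading_curve A tuning curve from [heading_tuning()] (tibble with
#'   `mean` and `populated` columns).
#' @return Scalar mV.
#' @export
baseline_vm <- function(heading_curve) {
  stopifnot(is.data.frame(heading_curve), "populated" %in% names(heading_curve))
  m <- heading_curve$mean[heading_curve$populated]
  if (length(m) == 0) rlang::abort("heading curve has no populated bins.")
  min(m)
}
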