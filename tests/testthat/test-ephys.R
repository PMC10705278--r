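make_trace <- function(vm, fs = 10000) ephys_trace(vm, fs = fs)

test_that("condition_vm downsamples, preserves slow structure and removes spikes", {
  n <- 10000 * 3
  const <- make_trace(rep(-60, n))
  out <- condition_vm(const)
  expect_equal(out$fs, 1000)
  expect_true(all(abs(out$vm + 60) < 1e-12))
  # one inserted 2 ms spike disappears under the 40 ms median
  vm <- rep(-60, n)
  vm[15000:15019] <- vm[15000:15019] + 3 * sin(pi * (1:20) / 20)
  out_sp <- condition_vm(make_trace(vm))
  expect_true(all(abs(out_sp$vm + 60) < 0.1))
  # a 1 Hz sinusoid passes with < 5% attenuation
  t <- (0:(n - 1)) / 10000
  sine <- make_trace(-60 + 5 * sin(2 * pi * 1 * t))
  out_s <- condition_vm(sine)
  mid <- out_s$vm[500:2500]
  expect_gt((max(mid) - min(mid)) / 2, 5 * 0.95)
  expect_error(condition_vm(make_trace(rep(0, 20))), "kernel")
})

test_that("sodium spike detection finds inserted templates and respects the refractory rule", {
  fs <- 10000
  n <- fs * 5
  set.seed(21)
  t_true <- seq(0.5, 4.5, length.out = 10)
  # low-level colored background, like subthreshold synaptic noise
  rho <- exp(-1 / (0.02 * fs))
  noise <- as.numeric(stats::filter(rnorm(n), rho, method = "recursive"))
  vm <- -60 + noise * 0.5 / sd(noise)
  tmpl <- c(3 * sin(pi * (1:10) / 10), -sin(pi * (1:10) / 10))
  for (ts in t_true) {
    i <- round(ts * fs)
    vm[i:(i + 19)] <- vm[i:(i + 19)] + tmpl
  }
  sp <- detect_sodium_spikes(make_trace(vm))
  expect_equal(nrow(sp), 10)
  match_err <- vapply(t_true, function(ts) min(abs(sp$spike_time - ts)),
                      numeric(1))
  expect_true(all(match_err < 5e-4))
  # pure subthreshold noise: no detections at the adaptive threshold
  sp0 <- detect_sodium_spikes(make_trace(-60 + 0.2 * rnorm(n)), threshold = 1)
  expect_equal(nrow(sp0), 0)
  # two spikes 5 ms apart collapse to one detection
  vm2 <- -60 + 0.05 * rnorm(n)
  for (ts in c(2, 2.005)) {
    i <- round(ts * fs)
    vm2[i:(i + 19)] <- vm2[i:(i + 19)] + tmpl
  }
  sp2 <- detect_sodium_spikes(make_trace(vm2), threshold = 1)
  expect_equal(nrow(sp2), 1)
  # spike times strictly increasing with >= 6.66 ms separation
  expect_true(all(diff(sp$spike_time) >= 1 / 150 - 1e-9))
})

test_that("spike detection stays silent during hyperpolarized oscillation epochs", {
  truth <- ground_truth_params(side = "right", preferred_heading = 0)
  beh <- constant_behavior(180, 30)   # anti-preferred: hyperpolarized
  tr <- simulate_vm_trace(truth, beh, NULL, seed = 4)
  sp <- detect_sodium_spikes(tr)
  expect_lt(nrow(sp) / 30, 0.1)   # < 0.1 Hz false-event rate
})

test_that("spike_rate is a unit-area Hann smoothing of the spike train", {
  grid <- seq(0, 10, by = 0.001)
  r1 <- spike_rate(tibble::tibble(spike_time = 5), grid)
  expect_equal(sum(r1$rate) * 0.001, 1, tolerance = 1e-6)
  expect_equal(grid[which.max(r1$rate)], 5, tolerance = 0.002)
  r0 <- spike_rate(tibble::tibble(spike_time = numeric(0)), grid)
  expect_true(all(r0$rate == 0))
  set.seed(13)
  st <- cumsum(rexp(4000, rate = 20))
  st <- st[st < 100]
  grid100 <- seq(0, 100, by = 0.001)
  rp <- spike_rate(st, grid100)
  expect_lt(abs(mean(rp$rate) - 20), 3 * sqrt(20 / 100) + 0.5)
})

test_that("band power matches an independent periodogram oracle on pure tones", {
  fs <- 10000
  t <- (0:(40 * fs - 1)) / fs
  tone4 <- make_trace(2 * sin(2 * pi * 4 * t))
  pw4 <- band_power_2_6(tone4)
  # independent oracle: direct Hann periodogram of 4 s segments at 100 Hz,
  # written against the definition rather than the implementation
  oracle <- function(x_full, f_lo = 2, f_hi = 6) {
    dec <- matrix(x_full[1:(length(x_full) %/% 100 * 100)], nrow = 100)
    x <- colMeans(dec)
    L <- 400
    w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # periodic Hann
    segs <- seq(1, length(x) - L + 1, by = L)
    ps <- sapply(segs, function(s0) {
      seg <- (x[s0:(s0 + L - 1)] - mean(x[s0:(s0 + L - 1)])) * w
      X <- fft(seg)
      f <- (0:(L / 2)) * 100 / L
      p <- 2 * Mod(X[1:(L / 2 + 1)])^2 / (100 * sum(w^2))
      mean(p[f >= f_lo & f <= f_hi])
    })
    mean(ps)
  }
  expect_equal(mean(pw4$band_power), oracle(tone4$vm), tolerance = 0.01)
  # out-of-band tone: < 1% leakage relative to the in-band case
  tone20 <- make_trace(2 * sin(2 * pi * 20 * t))
  pw20 <- band_power_2_6(tone20)
  expect_lt(mean(pw20$band_power), 0.01 * mean(pw4$band_power))
  # constant trace: exactly zero
  pwc <- band_power_2_6(make_trace(rep(-60, 10 * fs)))
  expect_true(all(pwc$band_power < 1e-20))
  expect_error(band_power_2_6(make_trace(rep(0, fs))), "window")
})

test_that("pulse-conditioned power removes step artifacts and keeps real oscillations", {
  fs <- 10000
  dur <- 12
  t <- (0:(dur * fs - 1)) / fs
  pulse <- c(4, 6)
  inside <- t >= pulse[1] & t < pulse[2]
  # pure step: conditioned power is ~0, unconditioned is clearly positive
  vm_step <- -60 + ifelse(inside, -10, 0)
  p_cond <- pulse_conditioned_power(make_trace(vm_step), pulse[1], pulse[2])
  raw_pw <- band_power_2_6(make_trace(vm_step), window_s = 2, step_s = 0.01)
  covers_edge <- raw_pw$t > pulse[1] - 0.5 & raw_pw$t < pulse[1] + 0.5
  p_raw <- mean(raw_pw$band_power[covers_edge])
  expect_lt(p_cond, 0.01 * p_raw)
  # oscillation confined to the pulse survives conditioning
  vm_osc <- -60 + ifelse(inside, 3 * sin(2 * pi * 4 * (t - pulse[1])), 0)
  p_osc <- pulse_conditioned_power(make_trace(vm_osc), pulse[1], pulse[2])
  core <- make_trace(3 * sin(2 * pi * 4 * t[t < 2]))
  p_core <- mean(band_power_2_6(core, window_s = 2, step_s = 0.01)$band_power)
  expect_equal(p_osc, p_core, tolerance = 0.1)
  expect_error(pulse_conditioned_power(make_trace(rep(0, fs * 12)), 4, 4.3),
               "shorter")
})

test_that("baseline Vm is the heading-curve minimum", {
  curve <- tibble::tibble(
    bin_center_deg = c(-90, 0, 90),
    mean = c(-64, -55, -50),
    occupancy_s = c(5, 5, 5),
    populated = c(TRUE, TRUE, TRUE)
  )
  expect_equal(baseline_vm(curve), -64)
  curve$mean <- rep(-58, 3)
  expect_equal(baseline_vm(curve), -58)
  curve$populated <- FALSE
  expect_error(baseline_vm(curve), "populated")
  # noiseless model curve: a0 + aH * min(cos) = -64 - 7 at the 180 bin
  truth <- ground_truth_params(a0 = -64, aH = 7, vm_noise_sd = 0,
                               bH = 0, bW = 0)
  beh <- sweep_behavior(360, deg_per_s = 10)   # 10 full sweeps? 1 sweep/36s
  tr <- simulate_vm_trace(truth, beh, NULL, seed = 2)
  cond <- condition_vm(tr)
  sig <- tibble::as_tibble(cond) |> dplyr::rename(value = vm)
  hc <- heading_tuning(sig, beh)
  expect_equal(baseline_vm(hc), -71, tolerance = 0.05)
})
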