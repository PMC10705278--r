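test_that("protocol blocks are balanced permutations of the 12 directions", {
  p <- make_protocol(3, seed = 4)
  expect_equal(nrow(p), 36)
  expect_true(all(table(p$airflow_direction) == 3))
  dirs <- sort(protocol_directions())
  expect_equal(dirs, sort(wrap_deg(seq(0, 330, 30))))
  for (b in 1:3) {
    expect_setequal(p$airflow_direction[p$block_index == b], dirs)
  }
  # 4 s pulses with >= 5 s gaps
  expect_true(all(p$duration == 4))
  gaps <- diff(p$onset_time) - p$duration[-nrow(p)]
  expect_true(all(gaps >= 5 - 1e-9))
  # determinism
  expect_identical(make_protocol(2, seed = 9), make_protocol(2, seed = 9))
  expect_error(make_protocol(0), ">= 1")
})

test_that("heading trajectory is a seeded random walk with speed gating", {
  b0 <- make_heading_trajectory(10, turn_rate_sd = 0, seed = 1, heading0 = 33)
  expect_true(all(b0$heading == 33))
  expect_identical(make_heading_trajectory(20, seed = 5),
                   make_heading_trajectory(20, seed = 5))
  b <- make_heading_trajectory(120, seed = 2)
  expect_true(all(b$forward_speed >= 0))
  expect_gt(mean(b$forward_speed > 0.5), 0.7)
  expect_true(all(b$heading > -180 & b$heading <= 180))
})

test_that("long trajectories occupy every 10-degree heading bin", {
  # empirical check across seeds: >= 2 s in every bin for 600 s walks
  ok <- vapply(1:20, function(s) {
    b <- make_heading_trajectory(600, seed = s)
    occ <- table(cut(b$heading, seq(-180, 180, by = 10))) / 80
    all(occ >= 2)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("Vm trace follows the sum-of-sinusoids mean", {
  truth <- ground_truth_params(side = "right", preferred_heading = 40,
                               vm_noise_sd = 0, bH = 0, bW = 0)
  beh <- constant_behavior(40, 6)
  tr <- simulate_vm_trace(truth, beh, trials = NULL, seed = 1)
  expect_equal(tr$fs, 10000)
  # H = 0 at preferred, no puffs: mean path is exactly a0 + aH
  expect_true(all(abs(tr$vm - (truth$a0 + truth$aH)) < 1e-9))
  # no sodium spikes when bH = bW = 0
  expect_length(attr(tr, "true_spike_times"), 0)
})

test_that("trial windows outside the recording are rejected", {
  truth <- ground_truth_params()
  beh <- constant_behavior(0, 5)
  trials <- make_protocol(1, seed = 1, lead_in_s = 100)
  expect_error(simulate_vm_trace(truth, beh, trials), "inside")
})

test_that("generated oscillation band power matches the model (round trip)", {
  # anti-preferred heading, puff at the angle minimizing the airflow term:
  # strong hyperpolarization, so the oscillation gate is open throughout
  truth <- ground_truth_params(side = "right", preferred_heading = 0,
                               vm_noise_sd = 0, bH = 0, bW = 0)
  beh <- constant_behavior(180, 30)
  trials <- tibble::tibble(trial = 1, block_index = 1,
                           airflow_direction = -135, onset_time = 5,
                           duration = 20)
  tr <- simulate_vm_trace(truth, beh, trials, seed = 3)
  p_model <- osc_model(180, -135, truth)
  # reference: same estimator on a pure sinusoid of that variance
  t10 <- (0:(30 * 10000 - 1)) / 10000
  ref <- ephys_trace(sqrt(2 * p_model) * sin(2 * pi * truth$osc_freq * t10),
                     fs = 10000)
  pw <- band_power_2_6(tr)
  pw_ref <- band_power_2_6(ref)
  steady <- pw$t > 8 & pw$t < 22
  expect_equal(mean(pw$band_power[steady]),
               mean(pw_ref$band_power[steady]), tolerance = 0.05)
})

test_that("sodium spike counts converge to the model rate", {
  truth <- ground_truth_params(side = "right", preferred_heading = 0,
                               vm_noise_sd = 0)
  beh <- constant_behavior(0, 60)   # H = 0: rate = bH^2 = 16 sp/s
  tr <- simulate_vm_trace(truth, beh, NULL, seed = 6)
  n_sp <- length(attr(tr, "true_spike_times"))
  lambda <- truth$bH^2 * 60
  expect_lt(abs(n_sp - lambda), 3 * sqrt(lambda))
})

test_that("imaging bumps align with the EPG phase under depolarization and invert under hyperpolarization", {
  truths <- make_population(vm_noise_sd = 0, imaging_noise_sd = 0)
  beh <- constant_behavior(60, 40)   # fixed heading at 60 deg
  # front puff depolarizes both sides; rear puff hyperpolarizes both
  trials <- tibble::tibble(trial = 1:2, block_index = 1,
                           airflow_direction = c(0, 180),
                           onset_time = c(10, 25), duration = 4)
  im <- simulate_imaging(truths, beh, trials, seed = 1)
  epg <- epg_phase_bridge(im$epg_bridge)
  geom <- sector_geometry("bridge18")
  peak_side <- function(frame, side) {
    cols <- which(geom$pfn_mask & geom$side == side)
    geom$center_deg[cols[which.max(im$pfn_bridge$F[frame, cols])]]
  }
  # frame near the end of each puff (kernel settled)
  f_front <- which.min(abs(im$pfn_bridge$t - 13.8))
  f_rear <- which.min(abs(im$pfn_bridge$t - 28.8))
  for (side in c("left", "right")) {
    expect_lt(abs(circ_diff(peak_side(f_front, side),
                            epg$phase_deg[f_front])), 45 + 1e-6)
    expect_gt(abs(circ_diff(peak_side(f_rear, side),
                            epg$phase_deg[f_rear])), 135 - 1e-6)
  }
})

test_that("nodulus airflow tuning is double-peaked with calcium spikes and single-peaked without", {
  beh <- constant_behavior(0, 200, speed = 5)
  trials <- make_protocol(1, seed = 2, lead_in_s = 10)
  n_peaks <- function(truths) {
    im <- simulate_imaging(truths, beh, trials, seed = 3)
    sig <- tibble::tibble(t = im$noduli$t, value = im$noduli$F[, "right"])
    curve <- airflow_tuning(sig, trials, window = c(2, 4))
    v <- curve$mean
    # substantive local maxima on the circular 12-point curve (indicator
    # kernel carry-over leaves ~1e-4 relative residuals in the tails)
    sum(v > v[c(12, 1:11)] & v > v[c(2:12, 1)] & v > 0.05 * max(v))
  }
  with_ca <- make_population(vm_noise_sd = 0, imaging_noise_sd = 0)
  no_ca <- make_population(vm_noise_sd = 0, imaging_noise_sd = 0,
                           theta_ca = -1000)
  expect_equal(n_peaks(with_ca), 2)
  expect_equal(n_peaks(no_ca), 1)
})

test_that("generators are deterministic given the seed", {
  a <- simulate_experiment(n_blocks = 1, seed = 3, n_ephys_cells = 0)
  b <- simulate_experiment(n_blocks = 1, seed = 3, n_ephys_cells = 0)
  expect_identical(a$trials, b$trials)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$imaging$pfn_bridge$F, b$imaging$pfn_bridge$F)
})
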