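test_that("heading tuning bins, gates and applies the occupancy rule", {
  beh <- sweep_behavior(720, deg_per_s = 20)   # 40 uniform sweeps
  sig <- tibble::tibble(t = beh$t, value = cos(pi / 180 * beh$heading))
  curve <- heading_tuning(sig, beh)
  expect_equal(nrow(curve), 36)
  expect_true(all(curve$populated))
  expect_equal(curve$mean, cos(pi / 180 * curve$bin_center_deg),
               tolerance = 0.01)
  # all standing: everything unpopulated
  beh0 <- dplyr::mutate(beh, forward_speed = 0.1)
  c0 <- heading_tuning(sig, beh0)
  expect_false(any(c0$populated))
  expect_true(all(is.na(c0$mean)))
  # a bin visited 1.9 s stays unpopulated
  beh1 <- constant_behavior(0, 1.9)
  sig1 <- tibble::tibble(t = beh1$t, value = 1)
  c1 <- heading_tuning(sig1, beh1)
  expect_false(c1$populated[c1$bin_center_deg == 0])
})

test_that("heading tuning is equivariant under relabeling the origin", {
  beh <- sweep_behavior(360, deg_per_s = 20)
  sig <- tibble::tibble(t = beh$t, value = cos(pi / 180 * (beh$heading - 40)))
  delta <- 30
  beh_rot <- dplyr::mutate(beh, heading = wrap_deg(heading + delta))
  c_a <- heading_tuning(sig, beh)
  c_b <- heading_tuning(sig, beh_rot)
  # bin for angle x + delta in the rotated frame holds the same samples
  shift <- delta / 10
  reord <- ((seq_len(36) - 1 + shift) %% 36) + 1
  expect_equal(c_b$mean[reord], c_a$mean, tolerance = 1e-9)
})

test_that("occupancy is conserved across populated and unpopulated bins", {
  beh <- make_heading_trajectory(120, seed = 9)
  sig <- tibble::tibble(t = beh$t, value = rnorm(nrow(beh)))
  curve <- heading_tuning(sig, beh)
  gated <- sum(beh$forward_speed > 0.5) / 80
  expect_equal(sum(curve$occupancy_s), gated, tolerance = 1 / 80)
})

test_that("preferred heading maximizes cosine correlation", {
  centers <- wrap_deg(-180 + (0:35) * 10)
  mk <- function(vals) {
    out <- tibble::tibble(bin_center_deg = centers, mean = vals,
                          occupancy_s = 10, populated = TRUE)
    class(out) <- c("tuning_curve", class(out))
    out
  }
  expect_equal(preferred_heading(mk(cos(pi / 180 * (centers - 30)))), 30)
  expect_equal(preferred_heading(mk(-cos(pi / 180 * centers))), 180)
  expect_error(preferred_heading(mk(rep(1, 36))), "constant")
  # Monte-Carlo: noisy model curves recover within 10 degrees in >= 95%
  set.seed(17)
  hits <- vapply(1:40, function(i) {
    phi <- runif(1, -180, 180)
    vals <- -64 + 7 * cos(pi / 180 * (centers - phi)) + rnorm(36, 0, 0.7)
    abs(circ_diff(preferred_heading(mk(vals)), phi)) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("airflow tuning averages trials within the stimulus window", {
  trials <- make_protocol(2, seed = 3)
  t <- seq(0, max(trials$onset_time) + 10, by = 1 / 80)
  on0 <- rep(0, length(t))
  for (i in which(trials$airflow_direction == 0)) {
    on0[t >= trials$onset_time[i] & t < trials$onset_time[i] + 4] <- 1
  }
  curve <- airflow_tuning(tibble::tibble(t = t, value = on0), trials)
  expect_equal(curve$mean[curve$bin_center_deg == 0], 1)
  expect_true(all(curve$mean[curve$bin_center_deg != 0] == 0))
  # window entirely outside every trial: all unpopulated
  c_out <- airflow_tuning(tibble::tibble(t = t, value = on0), trials,
                          window = c(1000, 1002))
  expect_false(any(c_out$populated))
  # noiseless generator Vm: curve is a0 + aW cos(W - 45) + aH for H = 0
  truth <- ground_truth_params(side = "right", preferred_heading = 0,
                               vm_noise_sd = 0, bH = 0, bW = 0)
  beh <- constant_behavior(0, max(trials$onset_time) + 10)
  tr <- simulate_vm_trace(truth, beh, trials, seed = 1)
  cond <- condition_vm(tr)
  sig <- tibble::as_tibble(cond) |> dplyr::rename(value = vm)
  cv <- airflow_tuning(sig, trials)
  pred <- vm_model(0, cv$bin_center_deg, truth)
  expect_gt(variance_explained(pred, cv$mean), 0.99)
})

test_that("conjunctive maps have 216 cells and match the noiseless model", {
  ds <- simulate_experiment(n_blocks = 2, seed = 5, n_ephys_cells = 1,
                            vm_noise_sd = 0, bH = 0, bW = 0)
  truth <- ds$truths[which(ds$truths$side == "right")[1], ]
  cond <- condition_vm(ds$vm$cell1)
  sig <- tibble::as_tibble(cond) |> dplyr::rename(value = vm)
  beh_rel <- dplyr::mutate(ds$behavior,
                           heading = circ_diff(heading, truth$preferred_heading))
  map <- conjunctive_map(sig, beh_rel, ds$trials)
  expect_equal(length(map$mean), 216)
  expect_equal(dim(map$mean), c(18, 12))
  td <- tidy(map)
  expect_equal(nrow(td), 216)
  ok <- td$populated
  pred <- vm_model(td$heading_deg[ok], td$airflow_deg[ok], truth)
  expect_gt(variance_explained(pred, td$mean[ok]), 0.99)
  # cells visited under 0.5 s are unpopulated
  expect_true(all(is.na(map$mean[map$occupancy_s < 0.5])))
})

test_that("pooling rotates to preferred heading and nulls the airflow axis", {
  truth_r <- ground_truth_params(side = "right")
  truth_l <- ground_truth_params(side = "left")
  map_r <- model_map(vm_model, truth_r)
  map_l <- model_map(vm_model, truth_l)
  # single cell with preferred 40: pooled = own map rotated by -40
  pooled <- pool_cells(list(map_r), preferred = 40, sides = "right")
  manual <- pfnavector:::rotate_heading_bins(map_r, 2)
  expect_equal(pooled$mean, manual$mean)
  # pooling a map with itself leaves it unchanged
  p2 <- pool_cells(list(map_r, map_r), preferred = c(0, 0),
                   sides = c("right", "right"))
  expect_equal(p2$mean, map_r$mean)
  # left + right with airflow nulling: a single airflow peak centered on 0
  # of the nulled axis (the -45-relabeled 30-degree grid has no bin at 0,
  # so the two flanking bins at +/-15 tie)
  pn <- pool_cells(list(map_l, map_r), preferred = c(0, 0),
                   sides = c("left", "right"), airflow_null = TRUE)
  prof <- colMeans(pn$mean) - min(colMeans(pn$mean))
  cm <- circ_mean(pn$airflow_centers, weights = prof)
  expect_lt(abs(cm$mean_deg), 1e-6)
  expect_lte(abs(pn$airflow_centers[which.max(prof)]), 15)
})
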