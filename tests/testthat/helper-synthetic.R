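# shared fixtures, all generated in code

# behavior trace with a prescribed constant heading, always moving
constant_behavior <- function(heading, duration, fs = 80, speed = 5) {
  n <- round(duration * fs)
  tibble::tibble(t = (seq_len(n) - 1) / fs,
                 heading = rep(wrap_deg(heading), n),
                 forward_speed = rep(speed, n))
}

# behavior sweeping heading uniformly (deg_per_s), always moving
sweep_behavior <- function(duration, deg_per_s = 20, fs = 80, speed = 5) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  tibble::tibble(t = t, heading = wrap_deg(deg_per_s * t),
                 forward_speed = rep(speed, n))
}

# noiseless conjunctive map evaluated from a model surface on the grid
model_map <- function(fun, params) {
  m <- new_map_grid()
  vals <- outer(m$H, m$W, function(H, W) fun(H, W, params))
  pfnavector:::new_conjunctive_map(vals)
}

new_map_grid <- function() {
  list(H = wrap_deg(-180 + (seq_len(18) - 1) * 20),
       W = sort(protocol_directions()))
}

# single-frame bridge matrix holding a 1 + cos bump at `phase` on both halves
bridge_bump_matrix <- function(phase, n_frames = 1, gain = 1, mask = "epg") {
  geom <- sector_geometry("bridge18")
  prof <- gain * (1 + cos(pi / 180 * (geom$center_deg - phase)))
  prof[!geom[[paste0(mask, "_mask")]]] <- 0
  sector_matrix(matrix(rep(prof, n_frames), n_frames, byrow = TRUE),
                t = (seq_len(n_frames) - 1) / 8, geometry = geom,
                normalization = "raw")
}

expect_circ_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(circ_diff(actual, expected)), tol)
}
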