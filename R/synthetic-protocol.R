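#' Build the open-loop air-puff protocol
#'
#' Twelve airflow directions around the fly at 30-degree increments, covering
#' 360 degrees; each block presents each direction exactly once in
#' pseudorandom order. Every pulse lasts `pulse_s` seconds with an
#' `interval_s` inter-pulse interval, after a `lead_in_s` baseline period.
#'
#' @param n_blocks Number of pseudorandomized blocks (>= 1).
#' @param seed Integer seed; the trial order is a pure function of it.
#' @param pulse_s Pulse duration in seconds (default 4).
#' @param interval_s Inter-pulse interval in seconds (default 5).
#' @param lead_in_s Baseline time before the first pulse (default 20 s).
#' @return Tibble of trials: `trial`, `block_index`, `airflow_direction`
#'   (degrees in (-180, 180]), `onset_time`, `duration` (s).
#' @examples
#' make_protocol(n_blocks = 2, seed = 1)
#' @export
make_protocol <- function(n_blocks, seed = 1, pulse_s = 4, interval_s = 5,
                          lead_in_s = 20) {
  if (!is.numeric(n_blocks) || n_blocks < 1) {
    rlang::abort("`n_blocks` must be >= 1.")
  }
  n_blocks <- as.integer(n_blocks)
  directions <- protocol_directions()
  # local RNG so the generator is a pure function of (params, seed)
  dirs <- local_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) sample(directions)))
  })
  n <- length(dirs)
  tibble::tibble(
    trial = seq_len(n),
    block_index = rep(seq_len(n_blocks), each = 12L),
    airflow_direction = dirs,
    onset_time = lead_in_s + (seq_len(n) - 1) * (pulse_s + interval_s),
    duration = pulse_s
  )
}

#' The twelve protocol airflow directions
#'
#' @return `c(0, 30, ..., 180, -150, ..., -30)` wrapped to (-180, 180].
#' @export
protocol_directions <- function() wrap_deg(seq(0, 330, by = 30))

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a closed-loop heading trajectory with forward speed
#'
#' Stand-in for a fly walking on an air-supported ball: the heading is a
#' wrapped random walk whose per-sample increments are white turn-rate noise,
#' and the forward speed alternates between a moving and a standing state via
#' a two-state Markov chain so that a configurable fraction of samples
#' exceeds the 0.5 mm/s behavioral gate.
#'
#' @param duration Trace length in seconds (> 0).
#' @param turn_rate_sd Standard deviation of the instantaneous turn rate in
#'   deg/s (default 400; 0 gives a constant heading).
#' @param seed Integer seed.
#' @param fs Behavioral sampling rate in Hz (default 80, the tracker rate).
#' @param moving_fraction Target fraction of time moving (default 0.9).
#' @param heading0 Initial heading in degrees.
#' @return Tibble: `t` (s), `heading` (degrees, wrapped), `forward_speed`
#'   (mm/s, non-negative).
#' @examples
#' b <- make_heading_trajectory(10, seed = 1)
#' range(b$heading)
#' @export
make_heading_trajectory <- function(duration, turn_rate_sd = 400, seed = 1,
                                    fs = 80, moving_fraction = 0.9,
                                    heading0 = 0) {
  if (!is.numeric(duration) || duration <= 0) {
    rlang::abort("`duration` must be positive.")
  }
  n <- as.integer(round(duration * fs))
  dt <- 1 / fs
  local_seed(seed, {
    increments <- stats::rnorm(n, 0, turn_rate_sd * dt)
    heading <- wrap_deg(heading0 + cumsum(increments) - increments[1])
    # moving/standing Markov chain: mean moving bout 25 s, standing bout set
    # so the stationary moving fraction matches `moving_fraction`
    dwell_move <- 25
    dwell_stand <- max(dwell_move * (1 - moving_fraction) /
                         max(moving_fraction, 1e-6), dt)
    p_stay_m <- 1 - dt / dwell_move
    p_stay_s <- 1 - dt / dwell_stand
    state <- logical(n)
    state[1] <- stats::runif(1) < moving_fraction
    u <- stats::runif(n)
    for (i in 2:n) {
      state[i] <- if (state[i - 1]) u[i] < p_stay_m else u[i] >= p_stay_s
    }
    speed <- ifelse(state,
                    0.6 + stats::rgamma(n, shape = 4, scale = 1),
                    stats::runif(n, 0, 0.3))
    tibble::tibble(t = (seq_len(n) - 1) * dt, heading = heading,
                   forward_speed = speed)
  })
}
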