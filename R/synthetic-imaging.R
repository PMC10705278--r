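#' Build a PFNa population that tiles the bridge
#'
#' Eight cells per side, one per PFN-innervated bridge glomerulus, with
#' preferred headings equal to the glomerulus angles so that a depolarized
#' population expresses a bump aligned with the heading signal.
#'
#' @param n_per_side Cells per side; must be 8 to tile the PFN glomeruli.
#' @param ... Passed to [ground_truth_params()] (shared by all cells).
#' @return Tibble of per-cell ground-truth rows with a `glomerulus` column.
#' @export
make_population <- function(n_per_side = 8, ...) {
  if (n_per_side < 8) {
    rlang::abort("population too small: 8 cells per side are needed to tile the PFN glomeruli.")
  }
  geom <- sector_geometry("bridge18")
  glo <- which(geom$pfn_mask)
  sides <- as.character(geom$side[glo])
  purrr::map2_dfr(glo, sides, function(g, s) {
    p <- ground_truth_params(side = s, preferred_heading = geom$center_deg[g], ...)
    p$glomerulus <- g
    p
  })
}

#' Simulate sector-resolved calcium-imaging matrices
#'
#' Applies the dual-threshold forward model to a PFNa population: the
#' instantaneous calcium drive of the cell in bridge glomerulus `g` is
#' `k_na [Vm_g - theta_na]+^2 + k_ca [theta_ca - Vm_g]+^2`, where `Vm_g` is
#' the cell's noiseless subthreshold mean. Drives are convolved with a
#' unit-area exponential indicator kernel (`ca_tau`), sampled at the frame
#' rate, and Gaussian noise is added. Also produced: an EPG matrix with a
#' bump at the heading on each bridge half and in the ellipsoid body, and
#' nodulus traces equal to the population-mean drive per side.
#'
#' @param truths Population tibble from [make_population()].
#' @param behavior Heading trajectory ([make_heading_trajectory()]).
#' @param trials Protocol tibble ([make_protocol()]).
#' @param seed Integer seed for the imaging noise.
#' @param epg_kappa Concentration of the EPG bump profile (von Mises shape).
#' @return Named list of [sector_matrix()] objects: `pfn_bridge`,
#'   `epg_bridge`, `epg_eb`, `noduli` (all `normalization = "raw"`).
#' @export
simulate_imaging <- function(truths, behavior, trials = NULL, seed = 1,
                             epg_kappa = 2) {
  stopifnot(is.data.frame(truths), nrow(truths) >= 16)
  geom <- sector_geometry("bridge18")
  fs_b <- behavior_fs(behavior)
  t <- behavior$t
  n <- length(t)
  frame_rate <- truths$frame_rate[1]
  ca_tau <- truths$ca_tau[1]
  noise_sd <- truths$imaging_noise_sd[1]
  air <- airflow_at(t, trials)
  Wv <- ifelse(air$on, air$W, 0)

  # per-cell drive at behavior rate
  drive <- matrix(0, n, 18)
  for (i in seq_len(nrow(truths))) {
    p <- truths[i, ]
    H <- circ_diff(behavior$heading, p$preferred_heading)
    vm <- vm_model(H, Wv, p, airflow_on = air$on)
    d <- p$k_na * pmax(vm - p$theta_na, 0)^2 +
      p$k_ca * pmax(p$theta_ca - vm, 0)^2
    drive[, p$glomerulus] <- d
  }

  # EPG bump: two bridge copies plus the ellipsoid-body ring
  hb <- deg2rad(behavior$heading)
  epg_profile <- function(center_deg) {
    0.1 + exp(epg_kappa * (cos(outer(hb, deg2rad(center_deg), function(h, a) h - a)) - 1))
  }
  epg_b <- epg_profile(geom$center_deg)
  epg_b[, !geom$epg_mask] <- 0
  geb <- sector_geometry("eb16")
  epg_eb <- epg_profile(geb$center_deg)

  nod <- cbind(
    left = rowMeans(drive[, which(geom$pfn_mask & geom$side == "left"), drop = FALSE]),
    right = rowMeans(drive[, which(geom$pfn_mask & geom$side == "right"), drop = FALSE])
  )

  step <- max(as.integer(round(fs_b / frame_rate)), 1L)
  fr_idx <- seq(1, n, by = step)

  local_seed(seed, {
    to_frames <- function(M, add_noise = TRUE) {
      Mf <- apply(M, 2, exp_smooth, tau = ca_tau, fs = fs_b)[fr_idx, , drop = FALSE]
      if (add_noise && noise_sd > 0) {
        Mf <- Mf + matrix(stats::rnorm(length(Mf), 0, noise_sd), nrow(Mf))
      }
      pmax(Mf, 0)
    }
    tf <- t[fr_idx]
    list(
      pfn_bridge = sector_matrix(to_frames(drive), tf, geom, "raw"),
      epg_bridge = sector_matrix(to_frames(epg_b), tf, geom, "raw"),
      epg_eb = sector_matrix(to_frames(epg_eb), tf, geb, "raw"),
      noduli = sector_matrix(to_frames(nod), tf, sector_geometry("noduli2"), "raw")
    )
  })
}

# causal convolution with a unit-area single-exponential indicator kernel,
# realized exactly as a first-order recursive filter (O(n))
exp_smooth <- function(x, tau, fs) {
  lambda <- exp(-1 / (tau * fs))
  y <- stats::filter((1 - lambda) * x, lambda, method = "recursive")
  as.numeric(y)
}

#' Simulate a complete in-silico experiment
#'
#' Assembles the full synthetic dataset every downstream stage consumes:
#' protocol, behavior, per-cell 10 kHz membrane-potential traces for a subset
#' of cells, and the imaging matrices for the whole population.
#'
#' @param n_blocks Protocol blocks (default 3).
#' @param seed Master integer seed; stage sub-seeds are derived from it.
#' @param n_ephys_cells Number of cells (alternating right/left, starting at
#'   the population's first right and first left cell) for which full Vm
#'   traces are simulated (default 2; traces are the expensive part).
#' @param lead_in_s Baseline period before the first puff.
#' @param ... Shared cell parameters forwarded to [make_population()].
#' @return List of class `pfna_dataset`: `trials`, `behavior`, `truths`,
#'   `vm` (named list of [ephys_trace()]), `imaging` (list of
#'   [sector_matrix()]), `seed`.
#' @export
simulate_experiment <- function(n_blocks = 3, seed = 1, n_ephys_cells = 2,
                                lead_in_s = 20, ...) {
  seed <- as.integer(seed)
  trials <- make_protocol(n_blocks, seed = seed, lead_in_s = lead_in_s)
  duration <- max(trials$onset_time + trials$duration) + 5
  behavior <- make_heading_trajectory(duration, seed = seed + 1L)
  truths <- make_population(...)
  vm <- list()
  if (n_ephys_cells > 0) {
    pick <- c(which(truths$side == "right")[1], which(truths$side == "left")[1],
              which(truths$side == "right")[2], which(truths$side == "left")[2])
    pick <- pick[seq_len(min(n_ephys_cells, 4))]
    vm <- purrr::imap(
      stats::setNames(pick, paste0("cell", seq_along(pick))),
      function(i, nm) simulate_vm_trace(truths[i, ], behavior, trials,
                                        seed = seed + 100L + i)
    )
  }
  imaging <- simulate_imaging(truths, behavior, trials, seed = seed + 2L)
  structure(list(trials = trials, behavior = behavior, truths = truths,
                 vm = vm, imaging = imaging, seed = seed),
            class = "pfna_dataset")
}

#' @export
print.pfna_dataset <- function(x, ...) {
  cat(sprintf(paste0("<pfna_dataset> %d trials (%d blocks), %.0f s behavior, ",
                     "%d Vm trace(s), %d imaging matrices, seed %d\n"),
              nrow(x$trials), max(x$trials$block_index),
              nrow(x$behavior) / behavior_fs(x$behavior),
              length(x$vm), length(x$imaging), x$seed))
  invisible(x)
}
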