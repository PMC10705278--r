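#' Decoder configuration
#'
#' @param kappa Calcium-to-sodium conversion factor applied to phase-inverted
#'   (calcium-spike) phasor components before vector summation (default 0.2).
#' @param side_shift_deg Anatomical fan-shaped-body shift applied to each
#'   side's phasor: left -45, right +45 degrees. The two shifts must be
#'   negatives of each other with magnitude 45.
#' @param profile_peak_method How profile peaks are located when needed:
#'   `"pva"` (default) or `"argmax"`.
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(kappa = 0.2,
                           side_shift_deg = c(left = -45, right = 45),
                           profile_peak_method = c("pva", "argmax")) {
  if (kappa < 0) rlang::abort("`kappa` must be non-negative.")
  if (!isTRUE(all.equal(unname(side_shift_deg["left"]),
                        -unname(side_shift_deg["right"]))) ||
      abs(side_shift_deg["left"]) != 45) {
    rlang::abort("side shifts must be opposite-signed with magnitude 45.")
  }
  structure(list(kappa = kappa, side_shift_deg = side_shift_deg,
                 profile_peak_method = match.arg(profile_peak_method)),
            class = "decoder_config")
}

#' Summed output of a matched left/right PFNa pair
#'
#' The combined (unrectified quadratic) output of two similarly tuned PFNa
#' neurons after their +/-45 degree anatomical shifts into the fan-shaped
#' body: `(bH cos(H - 45) + bW cos(W + 45))^2 +
#' (bH cos(H + 45) + bW cos(W - 45))^2`.
#'
#' @param bH,bW Heading and airflow amplitudes.
#' @param H,W Relative heading and egocentric airflow direction (degrees).
#' @return Non-negative combined output (vectorized).
#' @seealso [closed_form_output()] for the algebraically equal closed form.
#' @export
pair_output <- function(bH, bW, H, W) {
  Hr <- deg2rad(H); Wr <- deg2rad(W); q <- pi / 4
  (bH * cos(Hr - q) + bW * cos(Wr + q))^2 +
    (bH * cos(Hr + q) + bW * cos(Wr - q))^2
}

#' Closed form of the pair output
#'
#' `bH^2 + bW^2 + 2 bH bW cos(W + H)`: the pair output collapses, by
#' trigonometric identities, to a function of `W + H` alone — the airflow
#' direction in allocentric coordinates. This is what makes the summed
#' fan-shaped-body signal a phasor for the allocentric airflow direction.
#'
#' @inheritParams pair_output
#' @return Non-negative combined output (vectorized).
#' @export
closed_form_output <- function(bH, bW, H, W) {
  bH^2 + bW^2 + 2 * bH * bW * cos(deg2rad(W + H))
}

#' Decode the airflow direction from phase-nulled bridge profiles
#'
#' Implements the invertible-phasor read-out. Each side's phase-nulled
#' profile is decomposed by signed cosine projection at relative angle 0: a
#' positive amplitude is an EPG-aligned (sodium-spike) phasor at phase 0; a
#' negative amplitude is a phase-inverted (calcium-spike) phasor, whose
#' magnitude is multiplied by the conversion factor `kappa` and whose phase
#' is 180. Each phasor is then rotated by its side's anatomical shift
#' (left -45, right +45) and the two are summed as sinusoids; the decoded
#' egocentric (EPG-relative) direction is the phase of the sum, and the
#' allocentric direction adds the heading.
#'
#' @param left_profile,right_profile Tibbles with `rel_angle_deg`, `profile`
#'   ([phase_null()] output, one side each).
#' @param config A [decoder_config()].
#' @param heading_deg Optional heading to report the allocentric angle
#'   (default 0, i.e. relative = allocentric).
#' @return One-row tibble: `amp_left`, `amp_right` (signed projections),
#'   `inverted_left`, `inverted_right`, `decoded_rel_deg`,
#'   `decoded_allo_deg`, `amplitude`, `defined`.
#' @export
decode_allocentric <- function(left_profile, right_profile,
                               config = decoder_config(), heading_deg = 0) {
  a_l <- cosine_projection_grid(left_profile$profile,
                                left_profile$rel_angle_deg, 0)
  a_r <- cosine_projection_grid(right_profile$profile,
                                right_profile$rel_angle_deg, 0)
  phasor <- function(a, shift) {
    amp <- if (a >= 0) a else config$kappa * abs(a)
    phase <- if (a >= 0) 0 else 180
    amp * exp(1i * deg2rad(phase + shift))
  }
  z <- phasor(a_l, config$side_shift_deg[["left"]]) +
    phasor(a_r, config$side_shift_deg[["right"]])
  defined <- Mod(z) > 1e-12
  rel <- if (defined) wrap_deg(rad2deg(Arg(z))) else NA_real_
  tibble::tibble(
    amp_left = a_l, amp_right = a_r,
    inverted_left = a_l < 0, inverted_right = a_r < 0,
    decoded_rel_deg = rel,
    decoded_allo_deg = if (defined) wrap_deg(rel + heading_deg) else NA_real_,
    amplitude = Mod(z), defined = defined
  )
}

#' Decode every protocol direction of a synthetic experiment
#'
#' Runs the full imaging read-out for each of the 12 airflow directions:
#' extracts the EPG phase from the bridge, phase-nulls the PFNa bridge
#' matrix over the within-puff frames of all trials of that direction,
#' decodes the egocentric airflow direction from the two nulled profiles,
#' and compares against the truth (`W` relative; `wrap(W + H)`
#' allocentric, with `H` the circular-mean heading over those frames).
#'
#' @param dataset A [simulate_experiment()] result (or any list with
#'   `imaging`, `trials`, `behavior`).
#' @param config A [decoder_config()].
#' @param window Within-trial window (s post-onset) selecting the frames
#'   used for nulling (default `c(0.5, 4)`).
#' @return Tibble with one row per direction: `airflow_direction`,
#'   `decoded_rel_deg`, `error_rel_deg` (circular), `decoded_allo_deg`,
#'   `true_allo_deg`, `error_allo_deg`, amplitudes and inversion flags,
#'   `defined`.
#' @export
decode_protocol <- function(dataset, config = decoder_config(),
                            window = c(0.5, 4)) {
  pfn <- dataset$imaging$pfn_bridge
  epg <- epg_phase_bridge(dataset$imaging$epg_bridge)
  fs_b <- behavior_fs(dataset$behavior)
  purrr::map_dfr(sort(protocol_directions()), function(dir) {
    tr <- dataset$trials[dataset$trials$airflow_direction == dir, ]
    frames <- rep(FALSE, length(pfn$t))
    for (i in seq_len(nrow(tr))) {
      frames <- frames | (pfn$t >= tr$onset_time[i] + window[1] &
                            pfn$t < tr$onset_time[i] + window[2])
    }
    if (!any(frames & epg$defined)) {
      return(tibble::tibble(airflow_direction = dir, decoded_rel_deg = NA_real_,
                            error_rel_deg = NA_real_,
                            decoded_allo_deg = NA_real_,
                            true_allo_deg = NA_real_, error_allo_deg = NA_real_,
                            amp_left = NA_real_, amp_right = NA_real_,
                            inverted_left = NA, inverted_right = NA,
                            defined = FALSE))
    }
    prof <- phase_null(pfn, epg, frames = frames)
    # heading over the same frames (circular mean), for the allocentric truth
    idx <- pmin(pmax(floor(pfn$t[frames] * fs_b) + 1, 1), nrow(dataset$behavior))
    hmean <- circ_mean(dataset$behavior$heading[idx])$mean_deg
    if (is.na(hmean)) hmean <- 0
    dec <- decode_allocentric(prof[prof$side == "left", ],
                              prof[prof$side == "right", ],
                              config, heading_deg = hmean)
    tibble::tibble(
      airflow_direction = dir,
      decoded_rel_deg = dec$decoded_rel_deg,
      error_rel_deg = if (dec$defined) circ_diff(dec$decoded_rel_deg, dir) else NA_real_,
      decoded_allo_deg = dec$decoded_allo_deg,
      true_allo_deg = wrap_deg(dir + hmean),
      error_allo_deg = if (dec$defined) {
        circ_diff(dec$decoded_allo_deg, wrap_deg(dir + hmean))
      } else NA_real_,
      amp_left = dec$amp_left, amp_right = dec$amp_right,
      inverted_left = dec$inverted_left, inverted_right = dec$inverted_right,
      defined = dec$defined
    )
  })
}

#' Median absolute circular decode error
#'
#' @param decode_table Result of [decode_protocol()].
#' @param which `"rel"` (egocentric, default) or `"allo"`.
#' @return Median of `|circular error|` over defined directions, degrees.
#' @export
decode_error_summary <- function(decode_table, which = c("rel", "allo")) {
  which <- match.arg(which)
  col <- if (which == "rel") "error_rel_deg" else "error_allo_deg"
  stats::median(abs(decode_table[[col]]), na.rm = TRUE)
}
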