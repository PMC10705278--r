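#' Normalize a sector fluorescence matrix
#'
#' Per-sector normalization over the full recording, matching the convention
#' used for each structure:
#' * `dff` (ellipsoid body / fan-shaped body): `(F - F5) / F5` with `F5` the
#'   sector's 5th percentile;
#' * `range` (bridge glomeruli, which differ in brightness):
#'   `(F - F5) / (F95 - F5)` with the 5th and 95th percentiles;
#' * `zscore` (noduli): per-sector mean/SD standardization.
#'
#' Sectors whose denominator is degenerate (zero percentile, zero range or
#' zero SD) are rejected.
#'
#' @param matrix A raw [sector_matrix()].
#' @param method `"dff"`, `"range"` or `"zscore"`.
#' @return A [sector_matrix()] with the corresponding normalization state.
#' @export
normalize_sectors <- function(matrix, method = c("dff", "range", "zscore")) {
  stopifnot(inherits(matrix, "sector_matrix"))
  method <- match.arg(method)
  if (matrix$normalization != "raw") {
    rlang::abort("`matrix` must be raw fluorescence.")
  }
  F <- matrix$F
  out <- F
  bad <- logical(ncol(F))
  for (j in seq_len(ncol(F))) {
    x <- F[, j]
    if (method == "dff") {
      f5 <- stats::quantile(x, 0.05, names = FALSE)
      if (f5 <= 0) { bad[j] <- TRUE; next }
      out[, j] <- (x - f5) / f5
    } else if (method == "range") {
      q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
      if (diff(q) <= 0) { bad[j] <- TRUE; next }
      out[, j] <- (x - q[1]) / (q[2] - q[1])
    } else {
      s <- stats::sd(x)
      if (s == 0) { bad[j] <- TRUE; next }
      out[, j] <- (x - mean(x)) / s
    }
  }
  if (any(bad)) {
    rlang::abort(sprintf("degenerate sector(s) %s cannot be %s-normalized.",
                         paste(which(bad), collapse = ", "), method))
  }
  res <- matrix
  res$F <- out
  res$normalization <- method
  res
}

#' EPG heading phase from the protocerebral bridge
#'
#' The heading-bump phase is the phase of the discrete Fourier component
#' with a wavelength of 8 glomeruli across the 16 EPG-innervated glomeruli
#' (the two bump copies sit 8 glomeruli apart). The per-frame strength is
#' the magnitude of that component relative to the total spectral magnitude.
#'
#' @param matrix A bridge [sector_matrix()] (18 columns; the EPG-innervated
#'   16 are used) or an already-restricted 16-column matrix object.
#' @return Tibble `t`, `phase_deg`, `strength`, `defined` (all-zero frames
#'   are flagged undefined).
#' @export
epg_phase_bridge <- function(matrix) {
  stopifnot(inherits(matrix, "sector_matrix"))
  geom <- matrix$geometry
  F <- matrix$F
  if (geom$structure == "bridge18") {
    F <- F[, geom$epg_mask, drop = FALSE]
  }
  if (ncol(F) != 16) rlang::abort("EPG phase needs the 16 innervated glomeruli.")
  n <- 16
  j <- 0:(n - 1)
  # period-8 component (k = 2 for n = 16)
  e8 <- exp(-2i * pi * j / 8)
  X8 <- as.complex(F %*% e8)
  # total magnitude across all DFT components, for the confidence measure
  tot <- apply(F, 1, function(row) sum(Mod(stats::fft(row))))
  strength <- ifelse(tot > 0, Mod(X8) / tot, NA_real_)
  defined <- tot > 0 & Mod(X8) / pmax(tot, .Machine$double.eps) > 1e-9
  # glomerulus angles advance +45 deg per index, so phase angle = -Arg(X8)
  phase <- ifelse(defined, wrap_deg(rad2deg(-Arg(X8)) +
                                      first_epg_angle(geom)), NA_real_)
  tibble::tibble(t = matrix$t, phase_deg = phase, strength = strength,
                 defined = defined)
}

# angle of the first EPG-innervated glomerulus (index offset of the DFT)
first_epg_angle <- function(geom) {
  if (geom$structure == "bridge18") geom$center_deg[which(geom$epg_mask)[1]] else 0
}

#' Per-frame population-vector phase of a ring structure
#'
#' Applies [pva()] to every frame of an ellipsoid-body or fan-shaped-body
#' matrix; frames whose PVA strength falls below `strength_floor` are
#' flagged invalid (the bump is too weak for its phase to be meaningful).
#'
#' @param matrix A normalized [sector_matrix()] with `eb16`/`fb16` geometry.
#' @param strength_floor Minimum PVA strength (default 0.15).
#' @return Tibble `t`, `phase_deg`, `strength`, `valid`.
#' @export
pva_phase <- function(matrix, strength_floor = 0.15) {
  stopifnot(inherits(matrix, "sector_matrix"))
  res <- purrr::map_dfr(seq_len(nrow(matrix$F)), function(i) {
    pva(pmax(matrix$F[i, ], 0), matrix$geometry)
  })
  tibble::tibble(
    t = matrix$t,
    phase_deg = res$phase_deg,
    strength = res$strength,
    valid = res$defined & !is.na(res$strength) & res$strength >= strength_floor
  )
}

# periodic cubic-spline interpolation of an 8-sector bridge half onto a
# dense circular grid (res_frac of a glomerulus per step)
interp_half <- function(values, res_frac = 0.1) {
  n <- length(values)
  m <- as.integer(round(n / res_frac))
  # periodic spline over one full cycle of the half (8 glomeruli = 360 deg)
  sp <- stats::spline(x = 0:n, y = c(values, values[1]), method = "periodic",
                      xout = seq(0, n - res_frac, by = res_frac))
  sp$y[seq_len(m)]
}

#' Phase-null PFNa bridge profiles against the EPG phase
#'
#' For every frame, each bridge half's 8 PFN-innervated glomeruli are
#' interpolated to 1/10-glomerulus resolution with a periodic cubic spline
#' and circularly rotated so that the EPG phase sits at relative angle 0;
#' the rotated profiles are then averaged over the selected frames. The
#' result is, per side, a mean profile over EPG-relative angle: a peak at 0
#' means the PFNa bump is aligned with the heading bump, a peak at 180 means
#' the encoded vector is inverted.
#'
#' @param pfn_matrix A bridge [sector_matrix()] of PFNa signals (18 columns;
#'   normalized or raw).
#' @param epg_phase Tibble from [epg_phase_bridge()] on the same clock.
#' @param frames Optional logical/integer frame selector (e.g. within-puff
#'   frames); frames with undefined EPG phase are always excluded.
#' @param res_frac Interpolation resolution in glomeruli (default 0.1).
#' @return Tibble `side`, `rel_angle_deg` (grid over (-180, 180]), `profile`
#'   (mean signal), with the number of averaged frames in attribute
#'   `"n_frames"`.
#' @export
phase_null <- function(pfn_matrix, epg_phase, frames = NULL, res_frac = 0.1) {
  stopifnot(inherits(pfn_matrix, "sector_matrix"))
  geom <- pfn_matrix$geometry
  if (geom$structure != "bridge18") rlang::abort("phase nulling needs a bridge matrix.")
  n_fr <- nrow(pfn_matrix$F)
  sel <- rep(TRUE, n_fr)
  if (!is.null(frames)) {
    sel <- if (is.logical(frames)) frames else seq_len(n_fr) %in% frames
  }
  sel <- sel & epg_phase$defined & !is.na(epg_phase$phase_deg)
  if (!any(sel)) rlang::abort("no frames with a defined EPG phase selected.")
  halves <- list(left = which(geom$pfn_mask & geom$side == "left"),
                 right = which(geom$pfn_mask & geom$side == "right"))
  m <- as.integer(round(8 / res_frac))
  step_deg <- 360 / m
  rel_angle <- wrap_deg(seq(0, 360 - step_deg, by = step_deg))
  idx_sel <- which(sel)
  out <- purrr::imap_dfr(halves, function(cols, side_nm) {
    half_angle0 <- geom$center_deg[cols[1]]
    acc <- numeric(m)
    for (i in idx_sel) {
      prof <- interp_half(pfn_matrix$F[i, cols], res_frac)
      # rotate so the EPG phase lands at relative angle 0: the sample at
      # angle (epg + delta) moves to position delta
      shift <- as.integer(round(circ_diff(epg_phase$phase_deg[i],
                                          half_angle0) / step_deg)) %% m
      acc <- acc + prof[(((seq_len(m) - 1) + shift) %% m) + 1]
    }
    tibble::tibble(side = side_nm, rel_angle_deg = rel_angle,
                   profile = acc / length(idx_sel))
  })
  attr(out, "n_frames") <- length(idx_sel)
  out
}

#' Peak location of a phase-nulled profile
#'
#' Either the PVA phase of the profile over its relative-angle grid
#' (default) or the argmax angle.
#'
#' @param profile Tibble with `rel_angle_deg` and `profile` (one side).
#' @param method `"pva"` or `"argmax"`.
#' @return Peak relative angle in degrees.
#' @export
profile_peak <- function(profile, method = c("pva", "argmax")) {
  method <- match.arg(method)
  v <- profile$profile
  a <- profile$rel_angle_deg
  if (method == "argmax") return(a[which.max(v)])
  v0 <- v - min(v)
  if (sum(v0) <= 0) return(NA_real_)
  th <- deg2rad(a)
  wrap_deg(rad2deg(atan2(sum(v0 * sin(th)), sum(v0 * cos(th)))))
}

#' Circular phase-offset statistics between two phase series
#'
#' Computes per-frame circular differences `a - b` over a selected window,
#' their circular-mean offset, and the per-degree histogram density of the
#' offsets (integrating to 1 over 360 degrees) together with its mean within
#' +/-10 degrees of zero (the "frontal 20 degrees" summary).
#'
#' @param phase_a,phase_b Tibbles with `t` and `phase_deg` on a common clock
#'   (and optionally `valid`/`defined` flags, which are respected).
#' @param frames Optional logical/integer frame selector.
#' @param bin_deg Histogram bin width in degrees (default 20).
#' @return List with `offsets` (tibble `t`, `offset_deg`), `mean_offset_deg`,
#'   `resultant`, `density` (tibble `bin_center_deg`, `density`) and
#'   `frontal_density` (mean per-degree density within +/-10 degrees).
#' @export
phase_offset_stats <- function(phase_a, phase_b, frames = NULL, bin_deg = 20) {
  stopifnot(nrow(phase_a) == nrow(phase_b))
  ok <- !is.na(phase_a$phase_deg) & !is.na(phase_b$phase_deg)
  if ("valid" %in% names(phase_a)) ok <- ok & phase_a$valid
  if ("valid" %in% names(phase_b)) ok <- ok & phase_b$valid
  if (!is.null(frames)) {
    sel <- if (is.logical(frames)) frames else seq_len(nrow(phase_a)) %in% frames
    ok <- ok & sel
  }
  if (!any(ok)) rlang::abort("empty frame selection.")
  off <- circ_diff(phase_a$phase_deg[ok], phase_b$phase_deg[ok])
  cm <- circ_mean(off)
  edges <- seq(-180, 180, by = bin_deg)
  counts <- tabulate(findInterval(off, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  density <- counts / sum(counts) / bin_deg   # per-degree, integrates to 1
  centers <- edges[-1] - bin_deg / 2
  frontal <- sum(abs(off) <= 10) / length(off) / 20
  list(
    offsets = tibble::tibble(t = phase_a$t[ok], offset_deg = off),
    mean_offset_deg = cm$mean_deg,
    resultant = cm$resultant,
    density = tibble::tibble(bin_center_deg = centers, density = density),
    frontal_density = frontal
  )
}
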