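#' Wrap angles into (-180, 180] degrees
#'
#' All angles in the package are degrees with 0 = directly in front of the
#' fly, 180 = directly behind, negative angles to the fly's left and positive
#' angles to its right. `wrap_deg()` reduces any finite angle to the canonical
#' representative in (-180, 180]; 180 is preferred over -180 so that every
#' equivalence class has exactly one representative.
#'
#' @param x Numeric vector of angles in degrees. Must be finite.
#' @return Numeric vector of the same length, in (-180, 180].
#' @examples
#' wrap_deg(c(190, -180, 45, 360))
#' @export
wrap_deg <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    rlang::abort("`x` must be finite numeric angles in degrees.")
  }
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular difference a - b
#'
#' Angular subtraction wrapped into (-180, 180]. The tie at the half-turn is
#' resolved to +180 by the wrapping convention, so `circ_diff(0, 180)` is 180.
#'
#' @param a,b Angles in degrees (vectors are recycled as usual).
#' @return `wrap_deg(a - b)`.
#' @examples
#' circ_diff(170, -170)  # -20
#' @export
circ_diff <- function(a, b) wrap_deg(a - b)

#' Weighted circular mean (resultant-vector mean)
#'
#' The mean direction of a set of angles is the phase of the (weighted)
#' resultant vector, the convention of Fisher & Lee. When the resultant length
#' is numerically zero (balanced angles) the mean is undefined; this is
#' reported explicitly rather than returning an arbitrary angle.
#'
#' @param angles Angles in degrees; at least one.
#' @param weights Optional non-negative weights, same length, not all zero.
#' @param tol Resultant length (normalized to total weight) below which the
#'   mean is flagged undefined.
#' @return A one-row tibble with columns `mean_deg` (NA when undefined),
#'   `resultant` (normalized resultant length in `[0, 1]`) and `defined`.
#' @examples
#' circ_mean(c(10, 350))           # mean 0
#' circ_mean(c(0, 120, 240))       # undefined, resultant 0
#' @export
circ_mean <- function(angles, weights = NULL, tol = 1e-9) {
  if (length(angles) < 1) rlang::abort("`angles` must contain at least one angle.")
  angles <- wrap_deg(angles)
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles)) {
    rlang::abort("`weights` must have the same length as `angles`.")
  }
  if (any(weights < 0) || all(weights == 0)) {
    rlang::abort("`weights` must be non-negative and not all zero.")
  }
  th <- deg2rad(angles)
  cx <- sum(weights * cos(th))
  sx <- sum(weights * sin(th))
  r <- sqrt(cx^2 + sx^2) / sum(weights)
  defined <- r > tol
  tibble::tibble(
    mean_deg = if (defined) wrap_deg(rad2deg(atan2(sx, cx))) else NA_real_,
    resultant = r,
    defined = defined
  )
}

#' Sector geometries of central-complex structures
#'
#' Maps each anatomical sector (protocerebral-bridge glomerulus, ellipsoid-body
#' wedge, fan-shaped-body column, nodulus side) to the angle it represents.
#'
#' Conventions:
#' * `bridge18`: 18 glomeruli numbered left to right when viewed from
#'   posterior; glomeruli 1-9 form the left half and 10-18 the right half.
#'   Angles advance uniformly by 45 degrees per glomerulus across the bridge,
#'   so each half tiles 360 degrees and the two copies of any activity bump
#'   sit exactly eight glomeruli apart. PFN neurons do not
#'   innervate the medial-most pair (9, 10); EPG neurons do not innervate the
#'   lateral-most pair (1, 18).
#' * `eb16` / `fb16`: 16 sectors tiling 360 degrees in equal 22.5-degree
#'   steps. Wedge 1 and wedge 16 of the ellipsoid body flank the ventral
#'   bisector (the +/-180 boundary); fan-shaped-body column k corresponds
#'   functionally to wedge k, with column 1 leftmost viewed from posterior.
#' * `noduli2`: the two nodulus sides carry bulk (vector-length) signals, not
#'   angles; their nominal angles are set to NA.
#'
#' @param structure One of `"bridge18"`, `"eb16"`, `"fb16"`, `"noduli2"`.
#' @return An object of class `sector_geometry`: a list with `structure`,
#'   `n_sectors`, `center_deg` (angle per sector, degrees) and, for the
#'   bridge, logical masks `pfn_mask` / `epg_mask` and a `side` factor.
#' @examples
#' sector_geometry("eb16")$center_deg
#' @export
sector_geometry <- function(structure = c("bridge18", "eb16", "fb16", "noduli2")) {
  structure <- match.arg(structure)
  g <- switch(structure,
    bridge18 = {
      # one uniform 45-degree advance per glomerulus across the whole bridge,
      # so the two copies of any heading bump sit exactly 8 glomeruli apart
      list(
        structure = "bridge18", n_sectors = 18L,
        center_deg = wrap_deg(45 * (0:17)),
        pfn_mask = c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 8)),
        epg_mask = c(FALSE, rep(TRUE, 16), FALSE),
        side = factor(rep(c("left", "right"), each = 9), levels = c("left", "right"))
      )
    },
    eb16 = list(
      structure = "eb16", n_sectors = 16L,
      center_deg = wrap_deg(-180 + (seq_len(16) - 0.5) * 22.5)
    ),
    fb16 = list(
      structure = "fb16", n_sectors = 16L,
      center_deg = wrap_deg(-180 + (seq_len(16) - 0.5) * 22.5)
    ),
    noduli2 = list(
      structure = "noduli2", n_sectors = 2L,
      center_deg = c(NA_real_, NA_real_)
    )
  )
  structure(g, class = "sector_geometry")
}

#' @export
print.sector_geometry <- function(x, ...) {
  cat("<sector_geometry> ", x$structure, " (", x$n_sectors, " sectors)\n", sep = "")
  invisible(x)
}

#' Population vector average of a sector profile
#'
#' The standard phasor read-out of a population profile: the phase is the
#' angle of the resultant vector of sector activities placed at their sector
#' angles, the strength is the resultant length normalized by the total
#' activity (in `[0, 1]`), and the amplitude is the half peak-to-trough of the
#' best-fitting single-cycle sinusoid (the least-squares cosine amplitude).
#'
#' @param profile Non-negative activity per sector (length `n_sectors`).
#' @param geometry A [sector_geometry()] whose sectors carry angles.
#' @return One-row tibble: `phase_deg` (NA when undefined), `strength`,
#'   `amplitude`, `defined`.
#' @examples
#' g <- sector_geometry("eb16")
#' pva(1 + cos(pi / 180 * (g$center_deg - 60)), g)
#' @export
pva <- function(profile, geometry) {
  stopifnot(inherits(geometry, "sector_geometry"))
  if (length(profile) != geometry$n_sectors) {
    rlang::abort("`profile` length must equal the geometry's sector count.")
  }
  if (anyNA(profile) || any(!is.finite(profile))) {
    rlang::abort("`profile` must be finite.")
  }
  th <- deg2rad(geometry$center_deg)
  total <- sum(profile)
  cx <- sum(profile * cos(th))
  sx <- sum(profile * sin(th))
  res <- sqrt(cx^2 + sx^2)
  defined <- total > 0 && res / total > 1e-12
  # least-squares single-cycle sinusoid: profile ~ c + a*cos(th) + b*sin(th)
  X <- cbind(1, cos(th), sin(th))
  cf <- stats::.lm.fit(X, profile)$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  tibble::tibble(
    phase_deg = if (defined) wrap_deg(rad2deg(atan2(sx, cx))) else NA_real_,
    strength = if (total > 0) res / total else NA_real_,
    amplitude = amp,
    defined = defined
  )
}

#' Signed cosine projection of a profile onto a reference phase
#'
#' Least-squares coefficient of `cos(theta - ref_phase)` for a sector profile.
#' A negative value means the profile is phase-inverted (peak near
#' `ref_phase + 180`); the decoder uses this to split population signals into
#' aligned (sodium-spike) and inverted (calcium-spike) phasor components.
#'
#' @param profile Values per sector.
#' @param ref_phase_deg Reference phase in degrees.
#' @param geometry A [sector_geometry()].
#' @return Signed amplitude (same units as `profile`).
#' @examples
#' g <- sector_geometry("fb16")
#' cosine_projection(2 * cos(pi / 180 * (g$center_deg - 30)), 30, g)
#' @export
cosine_projection <- function(profile, ref_phase_deg, geometry) {
  stopifnot(inherits(geometry, "sector_geometry"))
  if (length(profile) != geometry$n_sectors) {
    rlang::abort("`profile` length must equal the geometry's sector count.")
  }
  th <- deg2rad(geometry$center_deg - ref_phase_deg)
  x <- cos(th)
  # least-squares slope with intercept, robust to asymmetric geometries
  X <- cbind(1, x)
  stats::.lm.fit(X, profile)$coefficients[2]
}

# cosine projection on an arbitrary dense angle grid (degrees); used by the
# decoder on interpolated phase-nulled profiles.
cosine_projection_grid <- function(values, angle_deg, ref_phase_deg = 0) {
  x <- cos(deg2rad(angle_deg - ref_phase_deg))
  X <- cbind(1, x)
  stats::.lm.fit(X, values)$coefficients[2]
}
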