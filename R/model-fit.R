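map_design <- function(map, side) {
  td <- tidy(map)
  td <- td[td$populated & !is.na(td$mean), , drop = FALSE]
  s <- airflow_shift_deg(side)
  list(
    H = td$heading_deg, W = td$airflow_deg, y = td$mean,
    cosH = cos(deg2rad(td$heading_deg)),
    cosW = cos(deg2rad(td$airflow_deg + s))
  )
}

# R^2 for fit objects: NA (rather than an error) for zero-variance data
safe_r2 <- function(pred, data) {
  if (sum((data - mean(data))^2) == 0) return(NA_real_)
  variance_explained(pred, data)
}

new_pfna_fit <- function(kind, params, side, r2, data, pred, convergence = NA) {
  structure(list(kind = kind, params = params, side = side, r2 = r2,
                 n = length(data), data = data, pred = pred,
                 convergence = convergence),
            class = c(paste0("pfna_fit_", kind), "pfna_fit"))
}

#' @export
print.pfna_fit <- function(x, ...) {
  cat(sprintf("<pfna_fit:%s> side=%s  %s  R2=%.4f (n=%d)\n", x$kind, x$side,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = " "), x$r2, x$n))
  invisible(x)
}

#' @exportS3Method
tidy.pfna_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method
glance.pfna_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, side = x$side, r.squared = x$r2, nobs = x$n,
                 convergence = x$convergence)
}

#' Fit the sum-of-sinusoids membrane-potential model
#'
#' Fits `Vm = a0 + aH cos(H) + aW cos(W + s 45)` to a conjunctive map by
#' linear least squares over its populated cells (the model is linear in
#' the three parameters). `H` is the map's heading axis, assumed centered on
#' the cell's preferred direction; `s` is +1 for left and -1 for right.
#'
#' @param map A [conjunctive_map()] of membrane potential.
#' @param side `"left"` or `"right"`.
#' @return A `pfna_fit` with parameters `a0`, `aH`, `aW` and `r2`; inspect
#'   with [tidy()] / [glance()].
#' @export
fit_vm <- function(map, side = c("right", "left")) {
  side <- match.arg(side)
  d <- map_design(map, side)
  if (length(d$y) < 4) rlang::abort("need at least 4 populated cells.")
  X <- cbind(a0 = 1, aH = d$cosH, aW = d$cosW)
  if (qr(X)$rank < 3) rlang::abort("rank-deficient design: map does not span both axes.")
  fit <- stats::lm.fit(X, d$y)
  pred <- X %*% fit$coefficients
  new_pfna_fit("vm", stats::setNames(fit$coefficients, c("a0", "aH", "aW")),
               side, safe_r2(pred, d$y), d$y, as.vector(pred),
               convergence = 0)
}

rectified_fit <- function(d, side, kind) {
  neg <- kind == "osc"
  has_c0 <- kind == "osc"
  resid_fn <- function(par) {
    u <- par[["bH"]] * d$cosH + par[["bW"]] * d$cosW
    pred <- if (neg) pmin(u, 0)^2 else pmax(u, 0)^2
    if (has_c0) pred <- pred + par[["c0"]]
    pred - d$y
  }
  scale0 <- sqrt(max(mean(abs(d$y)), .Machine$double.eps))
  starts <- expand.grid(bH = c(-1, 1) * scale0, bW = c(-1, 1) * scale0)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(bH = starts$bH[i], bW = starts$bW[i])
    if (has_c0) par0 <- c(c0 = max(min(d$y), 0), par0)
    res <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      sse <- sum(res$fvec^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = res, sse = sse)
    }
  }
  if (is.null(best)) rlang::abort("rectified-model fit failed to converge from every start.")
  par <- best$fit$par
  # the positively rectified surface is invariant under a joint sign flip of
  # (bH, bW); canonicalize bH >= 0 (the negatively rectified one is not)
  if (kind == "rate" && par[["bH"]] < 0) {
    par[["bH"]] <- -par[["bH"]]
    par[["bW"]] <- -par[["bW"]]
  }
  pred <- resid_fn(par) + d$y
  list(par = par, pred = pred, info = best$fit$info)
}

#' Fit the rectified-quadratic sodium-spike-rate model
#'
#' Fits `r = [bH cos(H) + bW cos(W + s 45)]+^2` (positive rectification,
#' then squaring) by multi-start nonlinear least squares over the populated
#' cells of a conjunctive spike-rate map. The surface is invariant under a
#' joint sign flip of `(bH, bW)`, which is resolved by reporting `bH >= 0`.
#'
#' @inheritParams fit_vm
#' @param map A [conjunctive_map()] of sodium-spike rate.
#' @return A `pfna_fit` with parameters `bH`, `bW`.
#' @export
fit_rate <- function(map, side = c("right", "left")) {
  side <- match.arg(side)
  d <- map_design(map, side)
  if (length(d$y) < 4) rlang::abort("need at least 4 populated cells.")
  r <- rectified_fit(d, side, "rate")
  new_pfna_fit("rate", stats::setNames(r$par[c("bH", "bW")], c("bH", "bW")),
               side, safe_r2(r$pred, d$y), d$y, r$pred,
               convergence = r$info)
}

#' Fit the reverse-rectified oscillation-power model
#'
#' Fits `p = c0 + [cH cos(H) + cW cos(W + s 45)]-^2` (negative
#' rectification, then squaring) to a conjunctive 2-6 Hz band-power map,
#' with the same multi-start scheme as [fit_rate()].
#'
#' @inheritParams fit_vm
#' @param map A [conjunctive_map()] of oscillation band power.
#' @return A `pfna_fit` with parameters `c0`, `cH`, `cW`.
#' @export
fit_osc <- function(map, side = c("right", "left")) {
  side <- match.arg(side)
  d <- map_design(map, side)
  if (length(d$y) < 4) rlang::abort("need at least 4 populated cells.")
  r <- rectified_fit(d, side, "osc")
  par <- stats::setNames(r$par[c("c0", "bH", "bW")], c("c0", "cH", "cW"))
  new_pfna_fit("osc", par, side, safe_r2(r$pred, d$y), d$y,
               r$pred, convergence = r$info)
}

#' Fraction of variance explained
#'
#' `1 - SSE / SST` over paired prediction/data values (populated cells
#' only); NA pairs are dropped.
#'
#' @param prediction,data Numeric vectors or matrices of equal shape.
#' @return Scalar fraction (can be negative for bad predictions).
#' @export
variance_explained <- function(prediction, data) {
  p <- as.vector(prediction)
  d <- as.vector(data)
  ok <- !is.na(p) & !is.na(d)
  p <- p[ok]; d <- d[ok]
  sst <- sum((d - mean(d))^2)
  if (sst == 0) rlang::abort("zero-variance data.")
  1 - sum((d - p)^2) / sst
}

#' Quadratic fit of the combined output versus membrane potential
#'
#' The sodium-spike rate and the 2-6 Hz power each depend on Vm on one side
#' of a threshold; min-max normalized to `[0, 1]` and summed, the combined
#' output is approximately a full (unrectified) quadratic function of the
#' baseline-referenced membrane potential. This fits that degree-2
#' polynomial by least squares.
#'
#' @param vm Baseline-referenced membrane potential values (the heading
#'   curve minimum subtracted).
#' @param rate,power Paired response values (same length as `vm`); each is
#'   min-max normalized to `[0, 1]` before summation. Alternatively supply
#'   `combined` directly.
#' @param combined Optional pre-combined response (overrides rate/power).
#' @return List of class `quadratic_io_fit`: `coefficients` (quadratic,
#'   linear, constant), `r2`, and the fitted tibble `data`.
#' @export
fit_quadratic_io <- function(vm, rate = NULL, power = NULL, combined = NULL) {
  if (is.null(combined)) {
    if (is.null(rate) || is.null(power)) {
      rlang::abort("supply `combined`, or both `rate` and `power`.")
    }
    combined <- minmax01(rate) + minmax01(power)
  }
  ok <- !is.na(vm) & !is.na(combined)
  vm <- vm[ok]; combined <- combined[ok]
  if (length(unique(vm)) < 3) rlang::abort("need at least 3 distinct Vm values.")
  X <- cbind(vm^2, vm, 1)
  fit <- stats::lm.fit(X, combined)
  pred <- as.vector(X %*% fit$coefficients)
  structure(list(
    coefficients = stats::setNames(fit$coefficients,
                                   c("quadratic", "linear", "constant")),
    r2 = variance_explained(pred, combined),
    data = tibble::tibble(vm = vm, combined = combined, fitted = pred)
  ), class = "quadratic_io_fit")
}

minmax01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) rlang::abort("cannot min-max normalize a constant curve.")
  (x - r[1]) / (r[2] - r[1])
}

#' @export
print.quadratic_io_fit <- function(x, ...) {
  cat(sprintf("<quadratic_io_fit> %.4g vm^2 + %.4g vm + %.4g  (R2=%.3f)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3], x$r2))
  invisible(x)
}

#' @exportS3Method
tidy.quadratic_io_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}
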