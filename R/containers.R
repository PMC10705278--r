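#' Construct an electrophysiology trace
#'
#' A uniformly sampled membrane-potential record. The native acquisition rate
#' of the experiments this package emulates is 10 kHz, so storing a time
#' column per sample would be wasteful; the trace keeps `t0` and `fs` and
#' materializes times on demand via [as_tibble()][tibble::as_tibble].
#'
#' @param vm Membrane potential in mV, one value per sample, finite.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param injected_current Optional current trace in pA (same length).
#' @param trials Optional tibble of stimulus annotations with columns
#'   `airflow_direction`, `onset_time`, `duration`, `block_index`.
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(vm, fs = 10000, t0 = 0, injected_current = NULL,
                        trials = NULL) {
  if (anyNA(vm) || any(!is.finite(vm))) rlang::abort("`vm` must be finite.")
  if (!is.null(injected_current) && length(injected_current) != length(vm)) {
    rlang::abort("`injected_current` must match `vm` in length.")
  }
  structure(
    list(vm = as.numeric(vm), fs = fs, t0 = t0,
         injected_current = injected_current, trials = trials),
    class = "ephys_trace"
  )
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %d samples @ %g Hz (%.1f s), %d trials\n",
              length(x$vm), x$fs, length(x$vm) / x$fs,
              if (is.null(x$trials)) 0L else nrow(x$trials)))
  invisible(x)
}

#' @exportS3Method
as_tibble.ephys_trace <- function(x, ...) {
  tibble::tibble(t = x$t0 + (seq_along(x$vm) - 1) / x$fs, vm = x$vm)
}

trace_times <- function(trace) trace$t0 + (seq_along(trace$vm) - 1) / trace$fs

trace_duration <- function(trace) length(trace$vm) / trace$fs

#' Construct a sector-resolved fluorescence matrix
#'
#' Frames-by-sectors fluorescence from one anatomical structure (bridge
#' glomeruli, ellipsoid-body wedges, fan-shaped-body columns or nodulus
#' sides), tagged with its [sector_geometry()] and normalization state.
#'
#' @param F Numeric matrix, frames x sectors. Raw fluorescence must be
#'   non-negative.
#' @param t Frame times in seconds (length `nrow(F)`).
#' @param geometry A [sector_geometry()] or a structure name accepted by it.
#' @param normalization One of `"raw"`, `"dff"`, `"range"`, `"zscore"`.
#' @return An object of class `sector_matrix`.
#' @export
sector_matrix <- function(F, t, geometry,
                          normalization = c("raw", "dff", "range", "zscore")) {
  if (is.character(geometry)) geometry <- sector_geometry(geometry)
  stopifnot(inherits(geometry, "sector_geometry"))
  normalization <- match.arg(normalization)
  F <- as.matrix(F)
  if (ncol(F) != geometry$n_sectors) {
    rlang::abort(sprintf("`F` must have %d columns for %s.",
                         geometry$n_sectors, geometry$structure))
  }
  if (length(t) != nrow(F)) rlang::abort("`t` must have one entry per frame.")
  if (anyNA(F) || any(!is.finite(F))) rlang::abort("`F` must be finite.")
  if (normalization == "raw" && any(F < 0)) {
    rlang::abort("raw fluorescence must be non-negative.")
  }
  structure(list(F = F, t = as.numeric(t), geometry = geometry,
                 normalization = normalization),
            class = "sector_matrix")
}

#' @export
print.sector_matrix <- function(x, ...) {
  cat(sprintf("<sector_matrix> %s: %d frames x %d sectors [%s]\n",
              x$geometry$structure, nrow(x$F), ncol(x$F), x$normalization))
  invisible(x)
}

#' @exportS3Method
as_tibble.sector_matrix <- function(x, ...) {
  tibble::as_tibble(x$F, .name_repair = ~ paste0("s", seq_along(.x))) |>
    dplyr::mutate(t = x$t, .before = 1) |>
    tidyr::pivot_longer(-"t", names_to = "sector", names_prefix = "s",
                        values_to = "F") |>
    dplyr::mutate(sector = as.integer(.data$sector))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
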