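#' Heading tuning curve with occupancy and behavioral gating
#'
#' Bins a signal time series by the concurrent heading into 36 bins of 10
#' degrees. Samples where the fly is standing (forward speed <= 0.5 mm/s)
#' are excluded, and bins with less than 2 s of occupancy are flagged
#' unpopulated (their means are reported as NA).
#'
#' @param signal Tibble with columns `t` (s) and `value`, on a uniform grid.
#' @param behavior Heading trajectory tibble (`t`, `heading`,
#'   `forward_speed`); headings are matched to the signal grid by
#'   sample-and-hold.
#' @param bin_deg Bin width in degrees (default 10).
#' @param min_occupancy_s Minimum per-bin occupancy (default 2 s).
#' @param speed_gate Forward-speed threshold in mm/s (default 0.5).
#' @return Tibble of class `tuning_curve`: `bin_center_deg`, `mean`,
#'   `occupancy_s`, `populated`.
#' @export
heading_tuning <- function(signal, behavior, bin_deg = 10,
                           min_occupancy_s = 2, speed_gate = 0.5) {
  stopifnot(all(c("t", "value") %in% names(signal)))
  dt <- signal$t[2] - signal$t[1]
  fs_b <- behavior_fs(behavior)
  idx <- pmin(pmax(floor((signal$t - behavior$t[1]) * fs_b) + 1, 1),
              nrow(behavior))
  heading <- behavior$heading[idx]
  moving <- behavior$forward_speed[idx] > speed_gate
  bin_tuning(signal$value[moving], heading[moving], dt, bin_deg,
             min_occupancy_s)
}

bin_tuning <- function(values, angles, dt, bin_deg, min_occupancy_s) {
  n_bins <- as.integer(round(360 / bin_deg))
  # centers at multiples of bin_deg (0 and 180 are centers); half-open bins
  # [center - w/2, center + w/2)
  centers <- wrap_deg(-180 + (seq_len(n_bins) - 1) * bin_deg)
  bin <- (floor((angles + 180 + bin_deg / 2) / bin_deg) %% n_bins) + 1
  occ <- tabulate(bin, nbins = n_bins) * dt
  sums <- rep(0, n_bins)
  agg <- tapply(values, factor(bin, levels = seq_len(n_bins)), sum)
  sums[!is.na(agg)] <- agg[!is.na(agg)]
  populated <- occ >= min_occupancy_s
  means <- ifelse(populated & occ > 0, sums / (occ / dt), NA_real_)
  out <- tibble::tibble(bin_center_deg = centers, mean = means,
                        occupancy_s = occ, populated = populated)
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Preferred heading direction of a tuning curve
#'
#' The angular shift of a normalized cosine that maximizes its Pearson
#' correlation with the tuning curve; ties are broken in favor of the
#' smallest absolute shift.
#'
#' @param curve A [heading_tuning()] curve with at least 3 populated bins.
#' @param step_deg Search resolution in degrees (default 1).
#' @return Preferred direction in degrees.
#' @export
preferred_heading <- function(curve, step_deg = 1) {
  pop <- curve$populated & !is.na(curve$mean)
  if (sum(pop) < 3) rlang::abort("need at least 3 populated bins.")
  y <- curve$mean[pop]
  if (stats::sd(y) == 0) rlang::abort("constant tuning curve has no preferred direction.")
  th <- deg2rad(curve$bin_center_deg[pop])
  shifts <- seq(-180 + step_deg, 180, by = step_deg)
  cors <- vapply(shifts, function(s) {
    stats::cor(y, cos(th - deg2rad(s)))
  }, numeric(1))
  best <- max(cors)
  cand <- shifts[cors >= best - 1e-12]
  cand[which.min(abs(cand))]
}

#' Airflow-direction tuning curve from protocol trials
#'
#' Averages a signal within a post-onset window of each air-puff trial and
#' then across trials of the same direction. The window is `c(0.5, 2.5)` s
#' for electrophysiological signals and `c(2, 4)` s for nodulus calcium.
#'
#' @param signal Tibble `t`, `value` on a uniform grid.
#' @param trials Protocol tibble from [make_protocol()].
#' @param window Post-onset window in seconds (default `c(0.5, 2.5)`).
#' @return Tibble of class `tuning_curve`: `bin_center_deg` (the 12 protocol
#'   directions), `mean`, `n_trials`, `populated`.
#' @export
airflow_tuning <- function(signal, trials, window = c(0.5, 2.5)) {
  stopifnot(all(c("t", "value") %in% names(signal)))
  per_trial <- purrr::pmap_dfr(
    list(trials$airflow_direction, trials$onset_time),
    function(dir, onset) {
      sel <- signal$t >= onset + window[1] & signal$t < onset + window[2]
      tibble::tibble(direction = dir,
                     value = if (any(sel)) mean(signal$value[sel]) else NA_real_)
    }
  )
  dirs <- sort(protocol_directions())
  out <- per_trial |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(mean = mean(.data$value), n_trials = dplyr::n(),
                     .groups = "drop") |>
    dplyr::right_join(tibble::tibble(direction = dirs), by = "direction") |>
    dplyr::arrange(.data$direction) |>
    dplyr::transmute(bin_center_deg = .data$direction, mean = .data$mean,
                     n_trials = dplyr::coalesce(.data$n_trials, 0L),
                     populated = .data$n_trials > 0 & !is.na(.data$mean))
  out$populated[is.na(out$populated)] <- FALSE
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Conjunctive heading-by-airflow tuning map
#'
#' Builds the 18 x 12 grid (20-degree heading bins x the 12 protocol airflow
#' directions, 216 cells) of within-puff signal means, with the heading
#' taken per sample from the concurrent behavior. Grid cells with less than
#' 0.5 s of data are unpopulated.
#'
#' @param signal Tibble `t`, `value` on a uniform grid.
#' @param behavior Heading trajectory tibble.
#' @param trials Protocol tibble.
#' @param min_occupancy_s Occupancy rule (default 0.5 s).
#' @param speed_gate Forward-speed gate in mm/s (default 0.5; set to `-Inf`
#'   to disable).
#' @return Object of class `conjunctive_map`: list with `heading_centers`
#'   (18), `airflow_centers` (12), matrices `mean` and `occupancy_s`
#'   (18 x 12), and `populated`.
#' @export
conjunctive_map <- function(signal, behavior, trials, min_occupancy_s = 0.5,
                            speed_gate = 0.5) {
  stopifnot(all(c("t", "value") %in% names(signal)))
  dt <- signal$t[2] - signal$t[1]
  fs_b <- behavior_fs(behavior)
  idx <- pmin(pmax(floor((signal$t - behavior$t[1]) * fs_b) + 1, 1),
              nrow(behavior))
  heading <- behavior$heading[idx]
  moving <- behavior$forward_speed[idx] > speed_gate
  air <- airflow_at(signal$t, trials)
  sel <- air$on & moving
  h_bin <- (floor((heading[sel] + 190) / 20) %% 18) + 1
  dirs <- sort(protocol_directions())
  w_bin <- match(air$W[sel], dirs)
  v <- signal$value[sel]
  occ <- matrix(0, 18, 12)
  sums <- matrix(0, 18, 12)
  for (k in seq_along(v)) {
    occ[h_bin[k], w_bin[k]] <- occ[h_bin[k], w_bin[k]] + dt
    sums[h_bin[k], w_bin[k]] <- sums[h_bin[k], w_bin[k]] + v[k]
  }
  populated <- occ >= min_occupancy_s
  means <- ifelse(populated & occ > 0, sums / (occ / dt), NA_real_)
  new_conjunctive_map(means, occ, populated)
}

new_conjunctive_map <- function(means, occ = NULL, populated = NULL) {
  if (is.null(occ)) occ <- matrix(Inf, 18, 12)
  if (is.null(populated)) populated <- !is.na(means)
  structure(list(
    heading_centers = wrap_deg(-180 + (seq_len(18) - 1) * 20),
    airflow_centers = sort(protocol_directions()),
    mean = means, occupancy_s = occ, populated = populated
  ), class = "conjunctive_map")
}

#' @export
print.conjunctive_map <- function(x, ...) {
  cat(sprintf("<conjunctive_map> 18 x 12 (%d populated of %d cells)\n",
              sum(x$populated), length(x$populated)))
  invisible(x)
}

#' @exportS3Method
tidy.conjunctive_map <- function(x, ...) {
  tibble::tibble(
    heading_deg = rep(x$heading_centers, times = 12),
    airflow_deg = rep(x$airflow_centers, each = 18),
    mean = as.vector(x$mean),
    occupancy_s = as.vector(x$occupancy_s),
    populated = as.vector(x$populated)
  )
}

# rotate the heading axis of a map by an integer number of 20-degree bins
rotate_heading_bins <- function(map, shift_bins) {
  s <- ((shift_bins %% 18) + 18) %% 18
  if (s == 0) return(map)
  ord <- ((seq_len(18) - 1 + s) %% 18) + 1
  map$mean <- map$mean[ord, , drop = FALSE]
  map$occupancy_s <- map$occupancy_s[ord, , drop = FALSE]
  map$populated <- map$populated[ord, , drop = FALSE]
  map
}

#' Pool conjunctive maps across cells
#'
#' Rotates each cell's heading axis so its preferred heading sits at 0
#' (nearest 20-degree bin) and averages cellwise, ignoring unpopulated
#' cells. With `airflow_null = TRUE` the airflow axis is additionally
#' nulled: left-bridge maps are mirrored about 0 degrees airflow and the
#' pooled airflow axis is relabeled by a -45 degree shift, so that both
#' hemispheres share a common airflow-preference axis peaking at 0.
#'
#' @param maps List of [conjunctive_map()]s.
#' @param preferred Per-cell preferred headings (degrees).
#' @param sides Per-cell `"left"`/`"right"` labels.
#' @param airflow_null Apply the mirror-and-shift airflow nulling.
#' @return A pooled `conjunctive_map`; when `airflow_null = TRUE` its
#'   `airflow_centers` carry the -45-degree relabeled axis.
#' @export
pool_cells <- function(maps, preferred, sides, airflow_null = FALSE) {
  stopifnot(length(maps) == length(preferred), length(maps) == length(sides))
  acc <- matrix(0, 18, 12)
  cnt <- matrix(0, 18, 12)
  occ <- matrix(0, 18, 12)
  for (i in seq_along(maps)) {
    m <- rotate_heading_bins(maps[[i]], round(preferred[i] / 20))
    if (airflow_null && sides[i] == "left") {
      # mirror the airflow axis about 0: direction W -> -W
      ord <- match(wrap_deg(-m$airflow_centers), m$airflow_centers)
      m$mean <- m$mean[, ord, drop = FALSE]
      m$occupancy_s <- m$occupancy_s[, ord, drop = FALSE]
      m$populated <- m$populated[, ord, drop = FALSE]
    }
    ok <- m$populated & !is.na(m$mean)
    acc[ok] <- acc[ok] + m$mean[ok]
    cnt[ok] <- cnt[ok] + 1
    occ <- occ + m$occupancy_s
  }
  means <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out <- new_conjunctive_map(means, occ, cnt > 0)
  if (airflow_null) out$airflow_centers <- wrap_deg(out$airflow_centers - 45)
  out
}
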