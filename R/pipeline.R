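#' Airflow-tube transit time
#'
#' Pressure changes travel through the airflow-delivery tubing at the speed
#' of sound, so a puff command reaches the fly after `length / c` seconds; a
#' one-meter tube costs about 2.9 ms, negligible against the 4 s pulses.
#'
#' @param length_m Tube length in meters (> 0).
#' @param speed_of_sound Speed of sound in m/s (default 343).
#' @return Transit time in milliseconds, reported to 0.1 ms.
#' @examples
#' tube_transit_time(1)     # 2.9
#' @export
tube_transit_time <- function(length_m, speed_of_sound = 343) {
  if (!is.numeric(length_m) || any(length_m <= 0) || speed_of_sound <= 0) {
    rlang::abort("`length_m` and `speed_of_sound` must be positive.")
  }
  round(1000 * length_m / speed_of_sound, 1)
}

#' Default run configuration
#'
#' All processing constants default to the experimental-protocol values this
#' package emulates: 40 ms median kernel, 150-1000 Hz spike band, 6.66 ms
#' refractory period, 1 s Hann rate kernel, 4 s / 20 ms spectrogram windows,
#' 2-6 Hz band, 10-degree heading bins with 2 s occupancy, 18 x 20-degree by
#' 12-direction conjunctive grid with 0.5 s occupancy, 0.5 mm/s forward-speed
#' gate, 5th/95th normalization percentiles, 0.15 PVA strength floor,
#' `[0.5, 2.5]` s electrophysiology and `[2, 4]` s nodulus airflow windows,
#' and conversion factor 0.2.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param n_blocks Protocol blocks.
#' @param n_ephys_cells Cells with simulated Vm traces.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param overrides Named list merged over the defaults.
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1, n_blocks = 3, n_ephys_cells = 2,
                               out_dir = NULL, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    n_blocks = n_blocks,
    n_ephys_cells = n_ephys_cells,
    out_dir = out_dir,
    stages = c("simulate", "process_ephys", "process_imaging", "tune",
               "fit", "decode"),
    median_kernel_s = 0.04,
    spike_band_hz = c(150, 1000),
    refractory_s = 1 / 150,
    spike_threshold_k = 4,
    rate_kernel_s = 1,
    spectrogram_window_s = 4,
    spectrogram_step_s = 0.02,
    power_band_hz = c(2, 6),
    heading_bin_deg = 10,
    heading_min_occupancy_s = 2,
    conjunctive_min_occupancy_s = 0.5,
    speed_gate_mm_s = 0.5,
    pva_strength_floor = 0.15,
    ephys_airflow_window_s = c(0.5, 2.5),
    noduli_airflow_window_s = c(2, 4),
    kappa = 0.2,
    cell_params = list()
  )
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [default_run_config()] values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1
  y$seed <- NULL
  default_run_config(seed = seed, overrides = y)
}

config_hash <- function(cfg) {
  # stable small hash of the serialized config (no external digest
  # dependency); output paths do not affect the scientific identity of a run
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  v <- utf8ToInt(as.character(s))
  sum(v * (seq_along(v) %% 97 + 1)) %% 1e9
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> process-ephys -> process-imaging -> tune -> fit
#' -> decode on a synthetic experiment, with all randomness derived from the
#' single config seed. When `out_dir` is set, tabular results are written as
#' CSV and the summary as JSON.
#'
#' @param config A [default_run_config()] / [read_run_config()] result.
#' @return List of class `run_report`: the dataset, per-cell processed
#'   signals and tuning structures, model fits with a truth-versus-fitted
#'   parameter-recovery table, the decode table, and run metadata
#'   (`seed`, `config_hash`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  report <- list(seed = config$seed, config = config,
                 config_hash = config_hash(config))

  dataset <- rlang::exec(simulate_experiment,
                         n_blocks = config$n_blocks, seed = config$seed,
                         n_ephys_cells = config$n_ephys_cells,
                         !!!config$cell_params)
  report$dataset <- dataset
  if (!"process_ephys" %in% stages) return(finalize_report(report, config))

  cells <- purrr::imap(dataset$vm, function(trace, nm) {
    truth <- dataset$truths[match_cell_truth(dataset, nm), ]
    process_cell(trace, dataset$behavior, dataset$trials, truth, config)
  })
  report$cells <- cells

  if ("fit" %in% stages && length(cells) > 0) {
    report$fits <- purrr::imap_dfr(cells, function(cl, nm) {
      truth <- dataset$truths[match_cell_truth(dataset, nm), ]
      recovery_row(cl, truth, nm)
    })
  }
  if ("decode" %in% stages) {
    report$decode <- decode_protocol(dataset,
                                     decoder_config(kappa = config$kappa))
    report$decode_median_error <- decode_error_summary(report$decode)
  }
  finalize_report(report, config)
}

match_cell_truth <- function(dataset, nm) {
  pick <- c(which(dataset$truths$side == "right")[1],
            which(dataset$truths$side == "left")[1],
            which(dataset$truths$side == "right")[2],
            which(dataset$truths$side == "left")[2])
  pick[as.integer(sub("cell", "", nm))]
}

# full single-cell processing chain: conditioning, spikes, power, tuning,
# conjunctive maps and the three model fits
process_cell <- function(trace, behavior, trials, truth, config) {
  cond <- condition_vm(trace, kernel_s = config$median_kernel_s)
  vm_tbl <- as_tibble(cond) |> dplyr::rename(value = "vm")
  spikes <- detect_sodium_spikes(trace, threshold_k = config$spike_threshold_k,
                                 refractory_s = config$refractory_s,
                                 band = config$spike_band_hz)
  rate <- spike_rate(spikes, vm_tbl$t, width_s = config$rate_kernel_s) |>
    dplyr::rename(value = "rate")
  power <- band_power_2_6(trace, band = config$power_band_hz,
                          window_s = config$spectrogram_window_s,
                          step_s = config$spectrogram_step_s) |>
    dplyr::rename(value = "band_power")

  hcurve <- heading_tuning(vm_tbl, behavior,
                           bin_deg = config$heading_bin_deg,
                           min_occupancy_s = config$heading_min_occupancy_s,
                           speed_gate = config$speed_gate_mm_s)
  pref <- preferred_heading(hcurve)
  base <- baseline_vm(hcurve)

  centered <- center_behavior(behavior, pref)
  maps <- list(
    vm = conjunctive_map(vm_tbl, centered, trials,
                         config$conjunctive_min_occupancy_s,
                         config$speed_gate_mm_s),
    rate = conjunctive_map(rate, centered, trials,
                           config$conjunctive_min_occupancy_s,
                           config$speed_gate_mm_s),
    osc = conjunctive_map(power, centered, trials,
                          config$conjunctive_min_occupancy_s,
                          config$speed_gate_mm_s)
  )
  side <- truth$side
  fits <- list(vm = fit_vm(maps$vm, side), rate = fit_rate(maps$rate, side),
               osc = fit_osc(maps$osc, side))
  list(heading_curve = hcurve, preferred_heading = pref, baseline_vm = base,
       airflow_curve = airflow_tuning(vm_tbl, trials,
                                      config$ephys_airflow_window_s),
       spikes = spikes, power = power, maps = maps, fits = fits, side = side)
}

# express behavior headings relative to a preferred direction, so downstream
# conjunctive maps are built directly on the relative-heading axis
center_behavior <- function(behavior, preferred) {
  behavior$heading <- circ_diff(behavior$heading, preferred)
  behavior
}

recovery_row <- function(cell, truth, nm) {
  f <- cell$fits
  tibble::tibble(
    cell = nm, side = truth$side,
    term = c("a0", "aH", "aW", "bH", "bW", "c0", "cH", "cW"),
    truth = c(truth$a0, truth$aH, truth$aW, truth$bH, truth$bW,
              truth$c0, truth$cH, truth$cW),
    fitted = c(f$vm$params[["a0"]], f$vm$params[["aH"]], f$vm$params[["aW"]],
               f$rate$params[["bH"]], f$rate$params[["bW"]],
               f$osc$params[["c0"]], f$osc$params[["cH"]], f$osc$params[["cW"]]),
    r2 = rep(c(f$vm$r2, f$rate$r2, f$osc$r2), c(3, 2, 3))
  )
}

finalize_report <- function(report, config) {
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, config hash %d\n", x$seed, x$config_hash))
  if (!is.null(x$fits)) {
    cat(sprintf("  parameter recovery: median |rel err| = %.3f\n",
                stats::median(abs(x$fits$fitted - x$fits$truth) /
                                pmax(abs(x$fits$truth), 1e-9))))
  }
  if (!is.null(x$decode_median_error)) {
    cat(sprintf("  decode: median |circular error| = %.1f deg\n",
                x$decode_median_error))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$dataset$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(report$dataset$behavior, file.path(out_dir, "behavior.csv"))
  if (!is.null(report$fits)) {
    readr::write_csv(report$fits, file.path(out_dir, "parameter_recovery.csv"))
  }
  if (!is.null(report$decode)) {
    readr::write_csv(report$decode, file.path(out_dir, "decode.csv"))
  }
  summary <- list(seed = report$seed, config_hash = report$config_hash,
                  decode_median_error = report$decode_median_error)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Write / read a synthetic dataset as a CSV + JSON container
#'
#' The dataset is laid out as a directory: `trials.csv`, `behavior.csv`,
#' `truth.json`, one `vm_<cell>.csv` per trace (time is implicit in the
#' stored rate), and one `imaging_<name>.csv` per sector matrix (first
#' column `t`, then one column per sector).
#'
#' @param dataset A [simulate_experiment()] result.
#' @param dir Directory to create/read.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `pfna_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$trials, file.path(dir, "trials.csv"))
  readr::write_csv(dataset$behavior, file.path(dir, "behavior.csv"))
  jsonlite::write_json(
    list(seed = dataset$seed,
         truths = dataset$truths),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  purrr::iwalk(dataset$vm, function(trace, nm) {
    readr::write_csv(tibble::tibble(vm = trace$vm, fs = trace$fs),
                     file.path(dir, paste0("vm_", nm, ".csv")))
  })
  purrr::iwalk(dataset$imaging, function(m, nm) {
    tb <- tibble::as_tibble(m$F, .name_repair = ~ paste0("s", seq_along(.x)))
    tb <- dplyr::mutate(tb, t = m$t, .before = 1)
    attr(tb, "structure") <- m$geometry$structure
    readr::write_csv(dplyr::mutate(tb, structure = m$geometry$structure),
                     file.path(dir, paste0("imaging_", nm, ".csv")))
  })
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  trials <- readr::read_csv(file.path(dir, "trials.csv"),
                            show_col_types = FALSE)
  behavior <- readr::read_csv(file.path(dir, "behavior.csv"),
                              show_col_types = FALSE)
  vm_files <- list.files(dir, pattern = "^vm_.*\\.csv$", full.names = TRUE)
  vm <- stats::setNames(lapply(vm_files, function(f) {
    tb <- readr::read_csv(f, show_col_types = FALSE)
    ephys_trace(tb$vm, fs = tb$fs[1], trials = trials)
  }), sub("^vm_(.*)\\.csv$", "\\1", basename(vm_files)))
  im_files <- list.files(dir, pattern = "^imaging_.*\\.csv$", full.names = TRUE)
  imaging <- stats::setNames(lapply(im_files, function(f) {
    tb <- readr::read_csv(f, show_col_types = FALSE)
    geom <- sector_geometry(tb$structure[1])
    Fm <- as.matrix(tb[, setdiff(names(tb), c("t", "structure"))])
    sector_matrix(pmax(Fm, 0), tb$t, geom, "raw")
  }), sub("^imaging_(.*)\\.csv$", "\\1", basename(im_files)))
  structure(list(trials = trials, behavior = behavior,
                 truths = tibble::as_tibble(truth$truths), vm = vm,
                 imaging = imaging, seed = truth$seed),
            class = "pfna_dataset")
}
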