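#' Configuration of a synthetic dynamic-microtubule assay
#'
#' Describes one imaging condition: species, tubulin and motor
#' concentrations, how many microtubules are followed, for how long, at what
#' frame interval, and with what tip-localization noise. Defaults mirror the
#' imaging conditions of the assays being emulated: 10-minute observation
#' windows, with a 2 s frame interval and 0.05 um (diffraction-limited)
#' Gaussian tip noise as assumed acquisition parameters.
#'
#' @param species `"porcine"` or `"yeast"`.
#' @param tubulin_um Tubulin concentration (uM).
#' @param kip2_nm Motor concentration (nM).
#' @param n_microtubules Number of microtubules.
#' @param duration_min Observation window (minutes).
#' @param frame_interval_s Frame interval (seconds); must be shorter than the
#'   observation window.
#' @param position_noise_sd_um SD of independent Gaussian tip-position noise
#'   (um).
#' @param seed Optional RNG seed.
#' @return An object of class `assay_config`.
#' @examples
#' assay_config(kip2_nm = 5, n_microtubules = 10, seed = 1)
#' @export
assay_config <- function(species = "porcine", tubulin_um = 12, kip2_nm = 0,
                         n_microtubules = 20, duration_min = 10,
                         frame_interval_s = 2, position_noise_sd_um = 0.05,
                         seed = NULL) {
  stopifnot(duration_min > 0, n_microtubules >= 1, position_noise_sd_um >= 0,
            frame_interval_s > 0, kip2_nm >= 0)
  if (frame_interval_s >= duration_min * 60) {
    rlang::abort("frame_interval_s must be shorter than the observation window")
  }
  structure(list(species = species, tubulin_um = tubulin_um,
                 kip2_nm = kip2_nm,
                 n_microtubules = as.integer(n_microtubules),
                 duration_min = duration_min,
                 frame_interval_s = frame_interval_s,
                 position_noise_sd_um = position_noise_sd_um,
                 seed = seed),
            class = "assay_config")
}

#' Generate sampled, noisy tip-position traces for one condition
#'
#' Simulates `n_microtubules` trajectories (plain two-state dynamics, or the
#' motor-coupled model when `m` and `p` are supplied), samples the
#' piecewise-linear tip position at the frame interval, and adds independent
#' Gaussian localization noise. A single root seed expands into
#' per-microtubule substreams (`sample.int` of the root-seeded stream), so
#' the output is reproducible as a whole and per trace.
#'
#' @param config An [assay_config()].
#' @param d A [dynamics_params()] object; the coupled models take shrinkage
#'   and rescue from it and use its growth/catastrophe entries as the
#'   zero-motor anchors.
#' @param m,p Optional [motor_params()] and [coupling_params()]; if both are
#'   given the motor-coupled simulator is used at `config$kip2_nm`.
#' @param law If `TRUE` (requires `p`), trajectories follow the explicit
#'   length law via [simulate_length_law()] instead of the occupancy model.
#' @return A tibble of traces: `mt_id`, `time_s`, `position_um`, with the
#'   true per-microtubule event logs attached as attribute `truth` (used only
#'   as a test oracle, never by the analysis functions).
#' @examples
#' cfg <- assay_config(n_microtubules = 2, duration_min = 2, seed = 1)
#' tr <- generate_assay(cfg, dynamics_params(0.32, 0.166, 27.6, 0.88))
#' @export
generate_assay <- function(config, d, m = NULL, p = NULL, law = FALSE) {
  stopifnot(inherits(config, "assay_config"))
  if (law && is.null(p)) rlang::abort("law = TRUE requires coupling params p")
  coupled <- !law && !is.null(m) && !is.null(p)
  if (!is.null(config$seed)) set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$n_microtubules)
  frame_t <- seq(0, config$duration_min * 60, by = config$frame_interval_s)
  ids <- sprintf("mt%03d", seq_len(config$n_microtubules))
  truth <- vector("list", config$n_microtubules)
  traces <- purrr::map2(seq_len(config$n_microtubules), sub_seeds, function(i, s) {
    traj <- if (law) {
      simulate_length_law(d, p, conc = config$kip2_nm,
                          t_end = config$duration_min, seed = s)
    } else if (coupled) {
      simulate_coupled(d, m, p, conc = config$kip2_nm,
                       t_end = config$duration_min, seed = s)
    } else {
      simulate_dynamic_instability(d, config$duration_min, seed = s)
    }
    truth[[i]] <<- trajectory_events(traj)
    pos <- trajectory_length_at(traj, frame_t / 60)
    if (config$position_noise_sd_um > 0) {
      pos <- pos + stats::rnorm(length(pos), 0, config$position_noise_sd_um)
    }
    tibble::tibble(mt_id = ids[i], time_s = frame_t, position_um = pos)
  })
  out <- dplyr::bind_rows(traces)
  names(truth) <- ids
  attr(out, "truth") <- dplyr::bind_rows(truth, .id = "mt_id")
  attr(out, "config") <- config
  out
}

#' Generate a single-molecule run table
#'
#' Wraps [simulate_single_molecule_runs()] into the flat record schema used
#' by the exponential fitting functions: one row per motor with run length,
#' run time, end dwell and censoring flags (bleach-terminated records are
#' censored). An optional detection-dropout filter emulates the
#' under-representation of very short runs seen in camera-limited data.
#'
#' @param m A [motor_params()] object.
#' @param n Number of runs (> 0).
#' @param seed Optional RNG seed.
#' @param track_length Track length passed to the simulator (um).
#' @param dropout_below If non-`NULL`, runs shorter than this (um) are
#'   dropped with probability `dropout_prob`.
#' @param dropout_prob Probability of losing a short run.
#' @return A tibble: `run_um`, `run_s`, `end_dwell_s`, `censored`,
#'   `dwell_censored`, `terminated_by`.
#' @examples
#' generate_run_table(motor_params(), 5, seed = 1)
#' @export
generate_run_table <- function(m, n, seed = NULL, track_length = Inf,
                               dropout_below = NULL, dropout_prob = 0.5) {
  if (n <= 0) rlang::abort("n must be positive")
  runs <- simulate_single_molecule_runs(m, n, seed = seed,
                                        track_length = track_length)
  out <- dplyr::select(runs, "run_um", "run_s", "end_dwell_s",
                       "censored", "dwell_censored", "terminated_by")
  if (!is.null(dropout_below)) {
    short <- out$run_um < dropout_below
    drop <- short & stats::runif(nrow(out)) < dropout_prob
    out <- out[!drop, ]
  }
  out
}

fixture_n_microtubules <- function(n_growth, catastrophe_freq, duration_min) {
  # growth phases per trace ~ 1 + f * duration (shrinkage occupies little time)
  max(3L, as.integer(round(n_growth / (1 + catastrophe_freq * duration_min))))
}

#' Write a complete synthetic dataset bundle
#'
#' Generates one assay dataset per condition row (by default, every published
#' porcine and yeast condition, with the number of microtubules chosen so the
#' expected number of growth phases matches the printed event counts), plus a
#' single-molecule run table, and writes everything to `dir` as plain CSV
#' files with a JSON manifest. The manifest separates assay metadata (which
#' the analysis stage may read) from the generating parameters (which it must
#' not); regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory.
#' @param seed Root seed; per-condition seeds are drawn from it.
#' @param conditions Condition table, as from [kip2_conditions()].
#' @param duration_min,frame_interval_s,position_noise_sd_um Assay defaults.
#' @param n_runs Rows in the single-molecule run table.
#' @param overwrite Overwrite an existing bundle directory.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(dir, seed, conditions = kip2_conditions(),
                               duration_min = 10, frame_interval_s = 2,
                               position_noise_sd_um = 0.05,
                               n_runs = 2000, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    rlang::abort("output directory exists and is not empty; use overwrite = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  cond_seeds <- sample.int(.Machine$integer.max, nrow(conditions) + 1L)
  manifest_conditions <- list()
  for (i in seq_len(nrow(conditions))) {
    row <- conditions[i, ]
    d <- as_dynamics_params(row)
    n_mt <- fixture_n_microtubules(row$n_growth, d$catastrophe_freq, duration_min)
    cfg <- assay_config(species = row$species, tubulin_um = row$tubulin_um,
                        kip2_nm = row$kip2_nm, n_microtubules = n_mt,
                        duration_min = duration_min,
                        frame_interval_s = frame_interval_s,
                        position_noise_sd_um = position_noise_sd_um,
                        seed = cond_seeds[i])
    traces <- generate_assay(cfg, d)
    id <- sprintf("%s_%02gnM", row$species, row$kip2_nm)
    readr::write_csv(traces, file.path(dir, paste0("traces_", id, ".csv")),
                     progress = FALSE)
    manifest_conditions[[id]] <- list(
      condition = list(id = id, species = row$species,
                       tubulin_um = row$tubulin_um, kip2_nm = row$kip2_nm,
                       n_microtubules = n_mt, duration_min = duration_min,
                       frame_interval_s = frame_interval_s,
                       trace_file = paste0("traces_", id, ".csv")),
      generator = list(growth_rate = d$growth_rate,
                       catastrophe_freq = d$catastrophe_freq,
                       shrink_rate = d$shrink_rate,
                       rescue_freq = d$rescue_freq,
                       position_noise_sd_um = position_noise_sd_um,
                       seed = cond_seeds[i],
                       shrink_rescue_assumed = is.na(row$shrink_rate %||% NA)))
  }
  runs <- generate_run_table(motor_params(), n_runs, seed = cond_seeds[nrow(conditions) + 1L])
  readr::write_csv(runs, file.path(dir, "single_molecule_runs.csv"),
                   progress = FALSE)
  manifest <- list(
    schema_version = "1.0",
    root_seed = seed,
    assumed_defaults = list(frame_interval_s = frame_interval_s,
                            position_noise_sd_um = position_noise_sd_um,
                            duration_min = duration_min,
                            yeast_shrink_rate_assumed = 27.6,
                            yeast_rescue_freq_assumed = 0),
    run_table = list(file = "single_molecule_runs.csv", n = n_runs),
    conditions = manifest_conditions)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a bundle manifest
#'
#' @param dir Bundle directory written by [make_fixture_suite()].
#' @return The manifest as a list.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) rlang::abort(paste0("no manifest.json in ", dir))
  jsonlite::read_json(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
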