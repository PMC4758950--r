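pipeline_defaults <- function() {
  list(root_seed = 1L,
       output_dir = "mtantenna_output",
       conditions = "published",
       assay = list(duration_min = 10, frame_interval_s = 2,
                    position_noise_sd_um = 0.05, n_runs = 2000),
       analysis = list(bin_edges = kip2_length_bins(), cutoff_um = 4,
                       seed_length_um = 0, freq_denominator = "growth_time"))
}

#' Read and validate a pipeline configuration file
#'
#' A single YAML or JSON file drives the simulate/analyze/report pipeline.
#' Recognised keys: `root_seed`, `output_dir`, `conditions` (`"published"` or
#' a path to a condition CSV), `assay` (`duration_min`, `frame_interval_s`,
#' `position_noise_sd_um`, `n_runs`) and `analysis` (`bin_edges`,
#' `cutoff_um`, `seed_length_um`, `freq_denominator`). Unknown keys are
#' rejected; omitted keys take the documented defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    rlang::abort("config must be a .yaml/.yml or .json file")
  }
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param x A named list of configuration values (possibly partial).
#' @export
as_pipeline_config <- function(x = list()) {
  def <- pipeline_defaults()
  unknown <- setdiff(names(x), names(def))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  for (blk in c("assay", "analysis")) {
    bad <- setdiff(names(x[[blk]]), names(def[[blk]]))
    if (length(bad)) {
      rlang::abort(paste0("unknown config keys in ", blk, ": ",
                          paste(bad, collapse = ", ")))
    }
    def[[blk]][names(x[[blk]])] <- x[[blk]]
  }
  for (k in setdiff(names(x), c("assay", "analysis"))) def[[k]] <- x[[k]]
  stopifnot(is.numeric(def$root_seed), length(def$root_seed) == 1)
  def$analysis$freq_denominator <-
    match.arg(def$analysis$freq_denominator, c("growth_time", "total_time"))
  structure(def, class = "pipeline_config")
}

pipeline_conditions <- function(config) {
  if (identical(config$conditions, "published")) return(kip2_conditions())
  readr::read_csv(config$conditions, show_col_types = FALSE, progress = FALSE)
}

#' Simulate a dataset bundle from a pipeline configuration
#'
#' Runs [make_fixture_suite()] for every condition in the configuration and
#' writes the trace CSVs, run table and manifest under
#' `<output_dir>/bundle`. Every assumed default (frame interval, noise SD,
#' shrinkage/rescue fallbacks) is recorded in the manifest.
#'
#' @param config A `pipeline_config` (or a path to one).
#' @param dir Override the bundle directory.
#' @param overwrite Overwrite an existing bundle.
#' @return The bundle directory, invisibly.
#' @export
pipeline_simulate <- function(config, dir = NULL, overwrite = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir <- dir %||% file.path(config$output_dir, "bundle")
  make_fixture_suite(dir, seed = config$root_seed,
                     conditions = pipeline_conditions(config),
                     duration_min = config$assay$duration_min,
                     frame_interval_s = config$assay$frame_interval_s,
                     position_noise_sd_um = config$assay$position_noise_sd_um,
                     n_runs = config$assay$n_runs, overwrite = overwrite)
  invisible(dir)
}

#' Analyze a simulated (or imported) dataset bundle
#'
#' Segments every trace file listed in the bundle manifest, estimates the
#' per-condition dynamic-instability statistics, and writes a combined
#' per-condition table (CSV shaped like the published tables) plus
#' dose-response saturation fits (JSON). Only the `condition` block of the
#' manifest is read; the generating parameters are never consulted.
#'
#' @param bundle_dir Bundle directory from [pipeline_simulate()].
#' @param out_dir Output directory (default `<bundle_dir>/../results`).
#' @param freq_denominator Passed to [estimate_dynamics()].
#' @return The per-condition results tibble, invisibly.
#' @export
pipeline_analyze <- function(bundle_dir, out_dir = NULL,
                             freq_denominator = "growth_time") {
  manifest <- read_manifest(bundle_dir)
  out_dir <- out_dir %||% file.path(dirname(bundle_dir), "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(manifest$conditions, function(entry) {
    cond <- entry$condition
    traces <- readr::read_csv(file.path(bundle_dir, cond$trace_file),
                              show_col_types = FALSE, progress = FALSE)
    est <- estimate_dynamics(segment_traces(traces),
                             freq_denominator = freq_denominator)
    dplyr::bind_cols(
      tibble::tibble(id = cond$id, species = cond$species,
                     tubulin_um = cond$tubulin_um, kip2_nm = cond$kip2_nm),
      est)
  })
  results <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$species, .data$kip2_nm)
  readr::write_csv(results, file.path(out_dir, "dynamics_estimates.csv"),
                   progress = FALSE)
  fits <- list()
  for (sp in unique(results$species)) {
    sub <- dplyr::filter(results, .data$species == sp)
    if (length(unique(sub$kip2_nm)) >= 4 && any(sub$kip2_nm == 0)) {
      gr <- fit_saturation(sub, response = "growth_rate", conc = "kip2_nm",
                           se = "growth_se")
      fits[[paste0(sp, "_growth")]] <- as.list(tibble::deframe(
        gr$terms[, c("term", "estimate")]))
    }
  }
  jsonlite::write_json(fits, file.path(out_dir, "saturation_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

fmt_pm <- function(est, se, n = NA, digits = 3) {
  if (is.na(est) || is.infinite(est)) return("---")
  s <- if (is.na(se) || is.infinite(se)) signif(est, digits) else
    paste0(signif(est, digits), " ± ", signif(se, 2))
  if (!is.na(n)) paste0(s, " (n = ", n, ")") else s
}

#' Render a plain-text report of per-condition results
#'
#' Writes a Markdown summary: one table per species mirroring the published
#' table layout (unbounded distances printed as dashes), the expected length
#' at the end of the observation window computed from the estimated growth
#' rate and catastrophe frequency, and the growth-rate dose-response fit.
#'
#' @param results Results tibble from [pipeline_analyze()] (or the path to
#'   its `dynamics_estimates.csv`).
#' @param out_file Output path (Markdown).
#' @param t_min Time for the expected-length column (minutes).
#' @return The output path, invisibly.
#' @export
pipeline_report <- function(results, out_file, t_min = 10) {
  if (is.character(results)) {
    if (!file.exists(results)) rlang::abort(paste0("results not found: ", results))
    results <- readr::read_csv(results, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(results) == 0) rlang::abort("no results to report")
  lines <- c("# Microtubule dynamics report", "")
  for (sp in unique(results$species)) {
    sub <- dplyr::filter(results, .data$species == sp)
    lines <- c(lines, paste0("## ", sp, " tubulin (", sub$tubulin_um[1], " µM)"), "",
               paste0("| [motor] (nM) | growth rate (µm/min) | catastrophe freq (1/min) |",
                      " catastrophe distance (µm) | shrinkage rate (µm/min) |",
                      " rescue freq (1/min) | rescue distance (µm) |",
                      " mean length (µm) | expected length at ", t_min, " min (µm) |"),
               "|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      el <- expected_length(dynamics_params(r$growth_rate,
                                            max(0, r$catastrophe_freq)), t_min)
      lines <- c(lines, paste0(
        "| ", r$kip2_nm,
        " | ", fmt_pm(r$growth_rate, r$growth_se, r$n_growth),
        " | ", fmt_pm(r$catastrophe_freq, r$catastrophe_se, r$n_cat),
        " | ", if (is.finite(r$catastrophe_distance))
          signif(r$catastrophe_distance, 3) else "---",
        " | ", fmt_pm(r$shrink_rate, r$shrink_se, r$n_shrink),
        " | ", fmt_pm(r$rescue_freq, r$rescue_se, r$n_rescue),
        " | ", if (is.finite(r$rescue_distance))
          signif(r$rescue_distance, 3) else "---",
        " | ", fmt_pm(r$mean_length_um, r$length_se, r$n_mt),
        " | ", signif(el, 3), " |"))
    }
    lines <- c(lines, "")
    if (length(unique(sub$kip2_nm)) >= 4 && any(sub$kip2_nm == 0)) {
      gr <- fit_saturation(sub, response = "growth_rate", conc = "kip2_nm",
                           se = "growth_se")
      K <- gr$terms$estimate[gr$terms$term == "half_max_conc"]
      lines <- c(lines, paste0(
        "Half-maximal growth stimulation at ≈", signif(K, 2), " nM."), "")
    }
  }
  writeLines(lines, out_file)
  invisible(out_file)
}
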