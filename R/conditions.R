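#' Published per-condition microtubule dynamics (porcine and yeast tubulin)
#'
#' Returns the packaged transcription of the per-condition dynamic-instability
#' parameters measured in dynamic microtubule assays: porcine tubulin at 12 uM
#' (seven Kip2 concentrations, 0-40 nM) and yeast tubulin at 4 uM (five
#' concentrations). Columns carry the mean, its standard error and the event
#' count `n_*` for each statistic; `NA` marks quantities the study did not
#' report (dashes in the tables: shrinkage and rescue in the rare-catastrophe
#' regime, and all yeast shrinkage/rescue columns).
#'
#' @param species `"porcine"`, `"yeast"` or `"all"`.
#' @return A tibble, one row per (species, Kip2 concentration).
#' @examples
#' kip2_conditions("porcine")
#' @export
kip2_conditions <- function(species = c("all", "porcine", "yeast")) {
  species <- match.arg(species)
  read_tbl <- function(f) {
    readr::read_csv(system.file("extdata", f, package = "mtantenna"),
                    show_col_types = FALSE, progress = FALSE)
  }
  porc <- read_tbl("table1_porcine.csv")
  yeast <- read_tbl("table2_yeast.csv")
  out <- dplyr::bind_rows(porc, yeast)
  if (species != "all") out <- dplyr::filter(out, .data$species == .env$species)
  out
}

#' Convert one condition row to simulation parameters
#'
#' Builds a [dynamics_params()] object from one row of [kip2_conditions()].
#' Yeast rows print no shrinkage or rescue columns; for simulation these fall
#' back to a porcine-like shrinkage rate (27.6 um/min) and zero rescue (the
#' assumptions are recorded in generated manifests).
#'
#' @param row A one-row data frame with columns `growth_rate`,
#'   `catastrophe_freq` and optionally `shrink_rate`, `rescue_freq`.
#' @param default_shrink_rate,default_rescue_freq Fallbacks for `NA`/missing
#'   shrinkage and rescue values.
#' @return A [dynamics_params()] object.
#' @examples
#' as_dynamics_params(kip2_conditions("porcine")[1, ])
#' @export
as_dynamics_params <- function(row, default_shrink_rate = 27.6,
                               default_rescue_freq = 0) {
  stopifnot(nrow(row) == 1L)
  get <- function(col, default) {
    v <- if (col %in% names(row)) row[[col]] else NA_real_
    if (is.na(v)) default else v
  }
  dynamics_params(
    growth_rate = row$growth_rate,
    catastrophe_freq = get("catastrophe_freq", 0),
    shrink_rate = get("shrink_rate", default_shrink_rate),
    rescue_freq = get("rescue_freq", default_rescue_freq))
}

#' Length bins used for growth-versus-length profiles
#'
#' The bin edges used for length-resolved growth rates: 0-2, 2-3, 3-4, 4-6,
#' 6-8, 8-12, 12-16 and 16-24 um.
#'
#' @return Numeric vector of bin edges (um).
#' @export
kip2_length_bins <- function() c(0, 2, 3, 4, 6, 8, 12, 16, 24)
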