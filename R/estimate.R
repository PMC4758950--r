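#' Poisson relative standard error
#'
#' The standard error of a frequency estimated from `n` events of a Poisson
#' process is the estimate divided by the square root of the event count.
#'
#' @param estimate Point estimate(s).
#' @param n_events Event count(s), >= 1.
#' @return Standard error(s), same units as `estimate`.
#' @examples
#' relative_se(0.166, 126) # ~0.015
#' @export
relative_se <- function(estimate, n_events) {
  if (any(n_events < 1)) rlang::abort("n_events must be >= 1")
  estimate / sqrt(n_events)
}

#' Elastic force-displacement conversion
#'
#' Displacement of a trapped microsphere under force in a harmonic optical
#' trap: force divided by trap stiffness.
#'
#' @param force_pn Force (pN).
#' @param stiffness_pn_nm Trap stiffness (pN/nm), > 0.
#' @return Displacement (nm).
#' @examples
#' force_displacement(0.5, 0.03) # ~17 nm
#' @export
force_displacement <- function(force_pn, stiffness_pn_nm) {
  if (any(stiffness_pn_nm <= 0)) rlang::abort("stiffness must be positive")
  force_pn / stiffness_pn_nm
}

#' Per-condition dynamic-instability estimates from segmented traces
#'
#' Computes the full set of statistics reported per assay condition: growth
#' and shrinkage rates as the mean of per-phase slopes with their standard
#' errors; the catastrophe frequency as the number of catastrophes divided by
#' the total time in growth (or by the total observation time, see
#' `freq_denominator`), with Poisson standard error [relative_se()]; the
#' observed rescue distance as the total shrinkage distance divided by the
#' number of rescues; the rescue frequency as the shrinkage rate divided by
#' the rescue distance (so the ratio identities hold exactly); catastrophe
#' and rescue distances; and the mean final length.
#'
#' @param seg An `mt_segmentation` from [segment_traces()].
#' @param freq_denominator `"growth_time"` (default) counts catastrophes per
#'   minute of growth, matching the ratio identity between catastrophe
#'   distance, growth rate and catastrophe frequency; `"total_time"` uses the
#'   whole observation time.
#' @param min_fit_frames Growth-phase slopes enter the rate average only when
#'   fitted over at least this many frames; slopes from shorter fragments
#'   (phases chopped to a few frames around transition events) carry noise
#'   far above the between-phase spread and are excluded, as a kymograph
#'   analyst would skip unmeasurably short phases. Phase durations and event
#'   counts still include every segment.
#' @return A one-row tibble of class `mt_dynamics_estimate`.
#' @examples
#' cfg <- assay_config(n_microtubules = 5, duration_min = 5, seed = 3)
#' tr <- generate_assay(cfg, dynamics_params(0.32, 0.166, 27.6, 0.88))
#' estimate_dynamics(segment_traces(tr))
#' @export
estimate_dynamics <- function(seg, freq_denominator = c("growth_time", "total_time"),
                              min_fit_frames = 6) {
  stopifnot(inherits(seg, "mt_segmentation"))
  freq_denominator <- match.arg(freq_denominator)
  segs <- seg$segments
  evs <- seg$events
  growth <- dplyr::filter(segs, .data$kind == "growth")
  shrink <- dplyr::filter(segs, .data$kind == "shrink")
  if (nrow(growth) == 0) rlang::abort("no growth segments found")

  g_use <- !is.na(growth$slope_um_min) & growth$n_fit_frames >= min_fit_frames
  g_slopes <- growth$slope_um_min[g_use]
  s_slopes <- -shrink$slope_um_min[!is.na(shrink$slope_um_min)]
  s_slopes <- s_slopes[s_slopes > 0]
  mean_se <- function(x) {
    n <- length(x)
    c(mean = if (n) mean(x) else NA_real_,
      se = if (n > 1) stats::sd(x) / sqrt(n) else if (n == 1) 0 else NA_real_, n = n)
  }
  g <- mean_se(g_slopes); s <- mean_se(s_slopes)

  growth_time <- sum(growth$t_end_min - growth$t_start_min)
  shrink_time_obs <- sum(shrink$t_end_min - shrink$t_start_min)
  # shrinkage phases detected only through their level shift have unresolved
  # duration; impute it from the measured shrinkage speed
  shrink_dist <- sum(pmax(0, shrink$L_start_um - shrink$L_end_um))
  unresolved <- shrink$t_end_min == shrink$t_start_min
  imputed <- if (any(unresolved) && is.finite(s[["mean"]]) && s[["mean"]] > 0) {
    sum(pmax(0, shrink$L_start_um[unresolved] - shrink$L_end_um[unresolved])) / s[["mean"]]
  } else 0
  shrink_time <- shrink_time_obs + imputed

  n_cat <- sum(evs$kind == "catastrophe")
  n_res <- sum(evs$kind == "rescue")
  denom <- if (freq_denominator == "growth_time") growth_time else
    growth_time + shrink_time

  # catastrophes whose shrinkage excursion is below the detector resolution
  # are invisible; with (near-)exponential excursions the missed fraction is
  # 1 - exp(-delta/x0), with x0 from the truncated-mean identity
  # E[X | X > delta] = delta + x0. Correct the event count accordingly.
  delta <- attr(seg, "resolution_um") %||% {
    opts <- seg$opts
    max(opts$min_shift,
        opts$shift_z * stats::median(seg$diagnostics$sigma_um) *
          sqrt(2 / opts$shift_window))
  }
  extents <- pmax(0, shrink$L_start_um - shrink$L_end_um)
  extents <- extents[extents > delta]
  p_miss <- if (length(extents) >= 10) {
    x0 <- mean(extents) - delta
    if (x0 > 0) min(0.25, 1 - exp(-delta / x0)) else 0
  } else 0
  n_cat_eff <- n_cat / (1 - p_miss)

  f_cat <- if (denom > 0) n_cat_eff / denom else NA_real_
  f_cat_se <- if (n_cat > 0) relative_se(f_cat, n_cat) else NA_real_

  resc_dist <- if (n_res > 0) shrink_dist / n_res else Inf
  f_res <- if (n_res > 0 && is.finite(s[["mean"]])) s[["mean"]] / resc_dist else
    if (n_res == 0) 0 else NA_real_
  f_res_se <- if (n_res > 0 && is.finite(f_res)) relative_se(f_res, n_res) else NA_real_

  cat_dist <- if (is.na(f_cat) || f_cat == 0) Inf else g[["mean"]] / f_cat

  final_len <- growth |>
    dplyr::bind_rows(shrink) |>
    dplyr::group_by(.data$mt_id) |>
    dplyr::slice_max(.data$t_end_min, n = 1, with_ties = FALSE) |>
    dplyr::pull(.data$L_end_um)
  fl <- mean_se(final_len)

  out <- tibble::tibble(
    growth_rate = g[["mean"]], growth_se = g[["se"]], n_growth = as.integer(g[["n"]]),
    shrink_rate = s[["mean"]], shrink_se = s[["se"]], n_shrink = as.integer(s[["n"]]),
    catastrophe_freq = f_cat, catastrophe_se = f_cat_se, n_cat = n_cat,
    rescue_freq = f_res, rescue_se = f_res_se, n_rescue = n_res,
    catastrophe_distance = cat_dist, rescue_distance = resc_dist,
    mean_length_um = fl[["mean"]], length_se = fl[["se"]], n_mt = as.integer(fl[["n"]]),
    growth_time_min = growth_time, shrink_time_min = shrink_time,
    detection_floor_um = delta, missed_fraction = p_miss)
  class(out) <- c("mt_dynamics_estimate", class(out))
  out
}

#' Local growth slopes for length-resolved analysis
#'
#' Splits each growth phase into short sliding windows and fits a local
#' slope in each, so that within-phase changes of growth rate with length
#' (the antenna effect) are resolved. Each window becomes a sub-segment
#' carrying its mean length, slope and duration.
#'
#' @param traces Trace tibble (`mt_id`, `time_s`, `position_um`).
#' @param seg The matching `mt_segmentation`.
#' @param window_frames Frames per local window.
#' @return A tibble of sub-segments: `mt_id`, `L_start_um`, `L_end_um`,
#'   `slope_um_min`, `duration_min`.
#' @export
local_growth_segments <- function(traces, seg, window_frames = 15) {
  stopifnot(inherits(seg, "mt_segmentation"))
  w <- as.integer(window_frames)
  growth <- dplyr::filter(seg$segments, .data$kind == "growth",
                          .data$n_fit_frames >= 2)
  by_mt <- split(traces, traces$mt_id)
  out <- purrr::pmap(
    list(growth$mt_id, growth$t_start_min, growth$t_end_min),
    function(id, t0, t1) {
      tr <- by_mt[[id]]
      t_min <- tr$time_s / 60
      idx <- which(t_min > t0 & t_min < t1)
      if (length(idx) < w) {
        co <- ls_slope(t_min[idx], tr$position_um[idx])
        if (is.na(co[["slope"]])) return(NULL)
        return(tibble::tibble(
          mt_id = id,
          L_start_um = min(tr$position_um[idx]), L_end_um = max(tr$position_um[idx]),
          slope_um_min = co[["slope"]],
          duration_min = t_min[idx[length(idx)]] - t_min[idx[1]]))
      }
      starts <- seq(1L, length(idx) - w + 1L, by = w)
      purrr::map_dfr(starts, function(a) {
        ii <- idx[a:(a + w - 1L)]
        co <- ls_slope(t_min[ii], tr$position_um[ii])
        lev <- co[["intercept"]] + co[["slope"]] * range(t_min[ii])
        tibble::tibble(mt_id = id,
                       L_start_um = max(0, min(lev)), L_end_um = max(0, max(lev)),
                       slope_um_min = co[["slope"]],
                       duration_min = t_min[ii[w]] - t_min[ii[1]])
      })
    })
  dplyr::bind_rows(out)
}

#' Length-binned growth rates
#'
#' Bins growth-phase slopes by filament length. Each (sub-)segment
#' contributes its slope to every bin its length interval crosses, weighted
#' by the time spent in that bin (lengths assumed to change linearly within
#' the segment). Default bin edges are [kip2_length_bins()].
#'
#' @param segments A tibble of growth segments or sub-segments with columns
#'   `L_start_um`, `L_end_um`, `slope_um_min` and `duration_min` (or
#'   `t_start_min`/`t_end_min`).
#' @param bin_edges Strictly increasing bin edges (um).
#' @return A tibble: `bin_lo`, `bin_hi`, `bin_mid`, `mean_rate`, `se`, `n`
#'   (number of contributing segments), `time_min` (total weighted time).
#'   Segments entirely outside all bins are ignored; their count is attached
#'   as attribute `n_outside`.
#' @export
binned_growth_vs_length <- function(segments, bin_edges = kip2_length_bins()) {
  if (any(diff(bin_edges) <= 0)) rlang::abort("bin edges must be strictly increasing")
  segs <- segments
  if (!"duration_min" %in% names(segs)) {
    segs <- dplyr::mutate(segs, duration_min = .data$t_end_min - .data$t_start_min)
  }
  if ("kind" %in% names(segs)) segs <- dplyr::filter(segs, .data$kind == "growth")
  segs <- dplyr::filter(segs, !is.na(.data$slope_um_min), .data$duration_min > 0)
  lo <- pmin(segs$L_start_um, segs$L_end_um)
  hi <- pmax(segs$L_start_um, segs$L_end_um)
  nb <- length(bin_edges) - 1L
  rows <- purrr::map_dfr(seq_len(nb), function(b) {
    a <- bin_edges[b]; z <- bin_edges[b + 1L]
    ov <- pmax(0, pmin(hi, z) - pmax(lo, a))
    span <- pmax(hi - lo, 1e-9)
    w <- segs$duration_min * ov / span
    use <- w > 0
    if (!any(use)) {
      return(tibble::tibble(bin_lo = a, bin_hi = z, bin_mid = (a + z) / 2,
                            mean_rate = NA_real_, se = NA_real_, n = 0L,
                            time_min = 0))
    }
    ww <- w[use]; vv <- segs$slope_um_min[use]
    mu <- sum(ww * vv) / sum(ww)
    n <- sum(use)
    se <- if (n > 1) sqrt(sum(ww * (vv - mu)^2) / sum(ww) / (n - 1)) else NA_real_
    tibble::tibble(bin_lo = a, bin_hi = z, bin_mid = (a + z) / 2,
                   mean_rate = mu, se = se, n = as.integer(n),
                   time_min = sum(ww))
  })
  n_outside <- sum(hi <= bin_edges[1] | lo >= bin_edges[length(bin_edges)])
  attr(rows, "n_outside") <- n_outside
  rows
}

#' Mean catastrophe length for short versus long microtubules
#'
#' Splits catastrophe statistics at a cutoff length (default 4 um, the motor
#' run length): the short-side statistic is the total distance grown while
#' shorter than the cutoff divided by the number of catastrophes at lengths
#' below the cutoff; the long side is the total distance grown while longer
#' than the cutoff divided by the number of catastrophes above it. A side
#' with zero catastrophes is undefined (`NA`) but its grown distance is still
#' reported.
#'
#' @param seg An `mt_segmentation`, or a growth-segment tibble (then `events`
#'   must be given).
#' @param events Event tibble when `seg` is a plain segment table.
#' @param cutoff Cutoff length (um).
#' @param seed_length Stabilized-seed length (um) added to the dynamic length
#'   before applying the cutoff (lengths "including seed").
#' @return A one-row tibble: `short_um`, `long_um`, `n_short`, `n_long`,
#'   `dist_short_um`, `dist_long_um`.
#' @export
catastrophe_length_statistic <- function(seg, events = NULL, cutoff = 4,
                                         seed_length = 0) {
  if (inherits(seg, "mt_segmentation")) {
    segments <- seg$segments
    events <- seg$events
  } else {
    segments <- seg
    if (is.null(events)) rlang::abort("events must be supplied with a plain segment table")
  }
  growth <- dplyr::filter(segments, .data$kind == "growth")
  lo <- pmin(growth$L_start_um, growth$L_end_um) + seed_length
  hi <- pmax(growth$L_start_um, growth$L_end_um) + seed_length
  dist_short <- sum(pmax(0, pmin(hi, cutoff) - pmin(lo, cutoff)))
  dist_long <- sum(pmax(0, hi - pmax(lo, cutoff)))
  cat_len <- events$length_um[events$kind == "catastrophe"] + seed_length
  n_short <- sum(cat_len < cutoff)
  n_long <- sum(cat_len > cutoff)
  tibble::tibble(
    short_um = if (n_short > 0) dist_short / n_short else NA_real_,
    long_um = if (n_long > 0) dist_long / n_long else NA_real_,
    n_short = n_short, n_long = n_long,
    dist_short_um = dist_short, dist_long_um = dist_long)
}
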