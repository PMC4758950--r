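#' Options for tip-trace segmentation
#'
#' Tuning parameters of the two-stage phase detector used by
#' [segment_traces()]. Stage 1 finds shrinkage phases as runs of large
#' per-frame drops (shrinkage moves the tip by far more per frame than either
#' growth or noise). Stage 2 finds catastrophes too fast to resolve as a
#' multi-frame shrinkage phase: because a depolymerizing filament regrows
#' from a lower level, every such event leaves a persistent downward level
#' shift, which is detected by a sliding two-window mean-difference
#' changepoint statistic on the detrended trace.
#'
#' @param min_phase_frames Minimum interior frames for a growth-phase slope
#'   fit.
#' @param slope_threshold Absolute slope (um/min) below which a fitted phase
#'   slope is treated as within noise of stationary (near-zero slopes are
#'   merged into the flanking growth phase; pausing is not a phase class).
#' @param drop_threshold Minimum per-frame drop (um) for a stage-1 shrinkage
#'   candidate; the effective threshold is never below `4.5 * sigma * sqrt(2)`
#'   where `sigma` is the noise SD estimated from the trace.
#' @param confirm_drop Minimum total drop (um) for a single-interval stage-1
#'   run to be confirmed.
#' @param shift_window Half-window (frames) of the stage-2 changepoint
#'   statistic.
#' @param shift_z Detection threshold in noise SDs for stage 2.
#' @param min_shift Minimum detectable level shift (um); shifts below this are
#'   within localization noise and constitute the detector's resolution.
#' @param rescue_min_length Level (um) above which the post-event position is
#'   classified as a rescue rather than full depolymerization to the seed.
#' @return A list of options.
#' @export
segment_options <- function(min_phase_frames = 3, slope_threshold = 0.1,
                            drop_threshold = 0.2, confirm_drop = 0.3,
                            shift_window = 30, shift_z = 4.2,
                            min_shift = 0.06, rescue_min_length = 0.25) {
  list(min_phase_frames = min_phase_frames, slope_threshold = slope_threshold,
       drop_threshold = drop_threshold, confirm_drop = confirm_drop,
       shift_window = as.integer(shift_window), shift_z = shift_z,
       min_shift = min_shift, rescue_min_length = rescue_min_length)
}

ls_slope <- function(t_min, y) {
  # least-squares slope and intercept; t in minutes
  n <- length(y)
  tm <- mean(t_min); ym <- mean(y)
  sxx <- sum((t_min - tm)^2)
  if (n < 2 || sxx == 0) return(c(slope = NA_real_, intercept = NA_real_))
  b <- sum((t_min - tm) * (y - ym)) / sxx
  c(slope = b, intercept = ym - b * tm)
}

# stage-2 level-shift changepoints within one provisional growth span,
# by recursive binary segmentation of the detrended trace
find_level_shifts <- function(t_min, pos, sigma, opts) {
  n <- length(pos)
  k_max <- opts$shift_window
  k_min <- 4L
  if (n < 2L * k_min + 2L) return(integer(0))
  # robust span slope: long-lag displacement median keeps the detrending
  # error well below the smallest detectable shift, while staying immune to
  # the level shifts being searched for
  lag <- max(2L, min(50L, n %/% 4L))
  vhat <- stats::median(pos[(lag + 1):n] - pos[1:(n - lag)]) /
    (lag * (t_min[2] - t_min[1]))
  one_pass <- function(vhat) {
    r <- pos - vhat * t_min
    cs <- cumsum(r)
    win_mean <- function(a, b) (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1)
    accepted <- integer(0)
    recurse <- function(a, b) {
      if (b - a + 1L < 2L * k_min + 2L) return(invisible())
      taus <- (a + k_min - 1L):(b - k_min)
      kk <- pmin(k_max, taus - a + 1L, b - taus)
      s <- vapply(seq_along(taus), function(i) {
        tau <- taus[i]; k <- kk[i]
        win_mean(tau + 1L, tau + k) - win_mean(tau - k + 1L, tau)
      }, numeric(1))
      z <- s / (sigma * sqrt(2 / kk))
      i_best <- which.min(s)
      if (z[i_best] < -opts$shift_z && s[i_best] < -opts$min_shift) {
        tau <- taus[i_best]
        accepted <<- c(accepted, tau)
        recurse(a, tau)
        recurse(tau + 1L, b)
      }
      invisible()
    }
    recurse(1L, n)
    sort(accepted)
  }
  acc1 <- one_pass(vhat)
  # second pass with a sharper slope: pooled least squares over the sub-spans
  # between first-pass shifts (clean of jumps, so LS is unbiased and its
  # error is negligible against the detection floor)
  bounds <- c(0L, acc1, n)
  num <- 0; den <- 0
  for (q in seq_len(length(bounds) - 1L)) {
    a <- bounds[q] + 1L; b <- bounds[q + 1L]
    if (b - a + 1L < 5L) next
    tt <- t_min[a:b]; yy <- pos[a:b]
    sxx <- sum((tt - mean(tt))^2)
    num <- num + sum((tt - mean(tt)) * (yy - mean(yy)))
    den <- den + sxx
  }
  if (den > 0) one_pass(num / den) else acc1
}

segment_one_trace <- function(time_s, position_um, opts) {
  n <- length(position_um)
  if (n < 2 * opts$min_phase_frames) {
    rlang::abort("trace too short: need at least 2 * min_phase_frames frames")
  }
  dt_s <- time_s[2] - time_s[1]
  t_min <- time_s / 60
  dt_min <- dt_s / 60
  d <- diff(position_um)
  sigma <- stats::mad(d) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(stats::sd(d) / sqrt(2), 1e-6)

  # ---- stage 1: runs of large per-frame drops = resolvable shrinkage phases
  thr <- max(opts$drop_threshold, 4.5 * sigma * sqrt(2))
  flagged <- d < -thr
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & (runs$lengths >= 2L |
    vapply(seq_along(runs$values), function(i) {
      runs$values[i] && sum(d[starts[i]:ends[i]]) <= -opts$confirm_drop
    }, logical(1)))
  # a genuine shrinkage phase yields strictly consecutive flagged intervals
  # (the per-frame drop exceeds the threshold by far more than the noise), so
  # distinct runs are distinct phases: rescue-regrow-catastrophe successions
  # frames apart stay separate events
  s1_start <- starts[keep]  # interval indices
  s1_end <- ends[keep]

  # ---- provisional growth spans between stage-1 shrink runs
  span_start <- c(1L, s1_end + 1L)
  span_end <- c(s1_start, n)         # frame indices (inclusive)
  spans <- purrr::map2(span_start, span_end, c)
  spans <- purrr::keep(spans, ~ .x[2] >= .x[1])

  # ---- stage 2: unresolved catastrophes inside growth spans
  s2 <- purrr::map(spans, function(sp) {
    a <- sp[1]; b <- sp[2]
    if (b - a + 1 < 10) return(integer(0))
    a - 1L + find_level_shifts(t_min[a:b], position_um[a:b], sigma, opts)
  })

  # ---- assemble boundaries: each event is (interval index, type)
  s2_idx <- as.integer(unlist(s2))
  bnd <- dplyr::bind_rows(
    tibble::tibble(j = as.integer(s1_start), k = as.integer(s1_end), stage = 1L),
    tibble::tibble(j = s2_idx, k = s2_idx, stage = 2L))
  bnd <- dplyr::arrange(bnd, .data$j)

  segs <- list(); evs <- list()
  add_seg <- function(kind, t0, t1, L0, L1, slope, nfit) {
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      kind = kind, t_start_min = t0, t_end_min = t1,
      L_start_um = L0, L_end_um = L1, slope_um_min = slope,
      n_fit_frames = nfit)
  }
  add_ev <- function(tt, kind, ll) {
    evs[[length(evs) + 1L]] <<- tibble::tibble(
      time_min = tt, kind = kind, length_um = ll)
  }

  # growth-span frame ranges delimited by boundaries
  g_start <- c(1L, bnd$k + 1L)        # first frame of each growth span
  g_end <- c(bnd$j, n)                # last frame of each growth span
  mid <- function(i) t_min[i] + dt_min / 2   # event time inside interval i

  fit_growth <- function(a, b) {
    # drop one boundary frame each side when affordable; frames a..b
    if (b - a + 1 >= opts$min_phase_frames + 2) { a <- a + 1L; b <- b - 1L }
    if (b - a + 1 < opts$min_phase_frames) {
      return(list(slope = NA_real_, intercept = NA_real_, nfit = 0L))
    }
    co <- ls_slope(t_min[a:b], position_um[a:b])
    list(slope = co[["slope"]], intercept = co[["intercept"]],
         nfit = b - a + 1L)
  }
  growth_fits <- purrr::map2(g_start, g_end, fit_growth)
  line_at <- function(fit, tt, fallback) {
    if (is.na(fit$slope)) fallback else fit$intercept + fit$slope * tt
  }

  for (i in seq_len(nrow(bnd) + 1L)) {
    a <- g_start[i]; b <- g_end[i]
    if (b >= a) {
      fit <- growth_fits[[i]]
      t0 <- if (i == 1L) t_min[1] else mid(bnd$k[i - 1L])
      t1 <- if (i <= nrow(bnd)) mid(bnd$j[i]) else t_min[n]
      L0 <- line_at(fit, t0, position_um[a])
      L1 <- line_at(fit, t1, position_um[b])
      add_seg("growth", t0, t1, L0, L1, fit$slope, fit$nfit)
    }
    if (i > nrow(bnd)) break
    j <- bnd$j[i]; k <- bnd$k[i]
    t_cat <- mid(j)
    fit_pre <- growth_fits[[i]]
    L_cat <- max(0, line_at(fit_pre, t_cat, position_um[j]))
    add_ev(t_cat, "catastrophe", L_cat)
    fit_post <- growth_fits[[i + 1L]]
    if (bnd$stage[i] == 1L) {
      censored_end <- k >= n - 1L  # shrinkage runs into the end of the record
      t_end <- if (censored_end) t_min[n] else mid(k)
      L_end <- if (censored_end) position_um[n] else
        max(0, line_at(fit_post, t_end, position_um[k + 1L]))
      sl <- NA_real_; nfit <- 0L
      if (k - 1L >= j + 1L) {   # interior frames guaranteed on the shrink line
        co <- ls_slope(t_min[(j + 1L):k], position_um[(j + 1L):k])
        sl <- co[["slope"]]; nfit <- k - j
      }
      add_seg("shrink", t_cat, max(t_end, t_cat), L_cat, L_end, sl, nfit)
      if (!censored_end) {
        # a rescued filament keeps growing from its valley; a reset dips to
        # the seed, so the next few frames discriminate the two
        floor_lvl <- min(position_um[(k + 1L):min(k + 5L, n)])
        if (min(L_end, floor_lvl) > opts$rescue_min_length) {
          add_ev(t_end, "rescue", L_end)
        } else {
          add_ev(t_end, "reset_to_seed", 0)
        }
      }
    } else {
      # sub-frame shrinkage: persistent level shift, duration unresolved
      L_end <- max(0, line_at(fit_post, t_cat, position_um[k + 1L]))
      if (L_end >= L_cat) L_end <- max(0, position_um[k + 1L])
      floor_lvl <- min(position_um[(k + 1L):min(k + 5L, n)])
      add_seg("shrink", t_cat, t_cat, L_cat, min(L_end, L_cat), NA_real_, 0L)
      if (min(L_end, floor_lvl) > opts$rescue_min_length) {
        add_ev(t_cat, "rescue", L_end)
      } else {
        add_ev(t_cat, "reset_to_seed", 0)
      }
    }
  }

  segments <- dplyr::bind_rows(segs)
  events <- if (length(evs)) dplyr::bind_rows(evs) else
    tibble::tibble(time_min = numeric(), kind = character(), length_um = numeric())
  # stationary record: no transitions and no slope resolvably different
  # from zero
  g_sl <- segments$slope_um_min[segments$kind == "growth"]
  all_noise <- nrow(events) == 0 &&
    (all(is.na(g_sl)) || max(abs(g_sl), na.rm = TRUE) < opts$slope_threshold)
  list(segments = segments, events = events,
       diagnostics = tibble::tibble(sigma_um = sigma, n_frames = n,
                                    all_noise = all_noise))
}

#' Segment tip-position traces into growth and shrinkage phases
#'
#' Decomposes sampled tip-position traces into piecewise-linear growth and
#' shrinkage phases and detects catastrophes (growth to shrinkage) and
#' rescues (shrinkage to regrowth above the seed). Phase slopes are
#' least-squares fits over frames that provably lie within one phase;
#' shrinkage phases too fast to span multiple frames are still detected and
#' counted through the persistent level shift they leave (see
#' [segment_options()]), although their slope is then unresolved (`NA`).
#'
#' @param traces A tibble with columns `mt_id`, `time_s`, `position_um`
#'   (uniformly sampled per microtubule), as produced by [generate_assay()].
#' @param opts Detector options from [segment_options()].
#' @return An object of class `mt_segmentation`: a list of tibbles
#'   `segments` (`mt_id`, `kind`, `t_start_min`, `t_end_min`, `L_start_um`,
#'   `L_end_um`, `slope_um_min`, `n_fit_frames`), `events` (`mt_id`,
#'   `time_min`, `kind`, `length_um`) and `diagnostics`.
#' @examples
#' cfg <- assay_config(n_microtubules = 2, duration_min = 3, seed = 2)
#' tr <- generate_assay(cfg, dynamics_params(0.32, 0.166, 27.6, 0.88))
#' seg <- segment_traces(tr)
#' seg$events
#' @export
segment_traces <- function(traces, opts = segment_options()) {
  stopifnot(all(c("mt_id", "time_s", "position_um") %in% names(traces)))
  by_mt <- split(traces, traces$mt_id)
  res <- purrr::map(by_mt, ~ segment_one_trace(.x$time_s, .x$position_um, opts))
  out <- list(
    segments = dplyr::bind_rows(purrr::map(res, "segments"), .id = "mt_id"),
    events = dplyr::bind_rows(purrr::map(res, "events"), .id = "mt_id"),
    diagnostics = dplyr::bind_rows(purrr::map(res, "diagnostics"), .id = "mt_id"),
    opts = opts)
  class(out) <- "mt_segmentation"
  out
}

#' @export
print.mt_segmentation <- function(x, ...) {
  cat(sprintf("<mt_segmentation> %d traces, %d segments, %d events\n",
              nrow(x$diagnostics), nrow(x$segments), nrow(x$events)))
  invisible(x)
}
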