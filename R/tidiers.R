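#' @export
#' @method tidy mt_dynamics_estimate
tidy.mt_dynamics_estimate <- function(x, ...) {
  tibble::tibble(
    statistic = c("growth_rate", "shrink_rate", "catastrophe_freq",
                  "rescue_freq", "catastrophe_distance", "rescue_distance",
                  "mean_length"),
    estimate = c(x$growth_rate, x$shrink_rate, x$catastrophe_freq,
                 x$rescue_freq, x$catastrophe_distance, x$rescue_distance,
                 x$mean_length_um),
    std.error = c(x$growth_se, x$shrink_se, x$catastrophe_se,
                  x$rescue_se, NA, NA, x$length_se),
    n = c(x$n_growth, x$n_shrink, x$n_cat, x$n_rescue, NA, NA, x$n_mt))
}

#' @export
#' @method glance mt_dynamics_estimate
glance.mt_dynamics_estimate <- function(x, ...) {
  tibble::tibble(n_growth = x$n_growth, n_cat = x$n_cat,
                 n_rescue = x$n_rescue, n_mt = x$n_mt,
                 growth_time_min = x$growth_time_min,
                 shrink_time_min = x$shrink_time_min)
}

#' @export
#' @method tidy mt_segmentation
tidy.mt_segmentation <- function(x, ...) x$segments

#' @export
#' @method glance mt_segmentation
glance.mt_segmentation <- function(x, ...) {
  tibble::tibble(
    n_traces = nrow(x$diagnostics),
    n_growth = sum(x$segments$kind == "growth"),
    n_shrink = sum(x$segments$kind == "shrink"),
    n_catastrophe = sum(x$events$kind == "catastrophe"),
    n_rescue = sum(x$events$kind == "rescue"),
    median_noise_um = stats::median(x$diagnostics$sigma_um))
}
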