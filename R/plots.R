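#' @export
#' @method autoplot mt_trajectory
autoplot.mt_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$length_um)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$phase, group = 1)) +
    ggplot2::labs(x = "time (min)", y = "length (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot mt_fit
autoplot.mt_fit <- function(object, ...) {
  df <- object$data
  td <- object$terms
  est <- function(nm) td$estimate[td$term == nm]
  base_pts <- function(x, y) {
    ggplot2::ggplot(df, ggplot2::aes(x = {{ x }}, y = {{ y }})) +
      ggplot2::geom_point() +
      ggplot2::theme_minimal()
  }
  switch(object$kind,
    saturation = {
      grid <- tibble::tibble(c = seq(0, max(df$c), length.out = 200))
      grid$r <- est("base") + (est("plateau") - est("base")) * grid$c /
        (est("half_max_conc") + grid$c)
      p <- base_pts(.data$c, .data$r) +
        ggplot2::geom_line(data = grid, colour = "red") +
        ggplot2::labs(x = "[motor] (nM)", y = "response")
      if (all(is.finite(df$se))) {
        p <- p + ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data$r - .data$se, ymax = .data$r + .data$se), width = 0)
      }
      p
    },
    length_law = {
      grid <- tidyr::expand_grid(c = unique(df$c),
                                 L = seq(0, max(df$L), length.out = 200))
      grid$v <- est("v0") + (est("vmax") - est("v0")) * grid$c * grid$L /
        (est("A") + grid$c * grid$L)
      ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$v,
                                       colour = factor(.data$c))) +
        ggplot2::geom_point() +
        ggplot2::geom_line(data = grid) +
        ggplot2::labs(x = "length (µm)", y = "growth rate (µm/min)",
                      colour = "[motor] (nM)") +
        ggplot2::theme_minimal()
    },
    exponential = {
      if (!is.null(object$model)) {
        grid <- tibble::tibble(mid = seq(0, max(df$mid), length.out = 200))
        grid$count <- est("A") * exp(-grid$mid / est("x0"))
        ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
          ggplot2::geom_col(width = diff(df$mid)[1] * 0.9, fill = "grey70") +
          ggplot2::geom_line(data = grid, colour = "red") +
          ggplot2::labs(x = "value", y = "count") +
          ggplot2::theme_minimal()
      } else {
        ggplot2::ggplot(tibble::tibble(x = df$x), ggplot2::aes(x = .data$x)) +
          ggplot2::geom_histogram(bins = 30, fill = "grey70") +
          ggplot2::labs(x = "value", y = "count") +
          ggplot2::theme_minimal()
      }
    },
    weighted_linear = {
      base_pts(.data$tub, .data$r) +
        ggplot2::geom_abline(intercept = est("intercept"), slope = est("slope"),
                             colour = "red") +
        ggplot2::labs(x = "[tubulin] (µM)", y = "growth rate (µm/min)")
    },
    rlang::abort(paste0("no autoplot for fit kind ", object$kind)))
}

#' Dose-response overview of per-condition estimates
#'
#' Growth rate and catastrophe frequency (with standard errors) as a
#' function of motor concentration, one panel per statistic.
#'
#' @param estimates A tibble with columns `kip2_nm`, `growth_rate`,
#'   `growth_se`, `catastrophe_freq`, `catastrophe_se` (e.g. the output of
#'   [pipeline_analyze()] or [kip2_conditions()]).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(estimates) {
  long <- dplyr::bind_rows(
    tibble::tibble(kip2_nm = estimates$kip2_nm, value = estimates$growth_rate,
                   se = estimates$growth_se, stat = "growth rate (µm/min)"),
    tibble::tibble(kip2_nm = estimates$kip2_nm, value = estimates$catastrophe_freq,
                   se = estimates$catastrophe_se, stat = "catastrophe frequency (1/min)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kip2_nm, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se), width = 0) +
    ggplot2::facet_wrap(~ .data$stat, scales = "free_y") +
    ggplot2::labs(x = "[motor] (nM)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Measured versus expected length at a fixed time
#'
#' Compares mean lengths with the expected length computed from the growth
#' rate and catastrophe frequency alone (instant-reset approximation,
#' [expected_length()]) across motor concentrations.
#'
#' @param conditions A tibble with `kip2_nm`, `length_um`, `length_se`,
#'   `growth_rate`, `catastrophe_freq`.
#' @param t Time (minutes).
#' @return A ggplot object.
#' @export
plot_expected_length <- function(conditions, t = 10) {
  exp_len <- purrr::map2_dbl(conditions$growth_rate, conditions$catastrophe_freq,
                             ~ expected_length(dynamics_params(.x, .y), t))
  df <- dplyr::mutate(conditions, expected = exp_len)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kip2_nm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$length_um)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$length_um - .data$length_se,
                                        ymax = .data$length_um + .data$length_se),
                           width = 0) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "red") +
    ggplot2::labs(x = "[motor] (nM)", y = paste0("length at ", t, " min (µm)")) +
    ggplot2::theme_minimal()
}
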