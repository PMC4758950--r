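new_mt_fit <- function(kind, terms, data = NULL, vcov = NULL,
                       flags = list(), model = NULL) {
  structure(list(kind = kind, terms = terms, data = data, vcov = vcov,
                 flags = flags, model = model),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("<mt_fit: %s>\n", x$kind))
  print(x$terms)
  if (length(x$flags)) {
    on <- names(x$flags)[vapply(x$flags, isTRUE, logical(1))]
    if (length(on)) cat("flags:", paste(on, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy mt_fit
tidy.mt_fit <- function(x, ...) x$terms

#' @export
#' @method glance mt_fit
glance.mt_fit <- function(x, ...) {
  rss <- if (!is.null(x$model)) tryCatch(stats::deviance(x$model), error = function(e) NA_real_)
    else NA_real_
  tibble::tibble(kind = x$kind,
                 nobs = if (!is.null(x$data)) nrow(x$data) else NA_integer_,
                 rss = rss,
                 flagged = any(vapply(x$flags, isTRUE, logical(1))))
}

fit_term <- function(term, estimate, se = NA_real_) {
  tibble::tibble(term = term, estimate = estimate, std.error = se)
}

#' Fit a single-exponential distribution, with censoring
#'
#' Run lengths and end-residence times of a processive motor are expected to
#' be exponentially distributed (memoryless detachment). The default is the
#' maximum-likelihood estimate of the exponential mean `x0` with
#' right-censored records (e.g. photobleach-terminated runs) handled exactly:
#' `x0 = sum(all values) / number uncensored`. For uncensored data this is
#' the sample mean. The alternative `method = "histogram"` reproduces the
#' histogram least-squares procedure `f(x) = A exp(-x/x0)`, optionally
#' excluding the first bin (short runs are under-represented in
#' camera-limited data).
#'
#' @param x Samples (um or s).
#' @param censored Logical vector: `TRUE` where the record is right-censored.
#' @param method `"mle"` or `"histogram"`.
#' @param bins Number of histogram bins (histogram method).
#' @param drop_first_bin Exclude the first bin from the histogram fit.
#' @return An `mt_fit` with terms `x0` (and `A` for the histogram method).
#' @examples
#' fit_exponential(rexp(200, 1 / 3.6))
#' @export
fit_exponential <- function(x, censored = NULL, method = c("mle", "histogram"),
                            bins = 30, drop_first_bin = FALSE) {
  method <- match.arg(method)
  if (is.null(censored)) censored <- rep(FALSE, length(x))
  keep <- !is.na(x)
  x <- x[keep]; censored <- censored[keep]
  n_unc <- sum(!censored)
  if (n_unc == 0) rlang::abort("all records are censored; the mean is not identifiable")
  if (method == "mle") {
    x0 <- sum(x) / n_unc
    se <- x0 / sqrt(n_unc)
    return(new_mt_fit("exponential", fit_term("x0", x0, se),
                      data = tibble::tibble(x = x, censored = censored),
                      flags = list(censored_fraction = mean(censored))))
  }
  h <- graphics::hist(x[!censored], breaks = bins, plot = FALSE)
  df <- tibble::tibble(mid = h$mids, count = h$counts)
  if (drop_first_bin) df <- df[-1, ]
  df <- dplyr::filter(df, .data$count > 0 | .data$mid < max(.data$mid[.data$count > 0]))
  fit <- minpack.lm::nlsLM(count ~ A * exp(-mid / x0), data = df,
                           start = list(A = max(df$count), x0 = mean(x[!censored])))
  co <- summary(fit)$coefficients
  new_mt_fit("exponential",
             dplyr::bind_rows(fit_term("A", co["A", 1], co["A", 2]),
                              fit_term("x0", co["x0", 1], co["x0", 2])),
             data = df, model = fit)
}

#' Fit a saturating dose-response in motor concentration
#'
#' Weighted least squares of `r(c) = base + (plateau - base) * c / (K + c)`,
#' with weights `1/se^2` when standard errors are supplied. With
#' `plateau = "anchor"` (default) the plateau is fixed at the
#' highest-concentration response and only `base` and the half-maximal
#' concentration `K` are free: on dose-response tables whose top is defined
#' by a single highest dose, the free 3-parameter fit is weakly identified
#' (see the methods vignette). `plateau = "free"` fits all three parameters
#' and flags the result `wide_se` when `K` is not resolved.
#'
#' @param data A data frame.
#' @param response,conc,se Column names of the response, concentration and
#'   (optional) standard error.
#' @param plateau `"anchor"` or `"free"`.
#' @return An `mt_fit` with terms `base`, `plateau`, `half_max_conc`.
#' @examples
#' fit_saturation(kip2_conditions("porcine"),
#'                response = "growth_rate", conc = "kip2_nm", se = "growth_se")
#' @export
fit_saturation <- function(data, response = "rate", conc = "conc", se = NULL,
                           plateau = c("anchor", "free")) {
  plateau <- match.arg(plateau)
  df <- tibble::tibble(r = data[[response]], c = data[[conc]],
                       se = if (!is.null(se)) data[[se]] else NA_real_)
  df <- dplyr::filter(df, !is.na(.data$r), !is.na(.data$c))
  if (length(unique(df$c)) < 4 || !any(df$c == 0)) {
    rlang::abort("need at least 4 concentrations including 0")
  }
  w <- if (all(is.finite(df$se)) && all(df$se > 0)) 1 / df$se^2 else rep(1, nrow(df))
  base0 <- df$r[which.min(df$c)]
  K0 <- stats::median(df$c[df$c > 0])
  top <- stats::weighted.mean(df$r[df$c == max(df$c)], w[df$c == max(df$c)])
  if (plateau == "anchor") {
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ base + (top - base) * c / (K + c), data = df,
                        start = list(base = base0, K = K0), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) rlang::abort("saturation fit failed to converge")
    co <- summary(fit)$coefficients
    top_se <- df$se[which.max(df$c)][1]
    terms <- dplyr::bind_rows(
      fit_term("base", co["base", 1], co["base", 2]),
      fit_term("plateau", top, if (is.finite(top_se)) top_se else NA_real_),
      fit_term("half_max_conc", co["K", 1], co["K", 2]))
    return(new_mt_fit("saturation", terms, data = df, model = fit,
                      flags = list(plateau_anchored = TRUE)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ base + (plat - base) * c / (K + c), data = df,
                      start = list(base = base0, plat = top, K = K0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # no saturation in range: report the data span with wide errors
    terms <- dplyr::bind_rows(
      fit_term("base", base0, Inf),
      fit_term("plateau", top, Inf),
      fit_term("half_max_conc", max(df$c), Inf))
    return(new_mt_fit("saturation", terms, data = df,
                      flags = list(wide_se = TRUE)))
  }
  co <- summary(fit)$coefficients
  terms <- dplyr::bind_rows(
    fit_term("base", co["base", 1], co["base", 2]),
    fit_term("plateau", co["plat", 1], co["plat", 2]),
    fit_term("half_max_conc", co["K", 1], co["K", 2]))
  new_mt_fit("saturation", terms, data = df, model = fit,
             flags = list(wide_se = co["K", 2] > abs(co["K", 1])))
}

#' Fit the length law of motor-stimulated growth
#'
#' Joint weighted nonlinear least squares of
#' `v(L, c) = v0 + (vmax - v0) cL / (A + cL)` over length-binned growth
#' rates measured at several motor concentrations.
#'
#' @param data A data frame of binned rates.
#' @param rate,length,conc,se Column names: mean rate (um/min), bin length
#'   (um), motor concentration (nM), optional SE.
#' @return An `mt_fit` with terms `v0`, `vmax`, `A`. With data at a single
#'   concentration of 0 the saturation parameters are unidentifiable: `v0`
#'   is then the weighted mean rate and the fit is flagged.
#' @export
fit_length_law <- function(data, rate = "mean_rate", length = "bin_mid",
                           conc = "kip2_nm", se = "se") {
  df <- tibble::tibble(v = data[[rate]], L = data[[length]],
                       c = data[[conc]],
                       se = if (se %in% names(data)) data[[se]] else NA_real_)
  df <- dplyr::filter(df, !is.na(.data$v), !is.na(.data$L))
  w <- if (all(is.finite(df$se)) && all(df$se > 0)) 1 / df$se^2 else rep(1, nrow(df))
  if (all(df$c == 0)) {
    v0 <- stats::weighted.mean(df$v, w)
    terms <- dplyr::bind_rows(
      fit_term("v0", v0, sqrt(1 / sum(w))),
      fit_term("vmax", NA_real_), fit_term("A", NA_real_))
    return(new_mt_fit("length_law", terms, data = df,
                      flags = list(unidentifiable = TRUE)))
  }
  if (length(unique(df$c)) < 2) {
    rlang::abort("need bins at >= 2 concentrations (one of them may be 0)")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ v0 + (vmax - v0) * c * L / (A + c * L), data = df,
                      start = list(v0 = min(df$v), vmax = max(df$v),
                                   A = stats::median(df$c * df$L) + 1),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) rlang::abort("length-law fit failed (singular design?)")
  co <- summary(fit)$coefficients
  terms <- dplyr::bind_rows(
    fit_term("v0", co["v0", 1], co["v0", 2]),
    fit_term("vmax", co["vmax", 1], co["vmax", 2]),
    fit_term("A", co["A", 1], co["A", 2]))
  new_mt_fit("length_law", terms, data = df, model = fit)
}

#' Weighted regression of growth rate on tubulin concentration
#'
#' Linear regression of microtubule growth rate (um/min) on free tubulin
#' concentration (uM), weighted by `1/SE^2`. The slope, multiplied by the
#' lattice packing density (1625 dimers/um) and converted to seconds, is the
#' effective second-order tubulin association rate constant k_on; the
#' intercept (converted the same way, in dimers/s) estimates minus the
#' off-rate and is flagged when consistent with zero.
#'
#' @param data A data frame with at least 3 concentrations.
#' @param rate,tubulin,se Column names (rate in um/min, tubulin in uM).
#' @param dimers_per_um Lattice packing density (dimers per um).
#' @return An `mt_fit` of kind `weighted_linear` with terms `slope`,
#'   `intercept` (um/min units), `kon` (uM^-1 s^-1) and `intercept_per_s`
#'   (dimers/s); flag `zero_intercept_consistent`.
#' @export
tubulin_kinetics_regression <- function(data, rate = "rate", tubulin = "tubulin_um",
                                        se = NULL, dimers_per_um = 1625) {
  df <- tibble::tibble(r = data[[rate]], tub = data[[tubulin]],
                       se = if (!is.null(se)) data[[se]] else NA_real_)
  df <- dplyr::filter(df, !is.na(.data$r), !is.na(.data$tub))
  if (nrow(df) < 3) rlang::abort("need at least 3 tubulin concentrations")
  w <- if (all(is.finite(df$se)) && all(df$se > 0)) 1 / df$se^2 else rep(1, nrow(df))
  fit <- stats::lm(r ~ tub, data = df, weights = w)
  co <- summary(fit)$coefficients
  conv <- dimers_per_um / 60
  terms <- dplyr::bind_rows(
    fit_term("slope", co["tub", 1], co["tub", 2]),
    fit_term("intercept", co["(Intercept)", 1], co["(Intercept)", 2]),
    fit_term("kon", kon_from_slope(co["tub", 1], dimers_per_um),
             co["tub", 2] * conv),
    fit_term("intercept_per_s", co["(Intercept)", 1] * conv,
             co["(Intercept)", 2] * conv))
  zero_ok <- abs(co["(Intercept)", 1]) < 2 * co["(Intercept)", 2]
  new_mt_fit("weighted_linear", terms, data = df, model = fit,
             flags = list(zero_intercept_consistent = zero_ok,
                          dimers_per_um = dimers_per_um))
}
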