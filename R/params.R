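#' Dynamic-instability parameters for one assay condition
#'
#' Bundles the four rates of the two-state (growth/shrinkage) model of
#' microtubule dynamic instability. All rates are in micrometres and minutes.
#'
#' @param growth_rate Growth-phase speed \eqn{v_+} (um/min).
#' @param catastrophe_freq Catastrophe frequency \eqn{f_{+-}} (events per
#'   minute of growth). `0` encodes the "very rare" regime.
#' @param shrink_rate Shrinkage-phase speed \eqn{v_-} (um/min, positive).
#' @param rescue_freq Rescue frequency (events per minute of shrinkage).
#'
#' @return An object of class `dynamics_params` (a named list).
#' @examples
#' dynamics_params(0.32, 0.166, 27.6, 0.88)
#' @export
dynamics_params <- function(growth_rate, catastrophe_freq = 0,
                            shrink_rate = 0, rescue_freq = 0) {
  vals <- c(growth_rate = growth_rate, catastrophe_freq = catastrophe_freq,
            shrink_rate = shrink_rate, rescue_freq = rescue_freq)
  if (anyNA(vals) || any(vals < 0)) {
    rlang::abort("all dynamic-instability rates must be non-negative and non-missing")
  }
  structure(as.list(vals), class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf(
    "<dynamics_params> v+ = %.3g um/min, f+- = %.3g /min, v- = %.3g um/min, f-+ = %.3g /min\n",
    x$growth_rate, x$catastrophe_freq, x$shrink_rate, x$rescue_freq))
  invisible(x)
}

#' Motor (kinesin) single-molecule parameters
#'
#' Landing, stepping, detachment, end-residence and photobleaching parameters
#' of a processive plus-end directed kinesin. Defaults are the single-molecule
#' measurements for Kip2: lattice velocity 5.0 +/- 0.9 um/min, mean run length
#' 4.1 um, plus-end residence ~30 s, photobleaching time 249 s, and a plus-end
#' pool that saturates at about 12 motors. On dynamic microtubules the motor
#' moves slower (2.1 um/min) but still faster than the growing end.
#'
#' @param landing_rate Lattice landing rate per um of filament per nM motor
#'   per minute. Not directly measured; the default is calibrated so that the
#'   occupancy model's initial length dependence matches the measured growth
#'   law (see the methods vignette).
#' @param velocity_lattice Velocity on stabilized lattices (um/min).
#' @param velocity_dynamic Velocity on dynamic microtubules (um/min); must not
#'   exceed `velocity_lattice`.
#' @param velocity_sd Between-molecule SD of velocity (um/min).
#' @param run_length Mean run length before lattice detachment (um).
#' @param end_residence Mean plus-end residence time (seconds).
#' @param bleach_time Mean time to photobleaching (seconds); `Inf` disables
#'   bleaching.
#' @param end_capacity Maximum number of motors in the plus-end pool.
#'
#' @return An object of class `motor_params`.
#' @examples
#' motor_params()
#' @export
motor_params <- function(landing_rate = 0.6, velocity_lattice = 5.0,
                         velocity_dynamic = 2.1, velocity_sd = 0.9,
                         run_length = 4.1, end_residence = 30,
                         bleach_time = 249, end_capacity = 12) {
  stopifnot(landing_rate > 0, velocity_lattice > 0, velocity_dynamic > 0,
            velocity_sd >= 0, run_length > 0, end_residence > 0,
            bleach_time > 0, end_capacity >= 1)
  if (velocity_dynamic > velocity_lattice) {
    rlang::abort("velocity_dynamic must not exceed velocity_lattice")
  }
  structure(list(landing_rate = landing_rate,
                 velocity_lattice = velocity_lattice,
                 velocity_dynamic = velocity_dynamic,
                 velocity_sd = velocity_sd,
                 run_length = run_length,
                 end_residence = end_residence,
                 bleach_time = bleach_time,
                 end_capacity = as.integer(end_capacity)),
            class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf(
    paste0("<motor_params> landing %.3g /um/nM/min; v %.3g (lattice) / %.3g (dynamic) um/min;\n",
           "  run length %.3g um; end residence %.3g s; bleach %.3g s; end capacity %d\n"),
    x$landing_rate, x$velocity_lattice, x$velocity_dynamic, x$run_length,
    x$end_residence, x$bleach_time, x$end_capacity))
  invisible(x)
}

#' Coupling between plus-end motor occupancy and microtubule dynamics
#'
#' Parameters of the saturating laws that map motor action at the plus end to
#' the growth rate and the catastrophe frequency:
#' \deqn{v(L, c) = v_0 + (v_{max} - v_0) \frac{cL}{A + cL}}
#' \deqn{f(L, c) = f_0 - (f_0 - f_{min}) \frac{cL}{A + cL}}
#' where `c` is motor concentration (nM) and `L` filament length (um), so the
#' response depends on the antenna product `cL` alone. Defaults are the
#' porcine fit (v0 = 0.294, vmax = 1.03 um/min, A = 39.8 um nM) with the
#' catastrophe endpoints anchored at the 0 and 40 nM table values.
#'
#' @param v0 Growth rate without motors (um/min).
#' @param vmax Saturating growth rate (um/min), `vmax >= v0`.
#' @param A Saturation constant (um nM).
#' @param f0 Catastrophe frequency without motors (per min).
#' @param fmin Saturating (minimum) catastrophe frequency (per min).
#'
#' @return An object of class `coupling_params`.
#' @examples
#' coupling_params()
#' @export
coupling_params <- function(v0 = 0.294, vmax = 1.03, A = 39.8,
                            f0 = 0.166, fmin = 0.004) {
  stopifnot(v0 >= 0, vmax >= v0, A > 0, fmin >= 0, f0 >= fmin)
  structure(list(v0 = v0, vmax = vmax, A = A, f0 = f0, fmin = fmin),
            class = "coupling_params")
}

#' @export
print.coupling_params <- function(x, ...) {
  cat(sprintf(
    "<coupling_params> v0 = %.3g, vmax = %.3g um/min; f0 = %.3g, fmin = %.3g /min; A = %.3g um*nM\n",
    x$v0, x$vmax, x$f0, x$fmin, x$A))
  invisible(x)
}

#' Is a reported distance unbounded?
#'
#' Catastrophe and rescue distances are ratios rate/frequency; when the
#' frequency is zero the mean excursion is unbounded and is represented as
#' `Inf` (printed as a dash in reports, as in the published tables).
#'
#' @param x Numeric vector of distances.
#' @return Logical vector.
#' @examples
#' is_unbounded(catastrophe_distance(dynamics_params(0.9, 0)))
#' @export
is_unbounded <- function(x) is.infinite(x) & x > 0
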