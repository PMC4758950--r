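#' Expected microtubule length under growth-catastrophe cycling
#'
#' Mean length at time `t` of a filament that grows at \eqn{v_+}, suffers
#' catastrophes as a Poisson process with frequency \eqn{f_{+-}}, and resets
#' instantly to zero length (rescues and the finite shrinkage time are
#' ignored):
#' \deqn{L(t) = (v_+ / f_{+-}) [1 - e^{-t f_{+-}}]}
#' For \eqn{f_{+-} = 0} the limit \eqn{v_+ t} is returned. As `t` grows the
#' expectation converges to the catastrophe distance \eqn{v_+ / f_{+-}}.
#'
#' @param d A [dynamics_params()] object (only `growth_rate` and
#'   `catastrophe_freq` are used).
#' @param t Time(s) since nucleation (minutes); vectorised.
#' @return Expected length(s) in um.
#' @examples
#' expected_length(dynamics_params(0.32, 0.166), 10)
#' @export
expected_length <- function(d, t) {
  stopifnot(inherits(d, "dynamics_params"))
  if (any(t < 0)) rlang::abort("t must be non-negative")
  v <- d$growth_rate
  f <- d$catastrophe_freq
  if (f == 0) return(v * t)
  (v / f) * (1 - exp(-t * f))
}

#' Catastrophe distance
#'
#' Mean length grown before a catastrophe: growth rate divided by catastrophe
#' frequency. A zero catastrophe frequency yields `Inf` (the unbounded
#' regime; see [is_unbounded()]).
#'
#' @param d A [dynamics_params()] object.
#' @return Distance in um.
#' @examples
#' catastrophe_distance(dynamics_params(0.32, 0.166)) # ~1.9 um
#' @export
catastrophe_distance <- function(d) {
  stopifnot(inherits(d, "dynamics_params"))
  if (d$catastrophe_freq == 0) return(Inf)
  d$growth_rate / d$catastrophe_freq
}

#' Rescue distance
#'
#' Mean length shrunk before a rescue: shrinkage rate divided by rescue
#' frequency. A zero rescue frequency yields `Inf`.
#'
#' @param d A [dynamics_params()] object.
#' @return Distance in um.
#' @examples
#' rescue_distance(dynamics_params(0.62, 0.065, 28.4, 2.2)) # ~13 um
#' @export
rescue_distance <- function(d) {
  stopifnot(inherits(d, "dynamics_params"))
  if (d$rescue_freq == 0) return(Inf)
  d$shrink_rate / d$rescue_freq
}

#' Growth rate as a function of length and motor concentration
#'
#' The saturating length law \eqn{v = v_0 + (v_{max}-v_0)\, cL/(A + cL)}:
#' monotone non-decreasing in `L` and `c`, bounded by `[v0, vmax]`, and a
#' function of the antenna product `cL` only.
#'
#' @param L Filament length(s), um.
#' @param conc Motor concentration(s), nM.
#' @param p A [coupling_params()] object.
#' @return Growth rate(s), um/min.
#' @examples
#' growth_rate_vs_length(4, 5, coupling_params())
#' @export
growth_rate_vs_length <- function(L, conc, p = coupling_params()) {
  stopifnot(inherits(p, "coupling_params"))
  if (any(L < 0) || any(conc < 0)) rlang::abort("L and conc must be non-negative")
  x <- conc * L
  p$v0 + (p$vmax - p$v0) * x / (p$A + x)
}

#' Catastrophe frequency as a function of length and motor concentration
#'
#' Mirror of [growth_rate_vs_length()] for catastrophe suppression:
#' \eqn{f = f_0 - (f_0 - f_{min})\, cL/(A + cL)}. At `conc = 0` it returns
#' `f0`; it decreases monotonically in the product `cL` towards `fmin`.
#'
#' @inheritParams growth_rate_vs_length
#' @return Catastrophe frequency(ies), per minute.
#' @examples
#' catastrophe_freq_vs_length(8, 5, coupling_params())
#' @export
catastrophe_freq_vs_length <- function(L, conc, p = coupling_params()) {
  stopifnot(inherits(p, "coupling_params"))
  if (any(L < 0) || any(conc < 0)) rlang::abort("L and conc must be non-negative")
  x <- conc * L
  p$f0 - (p$f0 - p$fmin) * x / (p$A + x)
}

#' Steady-state motor flux into the plus end (antenna model)
#'
#' Motors land anywhere along the filament at rate `landing_rate * conc` per
#' um, walk towards the plus end, and detach with mean run length
#' \eqn{\lambda}. At steady state the arrival rate at the plus end is
#' \deqn{J(L) = a\, c\, \lambda\, (1 - e^{-L/\lambda})}
#' linear in `L` for short filaments (every motor reaches the end) and
#' saturating at \eqn{a c \lambda} for filaments much longer than the run
#' length.
#'
#' @param L Filament length(s), um.
#' @param conc Motor concentration, nM.
#' @param m A [motor_params()] object (`landing_rate`, `run_length`).
#' @return Arrival rate(s), motors per minute.
#' @examples
#' antenna_end_flux(4, 5, motor_params(landing_rate = 1))
#' @export
antenna_end_flux <- function(L, conc, m = motor_params()) {
  stopifnot(inherits(m, "motor_params"))
  if (any(L < 0) || any(conc < 0)) rlang::abort("L and conc must be non-negative")
  lam <- m$run_length
  m$landing_rate * conc * lam * (1 - exp(-L / lam))
}

#' Convert a growth-rate slope to a tubulin on-rate constant
#'
#' A linear regression of growth rate (um/min) on free tubulin concentration
#' (uM) has slope in um min^-1 uM^-1; multiplying by the number of dimers per
#' um of microtubule (13 protofilaments x 125 dimers/um at 8 nm per dimer =
#' 1625) and dividing by 60 gives the second-order association rate constant
#' in uM^-1 s^-1.
#'
#' @param slope Regression slope, um min^-1 uM^-1.
#' @param dimers_per_um Tubulin dimers per um of lattice (default 1625).
#' @return k_on in uM^-1 s^-1.
#' @seealso [slope_from_kon()] for the inverse.
#' @examples
#' kon_from_slope(0.02585) # ~0.70
#' @export
kon_from_slope <- function(slope, dimers_per_um = 1625) {
  if (any(dimers_per_um <= 0)) rlang::abort("dimers_per_um must be positive")
  slope * dimers_per_um / 60
}

#' @rdname kon_from_slope
#' @param kon Association rate constant, uM^-1 s^-1.
#' @export
slope_from_kon <- function(kon, dimers_per_um = 1625) {
  if (any(dimers_per_um <= 0)) rlang::abort("dimers_per_um must be positive")
  kon * 60 / dimers_per_um
}

#' Mean lattice run time of a motor
#'
#' Mean run length divided by velocity; e.g. a 4.1 um mean run at 50 nm/s
#' (3.0 um/min) corresponds to 82 s.
#'
#' @param run_length Mean run length, um.
#' @param velocity Velocity, um/min.
#' @return Mean run time in seconds.
#' @examples
#' mean_run_time(4.1, 3.0) # 82 s
#' @export
mean_run_time <- function(run_length, velocity) {
  stopifnot(run_length >= 0, velocity > 0)
  60 * run_length / velocity
}
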