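new_trajectory <- function(nodes, events, params, seed,
                           occupancy = NULL, ledger = NULL) {
  traj <- tibble::new_tibble(nodes, class = "mt_trajectory")
  attr(traj, "events") <- events
  attr(traj, "params") <- params
  attr(traj, "seed") <- seed
  attr(traj, "occupancy") <- occupancy
  attr(traj, "motor_ledger") <- ledger
  traj
}

empty_events <- function() {
  tibble::tibble(time_min = numeric(), kind = character(), length_um = numeric())
}

#' Event log of a simulated trajectory
#'
#' @param traj An `mt_trajectory` from [simulate_dynamic_instability()] or
#'   [simulate_coupled()].
#' @return A tibble with columns `time_min`, `kind` (`catastrophe`, `rescue`,
#'   `reset_to_seed`, `nucleation`), `length_um`.
#' @export
trajectory_events <- function(traj) {
  ev <- attr(traj, "events")
  if (is.null(ev)) empty_events() else ev
}

#' Filament length at arbitrary times
#'
#' Linear interpolation of an event-resolved trajectory.
#'
#' @param traj An `mt_trajectory`.
#' @param t Times (minutes).
#' @return Lengths (um).
#' @export
trajectory_length_at <- function(traj, t) {
  stats::approx(traj$time_min, traj$length_um, xout = t, rule = 2)$y
}

#' Monte-Carlo mean length of the instant-reset growth process
#'
#' Each trial grows from zero at the growth rate, suffers catastrophes as a
#' Poisson process, resets instantly to zero and regrows; the ensemble mean
#' length at `t_end` is returned with its standard error. The closed form
#' [expected_length()] is the infinite-trial limit.
#'
#' @param d A [dynamics_params()] object (growth rate, catastrophe frequency).
#' @param t_end Observation time (minutes).
#' @param n_trials Number of independent trials.
#' @param seed Optional RNG seed.
#' @return A one-row tibble: `mean_length_um`, `se_um`, `n_trials`,
#'   `t_end_min`; the per-trial lengths are attached as attribute `lengths`.
#' @examples
#' simulate_reset_process(dynamics_params(0.32, 0.166), 10, 1000, seed = 1)
#' @export
simulate_reset_process <- function(d, t_end, n_trials = 1e5, seed = NULL) {
  stopifnot(inherits(d, "dynamics_params"), n_trials >= 1)
  if (t_end < 0) rlang::abort("t_end must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  v <- d$growth_rate
  f <- d$catastrophe_freq
  n <- as.integer(n_trials)
  if (t_end == 0) {
    lengths <- numeric(n)
  } else if (f == 0) {
    lengths <- rep(v * t_end, n)
  } else {
    # length at t_end is v * (time since last catastrophe); walk each trial's
    # Poisson event clock forward until it passes t_end
    t_last <- numeric(n)
    t_cur <- numeric(n)
    active <- seq_len(n)
    while (length(active) > 0) {
      t_cur[active] <- t_cur[active] + stats::rexp(length(active), f)
      hit <- t_cur[active] <= t_end
      t_last[active[hit]] <- t_cur[active[hit]]
      active <- active[hit]
    }
    lengths <- v * (t_end - t_last)
  }
  out <- tibble::tibble(
    mean_length_um = mean(lengths),
    se_um = stats::sd(lengths) / sqrt(n),
    n_trials = n, t_end_min = t_end)
  attr(out, "lengths") <- lengths
  out
}

#' Simulate two-state microtubule dynamic instability
#'
#' Exact event-driven simulation of the standard two-state model: growth at
#' constant speed interrupted by Poisson catastrophes; shrinkage at constant
#' speed ended by Poisson rescues or by reaching zero length, where the
#' filament renucleates (instantly by default) from the stabilized seed.
#'
#' @param d A [dynamics_params()] object.
#' @param t_end Observation time (minutes).
#' @param seed Optional RNG seed.
#' @param renucleation_delay Mean exponential delay (minutes) before regrowth
#'   after full depolymerization; `0` = instantaneous.
#' @param initial_length Starting length (um).
#' @return An `mt_trajectory`: a tibble of piecewise-linear nodes
#'   (`time_min`, `length_um`, `phase`), with the event log available via
#'   [trajectory_events()].
#' @examples
#' tr <- simulate_dynamic_instability(dynamics_params(0.32, 0.166, 27.6, 0.88),
#'                                    10, seed = 1)
#' trajectory_events(tr)
#' @export
simulate_dynamic_instability <- function(d, t_end, seed = NULL,
                                         renucleation_delay = 0,
                                         initial_length = 0) {
  stopifnot(inherits(d, "dynamics_params"))
  if (t_end <= 0) rlang::abort("t_end must be positive")
  if (!is.null(seed)) set.seed(seed)
  v <- d$growth_rate; f <- d$catastrophe_freq
  vs <- d$shrink_rate; fr <- d$rescue_freq

  t <- 0; L <- initial_length; phase <- "growing"
  nt <- c(0); nl <- c(L); np <- c("growing")
  ev_t <- numeric(); ev_k <- character(); ev_l <- numeric()
  push_node <- function(tt, ll, pp) {
    nt[[length(nt) + 1L]] <<- tt; nl[[length(nl) + 1L]] <<- ll
    np[[length(np) + 1L]] <<- pp
  }
  push_event <- function(tt, kk, ll) {
    ev_t[[length(ev_t) + 1L]] <<- tt; ev_k[[length(ev_k) + 1L]] <<- kk
    ev_l[[length(ev_l) + 1L]] <<- ll
  }

  it <- 0L
  while (t < t_end) {
    it <- it + 1L
    if (it > 1e7L) rlang::abort("event budget exceeded; check rates")
    if (phase == "growing") {
      dt_cat <- if (f > 0) stats::rexp(1, f) else Inf
      if (t + dt_cat >= t_end) {
        push_node(t_end, L + v * (t_end - t), "growing")
        break
      }
      t <- t + dt_cat; L <- L + v * dt_cat
      push_event(t, "catastrophe", L)
      push_node(t, L, "shrinking")
      phase <- "shrinking"
    } else {
      dt_zero <- if (vs > 0) L / vs else Inf
      dt_res <- if (fr > 0) stats::rexp(1, fr) else Inf
      dt <- min(dt_res, dt_zero)
      if (t + dt >= t_end) {
        push_node(t_end, L - vs * (t_end - t), "shrinking")
        break
      }
      t <- t + dt; L <- max(0, L - vs * dt)
      if (dt_res < dt_zero) {
        push_event(t, "rescue", L)
        push_node(t, L, "growing")
      } else {
        L <- 0
        push_event(t, "reset_to_seed", 0)
        push_node(t, 0, "growing")
        if (renucleation_delay > 0) {
          dt_nuc <- stats::rexp(1, 1 / renucleation_delay)
          if (t + dt_nuc >= t_end) {
            push_node(t_end, 0, "growing")
            break
          }
          t <- t + dt_nuc
          push_event(t, "nucleation", 0)
          push_node(t, 0, "growing")
        }
      }
      phase <- "growing"
    }
  }
  new_trajectory(
    tibble::tibble(time_min = nt, length_um = nl, phase = np),
    tibble::tibble(time_min = ev_t, kind = ev_k, length_um = ev_l),
    d, seed)
}

#' Simulate the coupled motor-filament antenna-feedback model
#'
#' Hybrid exact simulation of a dynamic microtubule whose growth rate and
#' catastrophe propensity are set by the current plus-end motor occupancy.
#' Motors land along the lattice as a Poisson process with rate
#' `landing_rate * conc * L(t)`, walk towards the plus end at the dynamic
#' velocity, detach at rate `velocity_lattice / run_length`, join the plus-end
#' pool on arrival (capped at `end_capacity`; an arrival at a full pool is
#' released), and leave the pool at rate `1 / end_residence`. With occupancy
#' `N` out of capacity `N_sat` the instantaneous rates are
#' `v = v0 + (vmax - v0) N/N_sat` and `f = f0 - (f0 - fmin) N/N_sat`.
#' At a catastrophe the end pool is released; a shrinking end annihilates the
#' lattice motors it passes. With `conc = 0` the model reduces exactly (same
#' random number stream) to [simulate_dynamic_instability()].
#'
#' @param d0 Baseline [dynamics_params()] at zero motor concentration; its
#'   growth rate and catastrophe frequency must equal `p$v0` and `p$f0`.
#' @param m A [motor_params()] object.
#' @param p A [coupling_params()] object.
#' @param conc Motor concentration (nM).
#' @param t_end Observation time (minutes).
#' @param seed Optional RNG seed.
#' @param bleaching If `TRUE`, motors also disappear at rate
#'   `1 / bleach_time` (off by default: the growth assays use unlabelled
#'   motors, bleaching is an imaging artefact).
#' @param renucleation_delay As in [simulate_dynamic_instability()].
#' @return An `mt_trajectory` with additional attributes: `occupancy`
#'   (a tibble `time_min`, `n_end` of plus-end pool changes) and
#'   `motor_ledger` (named counts used for conservation checks).
#' @examples
#' d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
#' tr <- simulate_coupled(d0, motor_params(), coupling_params(), 5, 5, seed = 1)
#' utils::head(attr(tr, "occupancy"))
#' @export
simulate_coupled <- function(d0, m, p, conc, t_end, seed = NULL,
                             bleaching = FALSE, renucleation_delay = 0) {
  stopifnot(inherits(d0, "dynamics_params"), inherits(m, "motor_params"),
            inherits(p, "coupling_params"))
  if (conc < 0) rlang::abort("conc must be non-negative")
  if (t_end <= 0) rlang::abort("t_end must be positive")
  if (abs(d0$growth_rate - p$v0) > 1e-9 || abs(d0$catastrophe_freq - p$f0) > 1e-9) {
    rlang::abort("baseline dynamics d0 must match coupling anchors (v0, f0)")
  }
  if (!is.null(seed)) set.seed(seed)

  vs <- d0$shrink_rate; fr <- d0$rescue_freq
  vm <- m$velocity_dynamic
  k_det <- m$velocity_lattice / m$run_length        # per min
  k_end <- 60 / m$end_residence                     # per min
  k_bl <- if (bleaching && is.finite(m$bleach_time)) 60 / m$bleach_time else 0
  ac <- m$landing_rate * conc
  cap <- m$end_capacity

  t <- 0; L <- 0; phase <- "growing"
  x <- numeric(0)        # lattice motor positions (um from minus end)
  n_end <- 0L
  nt <- c(0); nl <- c(0); np <- c("growing")
  ev_t <- numeric(); ev_k <- character(); ev_l <- numeric()
  oc_t <- c(0); oc_n <- c(0L)
  led <- c(landed = 0L, detached = 0L, arrived_end = 0L, end_released = 0L,
           end_overflow = 0L, bleached = 0L, released_shrink = 0L,
           released_catastrophe = 0L)

  push_node <- function(tt, ll, pp) {
    nt[[length(nt) + 1L]] <<- tt; nl[[length(nl) + 1L]] <<- ll
    np[[length(np) + 1L]] <<- pp
  }
  push_event <- function(tt, kk, ll) {
    ev_t[[length(ev_t) + 1L]] <<- tt; ev_k[[length(ev_k) + 1L]] <<- kk
    ev_l[[length(ev_l) + 1L]] <<- ll
  }
  push_occ <- function(tt) {
    oc_t[[length(oc_t) + 1L]] <<- tt; oc_n[[length(oc_n) + 1L]] <<- n_end
  }
  # landing time for a linearly changing length L(tau) = L + s*tau
  landing_dt <- function(L, s) {
    if (ac <= 0) return(Inf)
    E <- stats::rexp(1)
    if (s > 0) {
      dt <- (-L + sqrt(L^2 + 2 * s * E / ac)) / s
    } else if (s < 0) {
      lam_max <- ac * L^2 / (2 * (-s))
      if (E >= lam_max) return(Inf)
      dt <- (L - sqrt(L^2 + 2 * s * E / ac)) / (-s)
    } else {
      if (L <= 0) return(Inf)
      dt <- E / (ac * L)
    }
    dt
  }
  check_state <- function() {
    if (L < -1e-6 || n_end < 0L || n_end > cap ||
        (length(x) > 0 && (min(x) < -1e-6 || max(x) > L + 1e-6))) {
      rlang::abort("inconsistent simulator state (propensity/time-step error)")
    }
  }

  it <- 0L
  while (t < t_end) {
    it <- it + 1L
    if (it > 5e6L) rlang::abort("event budget exceeded; check rates")
    check_state()
    occ <- n_end / cap
    if (phase == "growing") {
      vg <- p$v0 + (p$vmax - p$v0) * occ
      fc <- p$f0 - (p$f0 - p$fmin) * occ
      dts <- c(
        catastrophe = if (fc > 0) stats::rexp(1, fc) else Inf,
        land = landing_dt(L, vg),
        arrive = if (length(x) > 0 && vm > vg) (L - max(x)) / (vm - vg) else Inf,
        detach = if (length(x) > 0) stats::rexp(1, length(x) * k_det) else Inf,
        end_release = if (n_end > 0) stats::rexp(1, n_end * k_end) else Inf,
        bleach = if (k_bl > 0 && (length(x) + n_end) > 0)
          stats::rexp(1, (length(x) + n_end) * k_bl) else Inf)
      dt <- min(dts)
      if (t + dt >= t_end) {
        push_node(t_end, L + vg * (t_end - t), "growing")
        break
      }
      t <- t + dt; L <- L + vg * dt
      if (length(x) > 0) x <- pmin(x + vm * dt, L)
      switch(names(dts)[which.min(dts)],
        catastrophe = {
          push_event(t, "catastrophe", L)
          push_node(t, L, "shrinking")
          led["released_catastrophe"] <- led["released_catastrophe"] + n_end
          if (n_end > 0L) { n_end <- 0L; push_occ(t) }
          phase <- "shrinking"
        },
        land = {
          x <- c(x, stats::runif(1, 0, L))
          led["landed"] <- led["landed"] + 1L
        },
        arrive = {
          i <- which.max(x); x <- x[-i]
          led["arrived_end"] <- led["arrived_end"] + 1L
          if (n_end < cap) {
            n_end <- n_end + 1L; push_occ(t)
          } else {
            led["end_overflow"] <- led["end_overflow"] + 1L
          }
        },
        detach = {
          i <- sample.int(length(x), 1L); x <- x[-i]
          led["detached"] <- led["detached"] + 1L
        },
        end_release = {
          n_end <- n_end - 1L; push_occ(t)
          led["end_released"] <- led["end_released"] + 1L
        },
        bleach = {
          if (stats::runif(1) < length(x) / (length(x) + n_end)) {
            i <- sample.int(length(x), 1L); x <- x[-i]
          } else {
            n_end <- n_end - 1L; push_occ(t)
          }
          led["bleached"] <- led["bleached"] + 1L
        })
    } else {
      dts <- c(
        rescue = if (fr > 0) stats::rexp(1, fr) else Inf,
        zero = if (vs > 0) L / vs else Inf,
        land = landing_dt(L, -vs),
        collide = if (length(x) > 0) (L - max(x)) / (vm + vs) else Inf,
        detach = if (length(x) > 0) stats::rexp(1, length(x) * k_det) else Inf,
        bleach = if (k_bl > 0 && length(x) > 0)
          stats::rexp(1, length(x) * k_bl) else Inf)
      dt <- min(dts)
      if (t + dt >= t_end) {
        push_node(t_end, L - vs * (t_end - t), "shrinking")
        break
      }
      t <- t + dt; L <- max(0, L - vs * dt)
      if (length(x) > 0) x <- pmin(x + vm * dt, L)
      switch(names(dts)[which.min(dts)],
        rescue = {
          push_event(t, "rescue", L)
          push_node(t, L, "growing")
          phase <- "growing"
        },
        zero = {
          L <- 0
          push_event(t, "reset_to_seed", 0)
          push_node(t, 0, "growing")
          if (length(x) > 0) {  # should have collided already
            rlang::abort("inconsistent simulator state: lattice motors at zero length")
          }
          if (renucleation_delay > 0) {
            dt_nuc <- stats::rexp(1, 1 / renucleation_delay)
            if (t + dt_nuc >= t_end) { push_node(t_end, 0, "growing"); t <- t_end; break }
            t <- t + dt_nuc
            push_event(t, "nucleation", 0)
            push_node(t, 0, "growing")
          }
          phase <- "growing"
        },
        land = {
          x <- c(x, stats::runif(1, 0, L))
          led["landed"] <- led["landed"] + 1L
        },
        collide = {
          i <- which.max(x); x <- x[-i]
          led["released_shrink"] <- led["released_shrink"] + 1L
        },
        detach = {
          i <- sample.int(length(x), 1L); x <- x[-i]
          led["detached"] <- led["detached"] + 1L
        },
        bleach = {
          i <- sample.int(length(x), 1L); x <- x[-i]
          led["bleached"] <- led["bleached"] + 1L
        })
    }
  }
  led <- c(led, lattice_now = length(x), end_now = n_end)
  new_trajectory(
    tibble::tibble(time_min = nt, length_um = nl, phase = np),
    tibble::tibble(time_min = ev_t, kind = ev_k, length_um = ev_l),
    list(d0 = d0, m = m, p = p, conc = conc), seed,
    occupancy = tibble::tibble(time_min = oc_t, n_end = as.integer(oc_n)),
    ledger = led)
}

#' Simulate single-molecule motor runs
#'
#' Draws independent motor runs on a (by default infinitely long) stabilized
#' microtubule: Gaussian velocity, exponential detachment distance (mean
#' `run_length`), competing exponential photobleaching (mean `bleach_time`).
#' On a finite track a run reaching the plus end converts into an exponential
#' end dwell (mean `end_residence`) that can itself be cut short by
#' bleaching.
#'
#' @param m A [motor_params()] object.
#' @param n Number of runs.
#' @param seed Optional RNG seed.
#' @param track_length Microtubule length (um); `Inf` means runs never reach
#'   an end (pure lattice statistics).
#' @return A tibble of class `mt_runs`: `landing_um`, `velocity_um_min`,
#'   `run_um`, `run_s`, `reached_end`, `end_dwell_s`, `dwell_censored`,
#'   `terminated_by` (`detach`, `bleach`, `end_release`), `censored`
#'   (run cut short by bleaching).
#' @examples
#' runs <- simulate_single_molecule_runs(motor_params(), 100, seed = 1)
#' mean(runs$run_um)
#' @export
simulate_single_molecule_runs <- function(m, n, seed = NULL,
                                          track_length = Inf) {
  stopifnot(inherits(m, "motor_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  v <- stats::rnorm(n, m$velocity_lattice, m$velocity_sd)
  v <- pmax(v, 0.05 * m$velocity_lattice)  # guard the Gaussian tail
  v_s <- v / 60                            # um/s
  d_detach <- stats::rexp(n, 1 / m$run_length)
  t_bleach <- if (is.finite(m$bleach_time)) stats::rexp(n, 1 / m$bleach_time) else rep(Inf, n)
  landing <- if (is.finite(track_length)) stats::runif(n, 0, track_length) else rep(0, n)
  d_to_end <- if (is.finite(track_length)) track_length - landing else rep(Inf, n)
  t_detach <- d_detach / v_s
  t_to_end <- d_to_end / v_s

  t_run <- pmin(t_detach, t_bleach, t_to_end)
  reached <- t_to_end <= t_detach & t_to_end <= t_bleach
  bleach_on_run <- t_bleach < t_detach & t_bleach < t_to_end
  terminated <- ifelse(reached, "end_release",
                       ifelse(bleach_on_run, "bleach", "detach"))
  end_dwell <- rep(NA_real_, n)
  dwell_censored <- rep(NA, n)
  if (any(reached)) {
    k <- which(reached)
    w <- stats::rexp(length(k), 1 / (m$end_residence))
    b2 <- if (is.finite(m$bleach_time)) stats::rexp(length(k), 1 / m$bleach_time) else rep(Inf, length(k))
    end_dwell[k] <- pmin(w, b2)
    dwell_censored[k] <- b2 < w
    terminated[k] <- ifelse(b2 < w, "bleach", "end_release")
  }
  tibble::new_tibble(tibble::tibble(
    landing_um = landing,
    velocity_um_min = v,
    run_um = v_s * t_run,
    run_s = t_run,
    reached_end = reached,
    end_dwell_s = end_dwell,
    dwell_censored = dwell_censored,
    terminated_by = terminated,
    censored = bleach_on_run), class = "mt_runs")
}

#' Simulate dynamic instability under the explicit length law
#'
#' Companion to [simulate_coupled()] in which the instantaneous growth rate
#' and catastrophe frequency are set directly by the saturating length laws
#' [growth_rate_vs_length()] and [catastrophe_freq_vs_length()] (functions of
#' the antenna product `conc * L`), rather than by explicit motors. Growth is
#' integrated on a fine grid with the catastrophe propensity thinned per
#' step; shrinkage and rescue are exact as in
#' [simulate_dynamic_instability()]. This is the generating model matching
#' the length-binned growth analysis and the length-law fit.
#'
#' @param d A [dynamics_params()] object supplying shrinkage and rescue (its
#'   growth/catastrophe entries must equal `p$v0`/`p$f0`).
#' @param p A [coupling_params()] object.
#' @param conc Motor concentration (nM).
#' @param t_end Observation time (minutes).
#' @param seed Optional RNG seed.
#' @param dt Integration step (minutes) for the growth phase.
#' @return An `mt_trajectory`.
#' @export
simulate_length_law <- function(d, p, conc, t_end, seed = NULL, dt = 1 / 30) {
  stopifnot(inherits(d, "dynamics_params"), inherits(p, "coupling_params"))
  if (conc < 0) rlang::abort("conc must be non-negative")
  if (t_end <= 0) rlang::abort("t_end must be positive")
  if (abs(d$growth_rate - p$v0) > 1e-9 || abs(d$catastrophe_freq - p$f0) > 1e-9) {
    rlang::abort("baseline dynamics d must match coupling anchors (v0, f0)")
  }
  if (!is.null(seed)) set.seed(seed)
  vs <- d$shrink_rate; fr <- d$rescue_freq
  t <- 0; L <- 0; phase <- "growing"
  nt <- c(0); nl <- c(0); np <- c("growing")
  ev_t <- numeric(); ev_k <- character(); ev_l <- numeric()
  push_node <- function(tt, ll, pp) {
    nt[[length(nt) + 1L]] <<- tt; nl[[length(nl) + 1L]] <<- ll
    np[[length(np) + 1L]] <<- pp
  }
  push_event <- function(tt, kk, ll) {
    ev_t[[length(ev_t) + 1L]] <<- tt; ev_k[[length(ev_k) + 1L]] <<- kk
    ev_l[[length(ev_l) + 1L]] <<- ll
  }
  it <- 0L
  while (t < t_end) {
    it <- it + 1L
    if (it > 1e7L) rlang::abort("event budget exceeded; check rates")
    if (phase == "growing") {
      h <- min(dt, t_end - t)
      v <- growth_rate_vs_length(L, conc, p)
      f <- catastrophe_freq_vs_length(L, conc, p)
      if (f * h > 0 && stats::runif(1) < f * h) {
        u <- stats::runif(1)          # event time within the step
        t <- t + u * h; L <- L + v * u * h
        push_event(t, "catastrophe", L)
        push_node(t, L, "shrinking")
        phase <- "shrinking"
      } else {
        t <- t + h; L <- L + v * h
        push_node(t, L, "growing")
      }
    } else {
      dt_zero <- if (vs > 0) L / vs else Inf
      dt_res <- if (fr > 0) stats::rexp(1, fr) else Inf
      step <- min(dt_res, dt_zero)
      if (t + step >= t_end) {
        push_node(t_end, L - vs * (t_end - t), "shrinking")
        break
      }
      t <- t + step; L <- max(0, L - vs * step)
      if (dt_res < dt_zero) {
        push_event(t, "rescue", L)
        push_node(t, L, "growing")
      } else {
        L <- 0
        push_event(t, "reset_to_seed", 0)
        push_node(t, 0, "growing")
      }
      phase <- "growing"
    }
  }
  new_trajectory(
    tibble::tibble(time_min = nt, length_um = nl, phase = np),
    tibble::tibble(time_min = ev_t, kind = ev_k, length_um = ev_l),
    list(d = d, p = p, conc = conc), seed)
}
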