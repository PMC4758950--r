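test_that("reset-process Monte Carlo agrees with the closed form", {
  d <- dynamics_params(0.32, 0.166)
  r <- simulate_reset_process(d, 10, n_trials = 2e4, seed = 5)
  expect_lt(abs(r$mean_length_um - expected_length(d, 10)), 3 * r$se_um)
  # degenerate cases
  r0 <- simulate_reset_process(dynamics_params(0.5, 0), 8, 100, seed = 1)
  expect_equal(r0$mean_length_um, 4)
  expect_equal(r0$se_um, 0)
  expect_equal(simulate_reset_process(d, 0, 50, seed = 1)$mean_length_um, 0)
  expect_error(simulate_reset_process(d, -1, 10), "non-negative")
})

test_that("two-state simulation reproduces the catastrophe distance", {
  # ratio estimator (total distance grown / number of catastrophes) is the
  # published definition and is unbiased under window censoring
  d <- porcine_0nM()
  set.seed(100)
  grown <- 0; ncat <- 0
  for (i in 1:200) {
    tr <- simulate_dynamic_instability(d, 10)
    dl <- diff(tr$length_um)
    grown <- grown + sum(dl[dl > 0])
    ncat <- ncat + sum(trajectory_events(tr)$kind == "catastrophe")
  }
  mu <- grown / ncat
  expect_lt(abs(mu - catastrophe_distance(d)), 3 * catastrophe_distance(d) / sqrt(ncat))
})

test_that("two-state model reduces to the reset process and to pure growth", {
  # instantaneous shrinkage, no rescue -> instant-reset process
  d <- dynamics_params(0.32, 0.166, 1e9, 0)
  set.seed(11)
  finals <- vapply(1:400, function(i) {
    tr <- simulate_dynamic_instability(d, 10)
    tr$length_um[nrow(tr)]
  }, numeric(1))
  expect_lt(abs(mean(finals) - expected_length(dynamics_params(0.32, 0.166), 10)),
            3 * sd(finals) / sqrt(length(finals)))
  # no catastrophe -> one unbroken phase
  tr <- simulate_dynamic_instability(dynamics_params(0.7, 0), 10, seed = 2)
  expect_equal(nrow(trajectory_events(tr)), 0)
  expect_equal(tr$length_um[nrow(tr)], 7)
  expect_true(all(tr$phase == "growing"))
})

test_that("growth waiting times are exponential (Kolmogorov-Smirnov)", {
  d <- dynamics_params(1, 1, 1e9, 0)  # unit catastrophe rate, instant resets
  set.seed(3)
  waits <- unlist(lapply(1:120, function(i) {
    ev <- trajectory_events(simulate_dynamic_instability(d, 100))
    tcat <- ev$time_min[ev$kind == "catastrophe"]
    tres <- c(0, ev$time_min[ev$kind == "reset_to_seed"])
    tcat - tres[seq_along(tcat)]
  }))
  expect_gt(length(waits), 1e4)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", 1))
  expect_gt(ks$p.value, 1e-3)
})

test_that("trajectories are reproducible and internally consistent", {
  d <- porcine_0nM()
  t1 <- simulate_dynamic_instability(d, 10, seed = 77)
  t2 <- simulate_dynamic_instability(d, 10, seed = 77)
  expect_identical(trajectory_events(t1), trajectory_events(t2))
  expect_identical(t1$length_um, t2$length_um)
  # node invariants: time strictly increasing, lengths non-negative, and
  # within-phase slopes equal the phase rates
  expect_true(all(diff(t1$time_min) >= 0))
  expect_true(all(t1$length_um >= -1e-12))
  dt <- diff(t1$time_min); dl <- diff(t1$length_um)
  sl <- dl[dt > 1e-12] / dt[dt > 1e-12]
  expect_true(all(abs(sl - 0.32) < 1e-9 | abs(sl + 27.6) < 1e-9))
})

test_that("coupled model at c = 0 reproduces the plain two-state model exactly", {
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0.5)
  tr1 <- simulate_dynamic_instability(d0, 10, seed = 9)
  tr2 <- simulate_coupled(d0, motor_params(), coupling_params(f0 = 0.166), 0, 10,
                          seed = 9)
  expect_equal(trajectory_events(tr1)$time_min, trajectory_events(tr2)$time_min)
  expect_equal(trajectory_events(tr1)$length_um, trajectory_events(tr2)$length_um)
})

test_that("coupled model conserves motors and caps end occupancy", {
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
  m <- motor_params()
  tr <- simulate_coupled(d0, m, coupling_params(), 20, 10, seed = 5)
  led <- attr(tr, "motor_ledger")
  expect_identical(unname(led[["landed"]]),
                   unname(sum(led[c("detached", "bleached", "end_released",
                                    "end_overflow", "released_shrink",
                                    "released_catastrophe", "lattice_now",
                                    "end_now")])))
  occ <- attr(tr, "occupancy")
  expect_true(all(occ$n_end >= 0 & occ$n_end <= m$end_capacity))
  expect_gt(led[["landed"]], 0)
  # mismatched anchors must raise
  expect_error(simulate_coupled(dynamics_params(0.5, 0.166, 27.6, 0), m,
                                coupling_params(), 5, 1),
               "anchors")
})

test_that("antenna feedback raises growth and catastrophe-free length with concentration", {
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
  m <- motor_params(); p <- coupling_params()
  stats_at <- function(conc) {
    grown <- 0; gtime <- 0; ncat <- 0
    for (i in 1:12) {
      tr <- simulate_coupled(d0, m, p, conc, 10, seed = 400 + i)
      seg_dt <- diff(tr$time_min); seg_dl <- diff(tr$length_um)
      up <- seg_dl > 0
      grown <- grown + sum(seg_dl[up]); gtime <- gtime + sum(seg_dt[up])
      ncat <- ncat + sum(trajectory_events(tr)$kind == "catastrophe")
    }
    c(rate = grown / gtime, cat_free = grown / max(1, ncat))
  }
  s <- vapply(c(0, 5, 20), stats_at, numeric(2))
  expect_true(all(diff(s["rate", ]) > 0))
  expect_true(all(diff(s["cat_free", ]) > 0))
  expect_true(all(s["rate", ] >= p$v0 - 1e-9 & s["rate", ] <= p$vmax + 1e-9))
})

test_that("vanishing end residence reverts the coupled model to baseline", {
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
  m <- motor_params(end_residence = 1e-4)
  tr <- simulate_coupled(d0, m, coupling_params(), 20, 10, seed = 13)
  occ <- attr(tr, "occupancy")
  # occupancy collapses, so the filament grows at essentially v0
  expect_lt(mean(occ$n_end), 1)
  dt <- diff(tr$time_min); dl <- diff(tr$length_um)
  up <- dl > 0
  expect_lt(sum(dl[up]) / sum(dt[up]), 0.35)
})

test_that("coupled growth tracks the mean-field antenna ODE direction", {
  skip_if_not_installed("deSolve")
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
  m <- motor_params(); p <- coupling_params()
  # mean-field: dL/dt = v(N(L)), N(L) = min(cap, flux * residence)
  rhs <- function(t, y, parms) {
    N <- min(m$end_capacity, antenna_end_flux(y[1], 40, m) * m$end_residence / 60)
    list(growth_rate_vs_length(0, 0, p) +
           (p$vmax - p$v0) * N / m$end_capacity)
  }
  ode <- deSolve::ode(y = c(L = 0.01), times = seq(0, 10, 0.5), func = rhs,
                      parms = NULL)
  expect_true(all(diff(diff(ode[, "L"])) > -1e-6))  # accelerating growth
  set.seed(21)
  finals <- vapply(1:8, function(i)
    tail(simulate_coupled(d0, m, p, 40, 10, seed = 500 + i)$length_um, 1),
    numeric(1))
  # stochastic mean within the mean-field bracket [v0*t, vmax*t]
  expect_gt(mean(finals), p$v0 * 10 * 0.5)
  expect_lt(mean(finals), p$vmax * 10)
})

test_that("single-molecule runs reproduce exponential and competing-risk statistics", {
  # mean run time: 4.1 um at 50 nm/s (3 um/min) is 82 s
  m3 <- motor_params(velocity_lattice = 3, velocity_dynamic = 2.1,
                     velocity_sd = 0, bleach_time = Inf)
  runs <- simulate_single_molecule_runs(m3, 5000, seed = 8)
  expect_lt(abs(mean(runs$run_s) - 82), 3 * sd(runs$run_s) / sqrt(5000))
  # exponential run length at bleach -> infinity
  mInf <- motor_params(bleach_time = Inf)
  r2 <- simulate_single_molecule_runs(mInf, 1e4, seed = 9)
  expect_lt(abs(mean(r2$run_um) - 4.1), 3 * 4.1 / sqrt(1e4))
  expect_equal(sum(r2$censored), 0)
  # competing exponential bleaching at fixed velocity:
  # P(bleach) = tau_run / (tau_run + tau_bleach), tau_run = lambda / v
  mfix <- motor_params(velocity_sd = 0)
  r3 <- simulate_single_molecule_runs(mfix, 1e4, seed = 10)
  tau_run <- 4.1 / (5 / 60)
  p_bleach <- tau_run / (tau_run + 249)
  expect_lt(abs(mean(r3$censored) - p_bleach),
            3 * sqrt(p_bleach * (1 - p_bleach) / 1e4))
  # immediate bleaching truncates everything
  r4 <- simulate_single_molecule_runs(motor_params(bleach_time = 1e-6), 200,
                                      seed = 11)
  expect_true(all(r4$terminated_by == "bleach"))
  expect_lt(max(r4$run_um), 1e-4)
  # finite track: end dwell is exponential with the end-residence mean
  mtrack <- motor_params(bleach_time = Inf)
  r5 <- simulate_single_molecule_runs(mtrack, 5000, seed = 12, track_length = 10)
  dw <- r5$end_dwell_s[r5$reached_end]
  expect_gt(length(dw), 500)
  expect_lt(abs(mean(dw) - 30), 3 * 30 / sqrt(length(dw)))
  expect_true(all(r5$run_um[r5$reached_end] <= 10 + 1e-9))
})

test_that("length-law simulator matches its generating law on average", {
  d0 <- dynamics_params(0.294, 0, 27.6, 0)  # no catastrophe: pure growth ODE
  p <- coupling_params(f0 = 0, fmin = 0)
  tr <- simulate_length_law(d0, p, conc = 10, t_end = 10, seed = 3)
  # growth accelerates with length under the saturating law
  dl <- diff(tr$length_um); dt <- diff(tr$time_min)
  sl <- dl[dt > 1e-6] / dt[dt > 1e-6]  # skip the fp-sized final step
  expect_true(all(diff(sl) > -1e-9))
  expect_true(all(sl >= p$v0 - 1e-9 & sl <= p$vmax + 1e-9))
})
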