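test_that("relative SE and force-displacement reproduce the printed values", {
  expect_equal(round(relative_se(0.166, 126), 3), 0.015)
  expect_equal(round(relative_se(0.103, 116), 3), 0.010)
  expect_equal(relative_se(0.7, 1), 0.7)
  expect_error(relative_se(1, 0), ">= 1")
  expect_equal(round(force_displacement(0.5, 0.03)), 17)
  expect_equal(force_displacement(0, 0.03), 0)
  expect_equal(force_displacement(0.81, 0.03), 27)
  expect_error(force_displacement(1, 0), "positive")
})

test_that("a single noiseless phase is estimated exactly with zero SE", {
  tt <- seq(0, 600, by = 2)
  tr <- tibble::tibble(mt_id = "mt001", time_s = tt, position_um = 0.45 * tt / 60)
  est <- estimate_dynamics(segment_traces(tr))
  expect_equal(est$growth_rate, 0.45, tolerance = 1e-9)
  expect_equal(est$growth_se, 0)
  expect_equal(est$n_cat, 0)
  expect_equal(est$catastrophe_freq, 0)
  expect_true(is_unbounded(est$catastrophe_distance))
  expect_equal(est$rescue_freq, 0)
})

test_that("reported distances satisfy the ratio identities exactly", {
  cfg <- assay_config(n_microtubules = 30, duration_min = 10, seed = 41)
  est <- estimate_dynamics(segment_traces(generate_assay(cfg, porcine_0nM())))
  expect_equal(est$catastrophe_distance,
               est$growth_rate / est$catastrophe_freq, tolerance = 1e-12)
  expect_equal(est$rescue_distance,
               est$shrink_rate / est$rescue_freq, tolerance = 1e-12)
})

test_that("the pipeline recovers generating parameters at published event counts", {
  d <- porcine_0nM()
  cfg <- assay_config(n_microtubules = 65, duration_min = 10, seed = 42)
  est <- estimate_dynamics(segment_traces(generate_assay(cfg, d)))
  within_3se(est$growth_rate, 0.32, est$growth_se, 0.02)
  within_3se(est$catastrophe_freq, 0.166, est$catastrophe_se, 0.015)
  within_3se(est$shrink_rate, 27.6, est$shrink_se, 1.0)
  within_3se(est$rescue_freq, 0.88, est$rescue_se, 0.33)
})

test_that("raising the catastrophe rate monotonically shrinks the estimated distance", {
  fs <- c(0.05, 0.1, 0.166, 0.3, 0.5)
  dists <- vapply(seq_along(fs), function(i) {
    d <- dynamics_params(0.32, fs[i], 27.6, 0)
    cfg <- assay_config(n_microtubules = 40, duration_min = 10, seed = 60 + i)
    estimate_dynamics(segment_traces(generate_assay(cfg, d)))$catastrophe_distance
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("total-time and growth-time denominators differ as shrinkage accumulates", {
  # slow shrinkage sampled at 4 s so shrink phases span several frames
  d <- dynamics_params(0.5, 0.3, 8, 0)
  cfg <- assay_config(n_microtubules = 20, duration_min = 10, seed = 43,
                      frame_interval_s = 4)
  seg <- segment_traces(generate_assay(cfg, d))
  f_g <- estimate_dynamics(seg, freq_denominator = "growth_time")
  f_t <- estimate_dynamics(seg, freq_denominator = "total_time")
  expect_lt(f_t$catastrophe_freq, f_g$catastrophe_freq)
  expect_equal(f_g$n_cat, f_t$n_cat)
})

test_that("binned growth rates are flat without motors and weight by bin occupancy", {
  # one segment fully inside one bin contributes its own slope
  segs <- tibble::tibble(kind = "growth", L_start_um = 2.2, L_end_um = 2.8,
                         slope_um_min = 0.42, duration_min = 1.5)
  b <- binned_growth_vs_length(segs)
  expect_equal(b$mean_rate[b$bin_lo == 2], 0.42)
  expect_true(all(is.na(b$mean_rate[b$bin_lo != 2])))
  # a segment spanning two bins splits its time proportionally
  segs2 <- tibble::tibble(kind = "growth", L_start_um = 1, L_end_um = 5,
                          slope_um_min = 0.5, duration_min = 4)
  b2 <- binned_growth_vs_length(segs2, bin_edges = c(0, 3, 6))
  expect_equal(b2$time_min, c(2, 2))
  # flat-truth fixture: no significant trend of rate on length
  cfg <- assay_config(n_microtubules = 50, duration_min = 10, seed = 44)
  traces <- generate_assay(cfg, porcine_0nM())
  seg <- segment_traces(traces)
  loc <- local_growth_segments(traces, seg)
  bb <- binned_growth_vs_length(loc)
  bb <- bb[bb$n >= 5, ]
  fit <- stats::lm(mean_rate ~ bin_mid, data = bb, weights = 1 / se^2)
  co <- summary(fit)$coefficients
  expect_lt(abs(co["bin_mid", 1]), 3 * co["bin_mid", 2])
})

test_that("binned growth tracks the generating length law in coupled fixtures", {
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
  p <- coupling_params()
  cfg <- assay_config(kip2_nm = 5, n_microtubules = 50, duration_min = 10,
                      seed = 31)
  traces <- generate_assay(cfg, d0, p = p, law = TRUE)
  seg <- segment_traces(traces)
  bb <- binned_growth_vs_length(local_growth_segments(traces, seg))
  bb <- bb[bb$n >= 20 & bb$bin_lo >= 2, ]
  expect_gt(nrow(bb), 1)
  pred <- growth_rate_vs_length(bb$bin_mid, 5, p)
  expect_true(all(abs(bb$mean_rate - pred) < 3 * bb$se + 0.02))
  expect_true(all(diff(bb$mean_rate) > 0))
})

test_that("catastrophe-length statistic splits hand-countable cases correctly", {
  # one trajectory growing 0 -> 6 um with a single catastrophe at 6 um
  segs <- tibble::tibble(kind = "growth", L_start_um = 0, L_end_um = 6,
                         slope_um_min = 0.5, duration_min = 12,
                         t_start_min = 0, t_end_min = 12)
  evs <- tibble::tibble(mt_id = "mt001", time_min = 12, kind = "catastrophe",
                        length_um = 6)
  r <- catastrophe_length_statistic(segs, evs, cutoff = 4)
  expect_true(is.na(r$short_um))
  expect_equal(r$dist_short_um, 4)
  expect_equal(r$long_um, 2)
  expect_equal(r$n_long, 1)
  # seed offset shifts the cutoff frame of reference
  r2 <- catastrophe_length_statistic(segs, evs, cutoff = 4, seed_length = 2)
  expect_equal(r2$dist_short_um, 2)
  expect_equal(r2$long_um, 4)
})

test_that("catastrophe-length statistic is symmetric for homogeneous dynamics", {
  cfg <- assay_config(n_microtubules = 60, duration_min = 10, seed = 32)
  tr0 <- generate_assay(cfg, dynamics_params(0.62, 0.065, 28.4, 0))
  r <- catastrophe_length_statistic(segment_traces(tr0))
  se <- sqrt((r$short_um / sqrt(r$n_short))^2 + (r$long_um / sqrt(r$n_long))^2)
  expect_lt(abs(r$short_um - r$long_um), 3 * se)
})

test_that("motor-coupled fixtures show length-dependent catastrophe protection", {
  d0 <- dynamics_params(0.294, 0.166, 27.6, 0)
  cfg <- assay_config(kip2_nm = 5, n_microtubules = 40, duration_min = 25,
                      seed = 33)
  traces <- generate_assay(cfg, d0, p = coupling_params(), law = TRUE)
  r <- catastrophe_length_statistic(segment_traces(traces))
  expect_gt(r$n_long, 5)
  expect_gt(r$long_um, r$short_um)
})
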