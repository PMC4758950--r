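# Published per-condition parameters used repeatedly in tests
porcine_0nM <- function() dynamics_params(0.32, 0.166, 27.6, 0.88)
porcine_40nM <- function() dynamics_params(0.94, 0.004, 27.6, 0)
yeast_0nM <- function() dynamics_params(0.257, 0.234, 27.6, 0)

# Hand-built noiseless trace: grow at v for t_grow minutes, then shrink at
# vs to zero, then regrow; sampled every dt_s seconds over duration_min.
sawtooth_trace <- function(v = 0.32, vs = 27.6, t_grow = 5, duration_min = 10,
                           dt_s = 2, mt_id = "mt001") {
  tt <- seq(0, duration_min * 60, by = dt_s) / 60
  peak <- v * t_grow
  t_zero <- t_grow + peak / vs
  pos <- ifelse(tt <= t_grow, v * tt,
         ifelse(tt <= t_zero, peak - vs * (tt - t_grow),
                v * (tt - t_zero)))
  tibble::tibble(mt_id = mt_id, time_s = tt * 60, position_um = pos)
}

# acceptance band: 3 x the largest applicable standard error
within_3se <- function(est, truth, ...) {
  ses <- c(...)
  ses <- ses[is.finite(ses) & ses > 0]
  expect_true(length(ses) > 0)
  expect_lt(abs(est - truth), 3 * max(ses))
}
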