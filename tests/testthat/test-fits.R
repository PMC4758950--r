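test_that("the exponential MLE equals the (censoring-adjusted) sample mean", {
  set.seed(5)
  x <- rexp(1e4, 1 / 3.6)
  f <- fit_exponential(x)
  x0 <- tidy(f)$estimate[tidy(f)$term == "x0"]
  expect_equal(x0, mean(x), tolerance = 1e-12)          # analytic identity
  expect_lt(abs(x0 - 3.6), 3 * 3.6 / 100)               # recovers the mean
  # right-censoring: x0 = sum of all records / number uncensored
  f2 <- fit_exponential(c(1, 2, 3), censored = c(FALSE, FALSE, TRUE))
  expect_equal(tidy(f2)$estimate, 3)
  # single observation
  expect_equal(tidy(fit_exponential(2.7))$estimate, 2.7)
  expect_error(fit_exponential(c(1, 2), censored = c(TRUE, TRUE)), "censored")
})

test_that("the histogram method reproduces the A*exp(-x/x0) fit", {
  set.seed(6)
  x <- rexp(5e3, 1 / 3.6)
  f <- fit_exponential(x, method = "histogram", bins = 25)
  td <- tidy(f)
  expect_setequal(td$term, c("A", "x0"))
  expect_lt(abs(td$estimate[td$term == "x0"] - 3.6), 0.4)
  # first-bin exclusion for short-run under-representation
  xd <- x[x > 0.5 | runif(length(x)) < 0.3]
  fd <- fit_exponential(xd, method = "histogram", bins = 25,
                        drop_first_bin = TRUE)
  expect_lt(abs(tidy(fd)$estimate[tidy(fd)$term == "x0"] - 3.6), 0.6)
})

test_that("censored-run fits recover the lattice run length", {
  tab <- generate_run_table(motor_params(), 5000, seed = 20)
  f <- fit_exponential(tab$run_um, censored = tab$censored)
  x0 <- tidy(f)$estimate[tidy(f)$term == "x0"]
  se <- tidy(f)$std.error[tidy(f)$term == "x0"]
  expect_lt(abs(x0 - 4.1), 3 * se)
})

test_that("saturation fits recover exact half-max and handle the published tables", {
  # zero-noise recovery in free mode
  cc <- c(0, 1, 2, 5, 10, 20, 40)
  df <- data.frame(conc = cc, rate = 0.3 + (1.0 - 0.3) * cc / (7 + cc))
  f <- fit_saturation(df, response = "rate", conc = "conc", plateau = "free")
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "half_max_conc"], 7, tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "base"], 0.3, tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "plateau"], 1.0, tolerance = 1e-6)
  # porcine growth column: anchored half-max near 7 nM
  porc <- kip2_conditions("porcine")
  fp <- fit_saturation(porc, response = "growth_rate", conc = "kip2_nm",
                       se = "growth_se")
  Kp <- tidy(fp)$estimate[tidy(fp)$term == "half_max_conc"]
  expect_gt(Kp, 4); expect_lt(Kp, 10)
  # the free 3-parameter fit on the same data is weakly identified
  ff <- fit_saturation(porc, response = "growth_rate", conc = "kip2_nm",
                       se = "growth_se", plateau = "free")
  Kse <- tidy(ff)$std.error[tidy(ff)$term == "half_max_conc"]
  expect_gt(Kse, 5)
  expect_error(fit_saturation(porc[1:3, ], response = "growth_rate",
                              conc = "kip2_nm"), "4 concentrations")
})

test_that("yeast dose-response half-max is consistent with about 12 nM", {
  yst <- kip2_conditions("yeast")
  fy <- fit_saturation(yst, response = "growth_rate", conc = "kip2_nm",
                       se = "growth_se")
  td <- tidy(fy)
  K <- td$estimate[td$term == "half_max_conc"]
  Kse <- td$std.error[td$term == "half_max_conc"]
  expect_lt(abs(K - 12), 3 * Kse)
})

test_that("length-law fits recover parameters and degenerate gracefully", {
  p <- coupling_params()
  grid <- expand.grid(bin_mid = c(1, 2.5, 3.5, 5, 7, 10, 14, 20),
                      kip2_nm = c(0, 1, 2, 5, 10, 20, 40))
  grid$mean_rate <- growth_rate_vs_length(grid$bin_mid, grid$kip2_nm, p)
  # exact data: essentially zero residual
  f0 <- fit_length_law(grid)
  expect_lt(glance(f0)$rss, 1e-12)
  td <- tidy(f0)
  expect_equal(td$estimate[td$term == "v0"], 0.294, tolerance = 1e-5)
  expect_equal(td$estimate[td$term == "vmax"], 1.03, tolerance = 1e-4)
  expect_equal(td$estimate[td$term == "A"], 39.8, tolerance = 1e-3)
  # SE-scaled noise: parameters within 3 SE
  set.seed(9)
  grid$se <- 0.02
  grid$mean_rate <- grid$mean_rate + rnorm(nrow(grid), 0, 0.02)
  f1 <- fit_length_law(grid)
  td1 <- tidy(f1)
  for (tm in c("v0", "vmax", "A")) {
    truth <- c(v0 = 0.294, vmax = 1.03, A = 39.8)[[tm]]
    expect_lt(abs(td1$estimate[td1$term == tm] - truth),
              3 * td1$std.error[td1$term == tm])
  }
  # data at c = 0 only: saturation parameters unidentifiable, flagged
  g0 <- grid[grid$kip2_nm == 0, ]
  fu <- fit_length_law(g0)
  expect_true(glance(fu)$flagged)
  expect_true(is.na(tidy(fu)$estimate[tidy(fu)$term == "vmax"]))
  expect_equal(tidy(fu)$estimate[tidy(fu)$term == "v0"],
               mean(g0$mean_rate), tolerance = 0.05)
})

test_that("weighted tubulin regression yields the association rate constant", {
  # exact line through kon = 0.70 uM^-1 s^-1 (slope 0.02585 um/min/uM)
  tub <- c(4, 6, 8, 10, 12, 14)
  df <- data.frame(tubulin_um = tub, rate = -0.05 + slope_from_kon(0.70) * tub,
                   se = rep(0.01, 6))
  f <- tubulin_kinetics_regression(df, rate = "rate", se = "se")
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "kon"], 0.70, tolerance = 1e-12)
  expect_equal(td$estimate[td$term == "intercept"], -0.05, tolerance = 1e-12)
  # noisy SE-weighted recovery within 3 SE
  set.seed(10)
  df2 <- data.frame(tubulin_um = tub,
                    rate = -0.05 + slope_from_kon(0.70) * tub + rnorm(6, 0, 0.01),
                    se = rep(0.01, 6))
  f2 <- tubulin_kinetics_regression(df2, rate = "rate", se = "se")
  td2 <- tidy(f2)
  expect_lt(abs(td2$estimate[td2$term == "kon"] - 0.70),
            3 * td2$std.error[td2$term == "kon"])
  expect_error(tubulin_kinetics_regression(df[1:2, ], rate = "rate"),
               "3 tubulin")
})

test_that("fit objects expose broom-style tidy, glance and autoplot", {
  porc <- kip2_conditions("porcine")
  f <- fit_saturation(porc, response = "growth_rate", conc = "kip2_nm",
                      se = "growth_se")
  expect_s3_class(tidy(f), "tbl_df")
  expect_named(tidy(f), c("term", "estimate", "std.error"))
  expect_s3_class(glance(f), "tbl_df")
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  tr <- simulate_dynamic_instability(porcine_0nM(), 5, seed = 1)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  expect_s3_class(plot_dose_response(porc), "ggplot")
  expect_s3_class(plot_expected_length(porc), "ggplot")
})
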