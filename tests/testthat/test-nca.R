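test_that("trapezoid AUC handles rectangles, single points and dense exponentials", {
  expect_equal(auc_linear_trapezoid(concentration_profile("RH2", c(0, 1), c(10, 10))), 10)
  expect_equal(auc_linear_trapezoid(concentration_profile("RH2", 3, 7)), 0)
  tt <- seq(0, 20, by = 0.01)
  prof <- concentration_profile("PPD", tt, 100 * exp(-0.5 * tt))
  expect_equal(auc_linear_trapezoid(prof), 100 / 0.5 * (1 - exp(-10)),
               tolerance = 1e-3)
})

test_that("AUC is additive over subintervals and monotone in the upper limit", {
  tt <- seq(0, 10, by = 0.5)
  cc <- 50 * exp(-0.4 * tt) + 5
  whole <- auc_linear_trapezoid(concentration_profile("RH2", tt, cc))
  lo <- auc_linear_trapezoid(concentration_profile("RH2", tt[tt <= 4], cc[tt <= 4]))
  hi <- auc_linear_trapezoid(concentration_profile("RH2", tt[tt >= 4], cc[tt >= 4]))
  expect_equal(lo + hi, whole, tolerance = 1e-12)
  partial <- vapply(seq(2, 21), function(k)
    auc_linear_trapezoid(concentration_profile("RH2", tt[1:k], cc[1:k])), numeric(1))
  expect_true(all(diff(partial) >= 0))
})

test_that("terminal slope is exact on log-linear data and fails on flat tails", {
  tt <- c(4, 8, 12, 16, 20)
  prof <- concentration_profile("RH2", tt, 50 * exp(-0.3 * tt))
  ts <- terminal_slope(prof)
  expect_equal(ts$lambda_z, 0.3, tolerance = 1e-9)
  expect_equal(ts$t_half, log(2) / 0.3, tolerance = 1e-9)
  flat <- concentration_profile("RH2", tt, rep(5, 5))
  expect_error(terminal_slope(flat), class = "deglypk_halflife_error")
})

test_that("Rh2 terminal half-life on the study grid is near the reported value", {
  p <- reference_parameters()
  prof <- simulate_profile(p, dose_event("IV_RH2", 10),
                           c(0.25, 0.5, 1, 2, 4, 8, 12, 16, 24))
  t_half <- terminal_slope(prof$rh2)$t_half
  expect_gt(t_half, 2.23 * 0.85)
  expect_lt(t_half, 2.23 * 1.15)
})

test_that("V_ss equals V for a one-compartment bolus and is absent extravascularly", {
  V <- 2.39; k <- 0.8
  d <- dose_event("IV_RH2", 10)
  tt <- seq(0, 30, by = 0.02)
  cc <- dose_amount_nmol(d) / V * exp(-k * tt)
  res <- nca_summary(concentration_profile("RH2", tt, cc), d)
  expect_equal(res$mode, "iv")
  expect_equal(res$v_ss, V, tolerance = 0.01)
  expect_equal(res$t_half, log(2) / k, tolerance = 1e-6)

  ev <- nca_summary(concentration_profile("PPD", tt, cc), d)
  expect_equal(ev$mode, "extravascular")
  expect_null(ev$v_ss)
})

test_that("T_max is the first sampled time for a monotone-decreasing profile", {
  tt <- c(0.25, 0.5, 1, 2, 4)
  res <- nca_summary(concentration_profile("RH2", tt, 100 * exp(-tt)),
                     dose_event("IV_RH2", 10))
  expect_equal(res$t_max, 0.25)
  expect_equal(res$c_max, 100 * exp(-0.25))
})

test_that("dataset-level NCA excludes BLQ records and summarises by group", {
  p0 <- reference_parameters(omega = 0, sigma = 0)
  ds <- generate_study(default_design(), p0, seed = 3)
  res <- nca_table(ds)
  expect_true(all(c("c_max", "t_max", "auc_0_t") %in% names(res$subjects)))
  g1 <- res$summary[res$summary$group == "G1_iv10" &
                      res$summary$analyte == "PPD" &
                      res$summary$metric == "auc_0_t", ]
  expect_equal(g1$n, 3)
  expect_equal(g1$cv_percent, 0, tolerance = 1e-6)
})
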