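tt_study <- c(0.25, 0.5, 1, 2, 4, 8, 12, 16, 24)

test_that("zero dose gives identically zero profiles", {
  p <- reference_parameters()
  prof <- simulate_profile(p, dose_event("IV_RH2", 0), tt_study)
  expect_equal(prof$rh2$conc, numeric(length(tt_study)))
  expect_equal(prof$ppd$conc, numeric(length(tt_study)))
})

test_that("with all transfer routes off, IV Rh2 decays as a one-compartment bolus", {
  p <- update_parameters(reference_parameters(),
                         k_47 = 0, k_74 = 0, k_43 = 0, k_45 = 0)
  d <- dose_event("IV_RH2", 10)
  tt <- seq(0.25, 12, by = 0.25)
  prof <- simulate_profile(p, d, tt)
  expected <- dose_amount_nmol(d) / param(p, "V_rh2_plasma") *
    exp(-param(p, "k_40") * tt)
  expect_equal(prof$rh2$conc, expected, tolerance = 1e-6)
})

test_that("mass balance holds at every output time for every route", {
  p <- reference_parameters()
  for (route in c("IV_RH2", "PO_RH2", "IV_PPD")) {
    d <- dose_event(route, 10)
    prof <- simulate_profile(p, d, tt_study)
    totals <- rowSums(attr(prof, "amounts"))
    expect_equal(totals, rep(dose_amount_nmol(d), length(tt_study)),
                 tolerance = 1e-9)
  }
})

test_that("profiles are exactly dose-linear", {
  p <- reference_parameters()
  for (route in c("IV_RH2", "PO_RH2")) {
    p1 <- simulate_profile(p, dose_event(route, 10), tt_study)
    p2 <- simulate_profile(p, dose_event(route, 20), tt_study)
    for (an in c("rh2", "ppd")) {
      nz <- p1[[an]]$conc > 0
      if (any(nz)) {
        expect_equal(p2[[an]]$conc[nz] / p1[[an]]$conc[nz],
                     rep(2, sum(nz)), tolerance = 1e-9)
      }
    }
  }
})

test_that("refining the output grid does not change shared times", {
  p <- reference_parameters()
  d <- dose_event("IV_RH2", 10)
  coarse <- simulate_profile(p, d, tt_study)
  fine <- simulate_profile(p, d, sort(c(tt_study, tt_study - 0.1)))
  idx <- match(tt_study, fine$ppd$times)
  expect_equal(fine$ppd$conc[idx], coarse$ppd$conc, tolerance = 1e-9)
  expect_equal(fine$rh2$conc[idx], coarse$rh2$conc, tolerance = 1e-9)
})

test_that("oral Rh2 never reaches plasma intact (structural zero)", {
  p <- reference_parameters()
  prof <- simulate_profile(p, dose_event("PO_RH2", 20), tt_study)
  expect_equal(prof$rh2$conc, numeric(length(tt_study)))
  expect_gt(max(prof$ppd$conc), 0)
})

test_that("individual simulation degenerates to the noise-free profile and is seeded", {
  p0 <- reference_parameters(omega = 0, sigma = 0)
  d <- dose_event("IV_RH2", 10)
  base <- simulate_profile(p0, d, tt_study)
  ind <- simulate_individual(p0, d, tt_study, seed = 5)
  expect_profile_equal(ind$rh2, base$rh2)
  expect_profile_equal(ind$ppd, base$ppd)

  p <- reference_parameters(omega = 0.3, sigma = 0.2)
  a <- simulate_individual(p, d, tt_study, seed = 42)
  b <- simulate_individual(p, d, tt_study, seed = 42)
  expect_identical(a$rh2$conc, b$rh2$conc)
  expect_identical(a$ppd$conc, b$ppd$conc)
  cc <- simulate_individual(p, d, tt_study, seed = 43)
  expect_false(identical(a$ppd$conc, cc$ppd$conc))
  expect_true(all(a$ppd$conc >= 0))
  expect_error(simulate_individual(p, d, tt_study),
               class = "deglypk_validation_error")
})

test_that("the multiplicative residual model reproduces its nominal CV", {
  p <- reference_parameters(omega = 0, sigma = 0.2)
  d <- dose_event("IV_RH2", 10)
  y <- vapply(1:2000, function(i) {
    simulate_individual(p, d, c(1), seed = 10000 + i)$rh2$conc
  }, numeric(1))
  cv <- stats::sd(y) / mean(y)
  expect_gte(cv, 0.18)
  expect_lte(cv, 0.22)
})

test_that("times outside the horizon and incompatible routes are rejected", {
  p <- reference_parameters()
  expect_error(simulate_profile(p, dose_event("IV_RH2", 10), c(1, 60)),
               class = "deglypk_validation_error")
  expect_error(simulate_profile(p, dose_event("PO_RH2", 10), tt_study,
                                submodel = submodel_spec("A")),
               class = "deglypk_config_error")
})
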