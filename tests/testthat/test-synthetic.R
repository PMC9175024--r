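test_that("the default design matches the rat study layout", {
  des <- default_design()
  rh2 <- des$groups[des$groups$route %in% c("IV_RH2", "PO_RH2"), ]
  expect_equal(nrow(rh2), 4)
  expect_true(all(rh2$n_subjects == 3))
  expect_setequal(rh2$dose_mg_per_kg, c(10, 20))
  expect_true(all(c(0.25, 16) %in% des$sampling_times))
  ppd <- des$groups[des$groups$route == "IV_PPD", ]
  expect_equal(ppd$dose_mg_per_kg, 0.2)
  expect_equal(max(des$sampling_times), 24)
  expect_equal(max(default_design(final_sample = "20")$sampling_times), 20)
})

test_that("without variability all subjects in a group share the noise-free profile", {
  p0 <- reference_parameters(omega = 0, sigma = 0)
  des <- default_design(lloq = c(RH2 = 0, PPD = 0))
  ds <- generate_study(des, p0, seed = 12)
  g1 <- ds[ds$group == "G1_iv10" & ds$analyte == "PPD", ]
  ref <- simulate_profile(p0, dose_event("IV_RH2", 10), des$sampling_times)$ppd$conc
  for (s in unique(g1$subject_id)) {
    expect_equal(g1$conc_nmol_per_L[g1$subject_id == s], ref, tolerance = 1e-12)
  }
  expect_false(any(ds$blq))
})

test_that("generation is deterministic per seed, down to the written file", {
  p <- reference_parameters(omega = 0.3, sigma = 0.2)
  d1 <- generate_study(default_design(), p, seed = 99)
  d2 <- generate_study(default_design(), p, seed = 99)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(d1, f1); write_dataset(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_study(default_design(), p, seed = 100)
  expect_false(identical(d1$conc_nmol_per_L, d3$conc_nmol_per_L))
})

test_that("oral groups contain no quantifiable intact Rh2", {
  p <- reference_parameters(omega = 0.3, sigma = 0.2)
  ds <- generate_study(default_design(), p, seed = 5)
  po_rh2 <- ds[ds$route == "PO_RH2" & ds$analyte == "RH2", ]
  expect_true(all(po_rh2$blq))
  expect_true(all(po_rh2$conc_true_nmol_per_L == 0))
})

test_that("below-LLOQ flags follow the assay limits and keep the shadow value", {
  p <- reference_parameters(omega = 0.3, sigma = 0.2)
  des <- default_design()
  ds <- generate_study(des, p, seed = 8)
  expect_identical(ds$blq, ds$conc_nmol_per_L < 2)
  expect_true(all(ds$conc_true_nmol_per_L >= 0))
})

test_that("exposure is dose proportional", {
  # exact at zero variability (no LLOQ censoring, which is dose-asymmetric);
  # approximately 2x under the default noise
  p0 <- reference_parameters(omega = 0, sigma = 0)
  ds0 <- generate_study(default_design(lloq = c(RH2 = 0, PPD = 0)), p0, seed = 2)
  auc_of <- function(ds, group) {
    d <- ds[ds$group == group & ds$analyte == "PPD" & !ds$blq, ]
    stats::median(vapply(unique(d$subject_id), function(s) {
      dd <- d[d$subject_id == s, ]
      auc_linear_trapezoid(concentration_profile("PPD", dd$time_h, dd$conc_nmol_per_L))
    }, numeric(1)))
  }
  expect_equal(auc_of(ds0, "G4_po20") / auc_of(ds0, "G3_po10"), 2, tolerance = 1e-9)
  expect_equal(auc_of(ds0, "G2_iv20") / auc_of(ds0, "G1_iv10"), 2, tolerance = 1e-9)
  p <- reference_parameters(omega = 0.3, sigma = 0.2)
  ds <- generate_study(default_design(), p, seed = 2)
  ratio <- auc_of(ds, "G4_po20") / auc_of(ds, "G3_po10")
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.3)
})

test_that("a generated study feeds the calibration and returns the generating routes", {
  p0 <- reference_parameters(omega = 0, sigma = 0)
  ds <- generate_study(default_design(), p0, seed = 31)
  d10 <- ds[ds$dose_mg_per_kg %in% c(10, 0.2), ]
  fitted <- staged_calibration(list(A = d10, B = d10, C = d10, D = d10),
                               init = ref_inits())
  for (mode in c("IV", "PO")) {
    gen <- if (mode == "IV") iv_route_fractions(p0) else po_route_fractions(p0)
    fit <- if (mode == "IV") iv_route_fractions(fitted) else po_route_fractions(fitted)
    expect_equal(fit$percent, gen$percent, tolerance = 0.5 / 100)
  }
})
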