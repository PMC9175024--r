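make_dataset <- function(params, route, analyte, dose, times, group = "G",
                         n_subjects = 1) {
  prof <- simulate_profile(params, dose_event(route, dose), times)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject_id = paste0(group, "_S", s), group = group,
               route = route, analyte = analyte, dose_mg_per_kg = dose,
               time_h = times,
               conc_nmol_per_L = prof[[tolower(analyte)]]$conc,
               blq = FALSE, stringsAsFactors = FALSE)
  }))
}

tt_study <- c(0.25, 0.5, 1, 2, 4, 8, 12, 16, 24)

test_that("the multiplicative objective is zero-residual at the generating values", {
  p <- reference_parameters()
  d <- make_dataset(p, "IV_RH2", "RH2", 10, tt_study)
  obj <- objective_multiplicative(p, d, submodel_spec("A"))
  expect_lt(attr(obj, "residual_sumsq"), 1e-18)
})

test_that("the proportional residual term is scale invariant", {
  p <- reference_parameters()
  d <- make_dataset(p, "IV_RH2", "RH2", 10, tt_study)
  d$conc_nmol_per_L <- d$conc_nmol_per_L * 1.1 # some misfit
  r1 <- attr(objective_multiplicative(p, d, submodel_spec("A")), "residual_sumsq")
  # scaling data and predictions by 10: shrink the volume, scale the data
  p10 <- update_parameters(p, V_rh2_plasma = 2.39 / 10)
  d10 <- d; d10$conc_nmol_per_L <- d$conc_nmol_per_L * 10
  r2 <- attr(objective_multiplicative(p10, d10, submodel_spec("A")), "residual_sumsq")
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("dropping a record never increases the residual sum; BLQ are excluded", {
  p <- reference_parameters()
  d <- make_dataset(p, "IV_RH2", "RH2", 10, tt_study)
  d$conc_nmol_per_L <- d$conc_nmol_per_L * seq(0.8, 1.2, length.out = nrow(d))
  full <- attr(objective_multiplicative(p, d, submodel_spec("A")), "residual_sumsq")
  less <- attr(objective_multiplicative(p, d[-3, ], submodel_spec("A")), "residual_sumsq")
  expect_lte(less, full)
  d_blq <- d
  d_blq$blq[3] <- TRUE
  flagged <- attr(objective_multiplicative(p, d_blq, submodel_spec("A")), "residual_sumsq")
  expect_equal(flagged, less, tolerance = 1e-12)
})

test_that("a non-positive prediction at an observation raises an objective error", {
  p <- reference_parameters()
  d <- make_dataset(p, "IV_RH2", "RH2", 10, tt_study)
  d$dose_mg_per_kg <- 0 # no dose, predictions identically zero
  expect_error(objective_multiplicative(p, d, submodel_spec("A")),
               class = "deglypk_objective_error")
})

test_that("the frozen biliary split reproduces the reported pair and guards feasibility", {
  fr <- derive_frozen_biliary(4.67, 0.276, 0.09)
  expect_equal(round(unname(fr[["k_43"]]), 2), 1.29)
  expect_equal(round(unname(fr[["k_40"]]), 2), 3.29)
  fr0 <- derive_frozen_biliary(4.67, 0, 0.09)
  expect_equal(unname(fr0[["k_43"]]), 0)
  expect_equal(unname(fr0[["k_40"]]), 4.67 - 0.09)
  expect_error(derive_frozen_biliary(1.0, 0.5, 0.6),
               class = "deglypk_infeasible_error")
})

test_that("sub-model A recovers its parameters from noise-free data", {
  p <- reference_parameters()
  d <- make_dataset(p, "IV_RH2", "RH2", 10, tt_study, n_subjects = 3)
  init <- ref_inits()$A
  fit <- fit_submodel(submodel_spec("A"), d, init = init)
  truth <- c(V_rh2_plasma = 2.39, k_e = 4.67, k_47 = 2.08, k_74 = 0.48)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-3)
  expect_true(fit$convergence)
  # objective no worse than at the initial values
  init_obj <- objective_multiplicative(
    parameter_set(c(init["V_rh2_plasma"], k_40 = unname(init[["k_e"]]),
                    k_43 = 0, k_45 = 0, init[c("k_47", "k_74")],
                    V_ppd_plasma = 1, k_50 = 0, k_58 = 0, k_85 = 0,
                    k_t = 0, k_60 = 0, k_12 = 0, k_13 = 0, k_20 = 0)),
    d, submodel_spec("A"))
  expect_lte(fit$objective_value, as.numeric(init_obj))
})

test_that("sub-model C honours its frozen biliary pair", {
  p <- reference_parameters()
  d <- make_dataset(p, "IV_RH2", "PPD", 10, tt_study)
  fixed <- c(V_rh2_plasma = 2.39, k_e = 4.67, k_47 = 2.08, k_74 = 0.48,
             V_ppd_plasma = 0.29, k_50 = 4.88, k_58 = 27.3, k_85 = 3.38,
             k_43 = 0.276 * 4.67)
  fit <- fit_submodel(submodel_spec("C"), d, init = ref_inits()$C, fixed = fixed)
  expect_identical(unname(fit$fixed[["k_43"]]), unname(fixed[["k_43"]]))
  expect_equal(unname(fit$fixed[["k_40"]]),
               4.67 - fixed[["k_43"]] - fit$estimates[["k_45"]], tolerance = 1e-12)
})

test_that("staged calibration aborts naming the missing step and preserves stage results", {
  p0 <- reference_parameters(omega = 0, sigma = 0)
  ds <- generate_study(default_design(), p0, seed = 21)
  d10 <- ds[ds$dose_mg_per_kg %in% c(10, 0.2), ]
  expect_error(
    staged_calibration(list(A = d10, C = d10, D = d10), init = ref_inits()),
    class = "deglypk_staging_error", regexp = "Step 2")
  fitted <- staged_calibration(list(A = d10, B = d10, C = d10, D = d10),
                               init = ref_inits())
  fits <- attr(fitted, "fits")
  # step 3 leaves step-1 estimates untouched in the assembled set
  expect_identical(unname(param_values(fitted)[["V_rh2_plasma"]]),
                   unname(fits$A$estimates[["V_rh2_plasma"]]))
  expect_identical(unname(param_values(fitted)[["k_47"]]),
                   unname(fits$A$estimates[["k_47"]]))
  # assembled set passes validation with k_e == k_40 + k_43 + k_45
  expect_equal(param(fitted, "k_e"),
               param(fitted, "k_40") + param(fitted, "k_43") + param(fitted, "k_45"),
               tolerance = 1e-9)
})

test_that("cluster-robust confidence intervals cover the truth in replicate studies", {
  rec <- cached_recovery()
  expect_equal(rec$n_studies, 20)
  expect_gte(rec$ci_coverage, 0.80)
})
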