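# Synthetic rat-study generator. Emulates the study design: four Rh2 groups
# (I.V. and P.O. at 10 and 20 mg/kg, n = 3 each) plus an auxiliary I.V. PPD
# group (0.2 mg/kg, n = 3) supporting PPD-disposition estimation; sampling at
# 0.25, 0.5, 1, 2, 4, 8, 12, 16 and 20 or 24 h. Body weight is ignored: all
# rates and volumes are per kg, so it cancels.

#' Define a study design
#'
#' @param groups Data frame with columns `group`, `route`, `dose_mg_per_kg`,
#'   `n_subjects`.
#' @param sampling_times Increasing post-dose sampling times, h.
#' @param lloq Named vector of assay lower limits of quantitation per analyte,
#'   nmol/L (assumed values; the original assay limits are not public).
#' @param horizon Study horizon, h.
#' @return A `study_design` object.
#' @export
study_design <- function(groups, sampling_times, lloq = c(RH2 = 2, PPD = 2),
                         horizon = 24) {
  stopifnot(is.data.frame(groups),
            all(c("group", "route", "dose_mg_per_kg", "n_subjects") %in% names(groups)))
  if (any(groups$n_subjects < 1)) {
    pk_error("n_subjects must be >= 1", "deglypk_validation_error")
  }
  if (!all(groups$route %in% DOSE_ROUTES)) {
    pk_error("unknown route in design", "deglypk_validation_error")
  }
  if (any(diff(sampling_times) <= 0) || any(sampling_times < 0)) {
    pk_error("sampling times must be increasing and non-negative",
             "deglypk_validation_error")
  }
  if (any(lloq < 0)) pk_error("lloq must be >= 0", "deglypk_validation_error")
  structure(list(groups = groups, sampling_times = as.numeric(sampling_times),
                 lloq = lloq, horizon = horizon),
            class = "study_design")
}

#' The default rat study design
#'
#' Four Rh2 groups of three rats (I.V. bolus 10 and 20 mg/kg; P.O. 10 and
#' 20 mg/kg) plus one auxiliary I.V. PPD group at 0.2 mg/kg (n = 3), sampled
#' at 0.25, 0.5, 1, 2, 4, 8, 12, 16 and 20 or 24 h post dose.
#'
#' @param final_sample `"24"` (default) or `"20"`: the last sampling time, h.
#' @param lloq Assay limits per analyte, nmol/L.
#' @return A `study_design`.
#' @export
default_design <- function(final_sample = c("24", "20"), lloq = c(RH2 = 2, PPD = 2)) {
  final_sample <- as.numeric(match.arg(final_sample))
  groups <- data.frame(
    group = c("G1_iv10", "G2_iv20", "G3_po10", "G4_po20", "G5_ppd_iv"),
    route = c("IV_RH2", "IV_RH2", "PO_RH2", "PO_RH2", "IV_PPD"),
    dose_mg_per_kg = c(10, 20, 10, 20, 0.2),
    n_subjects = 3,
    stringsAsFactors = FALSE
  )
  times <- c(0.25, 0.5, 1, 2, 4, 8, 12, 16, final_sample)
  study_design(groups, times, lloq = lloq, horizon = max(24, final_sample))
}

#' Generate a complete synthetic study
#'
#' For every subject: draw log-normal inter-individual parameter multipliers,
#' simulate the individual's noise-free profiles, apply multiplicative
#' residual error (truncated at zero), and flag measurements below the
#' analyte's LLOQ as BLQ. The noise-free model value is retained in the
#' `conc_true_nmol_per_L` shadow column. Deterministic given `seed`.
#'
#' @param design A [study_design()].
#' @param params A `pk_parameters` object; its `omega`/`sigma` drive the
#'   variability.
#' @param seed Integer seed (required).
#' @param n_transit Number of transit compartments.
#' @return A validated long-format dataset (data frame).
#' @export
generate_study <- function(design, params, seed, n_transit = 3) {
  stopifnot(inherits(design, "study_design"), inherits(params, "pk_parameters"))
  if (missing(seed)) pk_error("seed is required", "deglypk_validation_error")
  tt <- design$sampling_times
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(design$groups))) {
      grp <- design$groups[g, ]
      dose <- dose_event(grp$route, grp$dose_mg_per_kg)
      true_prof <- NULL
      for (s in seq_len(grp$n_subjects)) {
        subj_seed <- floor(stats::runif(1, 1, 2^30))
        indiv <- simulate_individual(params, dose, tt, seed = subj_seed,
                                     n_transit = n_transit,
                                     horizon = max(design$horizon, max(tt), 48))
        truth <- simulate_profile(apply_iiv(params, attr(indiv, "eta")),
                                  dose, tt, n_transit = n_transit,
                                  horizon = max(design$horizon, max(tt), 48))
        for (an in c("RH2", "PPD")) {
          y <- indiv[[tolower(an)]]$conc
          lloq <- unname(design$lloq[[an]])
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sprintf("%s_S%d", grp$group, s),
            group = grp$group, route = grp$route, analyte = an,
            dose_mg_per_kg = grp$dose_mg_per_kg,
            time_h = tt, conc_nmol_per_L = y,
            blq = y < lloq,
            conc_true_nmol_per_L = truth[[tolower(an)]]$conc,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    validate_dataset(do.call(rbind, rows))
  })
}
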