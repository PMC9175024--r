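# Non-compartmental analysis: linear trapezoid AUC/AUMC, terminal log-linear
# regression with adjusted-R^2 window selection, and the summary metric set
# (C_max, T_max, AUC_0-t, t_1/2, lambda_z, V_ss for intravenous profiles).

as_profile <- function(profile) {
  if (inherits(profile, "concentration_profile")) return(profile)
  pk_error("expected a concentration_profile", "deglypk_validation_error")
}

#' Linear-trapezoid area under the curve
#'
#' `AUC = sum 0.5 (C_i + C_{i+1}) (t_{i+1} - t_i)`; zero for a single point.
#'
#' @param profile A [concentration_profile()].
#' @return AUC from the first to the last sampled time, h*nmol/L.
#' @export
auc_linear_trapezoid <- function(profile) {
  p <- as_profile(profile)
  if (length(p$times) < 1L) pk_error("empty profile", "deglypk_validation_error")
  if (length(p$times) == 1L) return(0)
  sum(0.5 * (p$conc[-1] + p$conc[-length(p$conc)]) * diff(p$times))
}

# First-moment area by the same trapezoid rule (for V_ss).
aumc_linear_trapezoid <- function(profile) {
  p <- as_profile(profile)
  if (length(p$times) < 2L) return(0)
  m <- p$conc * p$times
  sum(0.5 * (m[-1] + m[-length(m)]) * diff(p$times))
}

#' Terminal elimination rate constant and half-life
#'
#' Fits log-linear regressions over candidate terminal windows (the last `k`
#' positive-concentration points strictly after `T_max`, for every
#' `k >= min_points`) and keeps the window with the best adjusted R-squared.
#'
#' @param profile A [concentration_profile()].
#' @param min_points Minimum number of points in the regression (>= 3).
#' @return List with `lambda_z` (1/h), `t_half` (h), `n_points`,
#'   `adj_r_squared` and `intercept` (log nmol/L).
#' @export
terminal_slope <- function(profile, min_points = 3) {
  p <- as_profile(profile)
  stopifnot(min_points >= 3)
  i_max <- which.max(p$conc)
  sel <- seq_along(p$times) > i_max & p$conc > 0
  t <- p$times[sel]; y <- log(p$conc[sel])
  n <- length(t)
  if (n < min_points) {
    pk_error("not enough terminal points after T_max for regression",
             "deglypk_halflife_error")
  }
  best <- NULL
  for (k in min_points:n) {
    idx <- (n - k + 1):n
    fit <- stats::lm(y[idx] ~ t[idx])
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || (is.finite(r2) && r2 > best$r2 + 1e-12)) {
      best <- list(r2 = r2, slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]), k = k)
    }
  }
  # a slope this shallow (half-life > ~200 years) is numerical noise on a
  # flat tail, not decay
  if (!is.finite(best$slope) || best$slope >= -1e-10) {
    pk_error("terminal phase is not decaying; half-life undefined",
             "deglypk_halflife_error")
  }
  lambda_z <- -best$slope
  list(lambda_z = lambda_z, t_half = log(2) / lambda_z,
       n_points = best$k, adj_r_squared = best$r2, intercept = best$intercept)
}

#' Non-compartmental summary of a concentration profile
#'
#' Computes `C_max`/`T_max` from the observed maximum, `AUC_0-t` by the linear
#' trapezoid, the terminal slope (when enough decaying points exist), and for
#' intravenous profiles the steady-state volume of distribution
#' `V_ss = Dose * AUMC_inf / AUC_inf^2`. The extravascular mode reports no
#' `V_ss`.
#'
#' @param profile A [concentration_profile()].
#' @param dose A `dose_event` for the administered dose.
#' @param mode `"auto"` (intravenous when the profile's analyte is the dosed
#'   analyte given by an I.V. route), `"iv"` or `"extravascular"`.
#' @param min_points Passed to [terminal_slope()].
#' @return An `nca_result` list: `c_max`, `t_max`, `auc_0_t`, `lambda_z`,
#'   `t_half`, `auc_extrapolated_fraction`, and for I.V. profiles `v_ss`,
#'   `c0_back_extrapolated` (log-linear through the first two samples) and
#'   `auc_0_t_with_c0` (AUC including the pre-first-sample segment).
#' @export
nca_summary <- function(profile, dose, mode = c("auto", "iv", "extravascular"),
                        min_points = 3) {
  p <- as_profile(profile)
  stopifnot(inherits(dose, "dose_event"))
  mode <- match.arg(mode)
  if (mode == "auto") {
    dosed_analyte <- if (dose$route == "IV_PPD") "PPD" else "RH2"
    iv <- startsWith(dose$route, "IV") && p$analyte == dosed_analyte
    mode <- if (iv) "iv" else "extravascular"
  }
  i_max <- which.max(p$conc)
  res <- list(
    analyte = p$analyte, mode = mode,
    c_max = p$conc[i_max], t_max = p$times[i_max],
    auc_0_t = auc_linear_trapezoid(p),
    lambda_z = NA_real_, t_half = NA_real_,
    auc_extrapolated_fraction = NA_real_
  )
  # I.V. bolus: back-extrapolate C0 log-linearly through the first two
  # samples (standard NCA practice for the pre-first-sample segment) and
  # report the AUC including the [0, t1] piece alongside the plain trapezoid
  if (mode == "iv" && p$times[1] > 0 && length(p$conc) >= 2 &&
      p$conc[1] > p$conc[2] && p$conc[2] > 0) {
    lam01 <- log(p$conc[1] / p$conc[2]) / (p$times[2] - p$times[1])
    res$c0_back_extrapolated <- p$conc[1] * exp(lam01 * p$times[1])
    res$auc_0_t_with_c0 <- res$auc_0_t +
      0.5 * (res$c0_back_extrapolated + p$conc[1]) * p$times[1]
  }
  term <- tryCatch(terminal_slope(p, min_points), deglypk_halflife_error = function(e) NULL)
  if (!is.null(term)) {
    res$lambda_z <- term$lambda_z
    res$t_half <- term$t_half
    c_last <- p$conc[length(p$conc)]
    tail_auc <- c_last / term$lambda_z
    auc_inf <- res$auc_0_t + tail_auc
    res$auc_extrapolated_fraction <- tail_auc / auc_inf
    if (mode == "iv") {
      t_last <- p$times[length(p$times)]
      aumc_inf <- aumc_linear_trapezoid(p) +
        c_last * t_last / term$lambda_z + c_last / term$lambda_z^2
      res$v_ss <- dose_amount_nmol(dose) * aumc_inf / auc_inf^2
    }
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA (%s, %s dosing)\n", x$analyte, x$mode))
  cat(sprintf("  C_max  %.4g nmol/L at T_max %.3g h\n", x$c_max, x$t_max))
  cat(sprintf("  AUC_0-t %.4g h*nmol/L\n", x$auc_0_t))
  if (is.finite(x$t_half)) {
    cat(sprintf("  t_1/2  %.3g h (lambda_z %.3g 1/h)\n", x$t_half, x$lambda_z))
  }
  if (!is.null(x$v_ss)) cat(sprintf("  V_ss   %.3g L/kg\n", x$v_ss))
  invisible(x)
}

#' Per-subject NCA over a long-format dataset
#'
#' Runs [nca_summary()] for every (subject, analyte) profile in a dataset
#' (BLQ records excluded) and returns a per-subject table together with
#' group-level mean and CV% summaries.
#'
#' @param dataset A validated dataset data frame (see [read_dataset()]).
#' @param min_points Passed to [terminal_slope()].
#' @return List with data frames `subjects` and `summary`.
#' @export
nca_table <- function(dataset, min_points = 3) {
  dataset <- validate_dataset(dataset)
  keys <- unique(dataset[, c("subject_id", "group", "route", "analyte",
                             "dose_mg_per_kg")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    d <- dataset[dataset$subject_id == k$subject_id & dataset$analyte == k$analyte &
                   !dataset$blq, , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    prof <- concentration_profile(k$analyte, d$time_h, d$conc_nmol_per_L,
                                  subject = k$subject_id)
    dose <- dose_event(k$route, k$dose_mg_per_kg)
    r <- nca_summary(prof, dose, min_points = min_points)
    data.frame(k, c_max = r$c_max, t_max = r$t_max, auc_0_t = r$auc_0_t,
               t_half = r$t_half,
               v_ss = if (is.null(r$v_ss)) NA_real_ else r$v_ss,
               stringsAsFactors = FALSE)
  })
  subjects <- do.call(rbind, rows)
  metrics <- c("c_max", "t_max", "auc_0_t", "t_half", "v_ss")
  groups <- unique(subjects[, c("group", "route", "analyte", "dose_mg_per_kg")])
  summ <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    d <- subjects[subjects$group == g$group & subjects$analyte == g$analyte, ]
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]][is.finite(d[[m]])]
      if (!length(v)) return(NULL)
      data.frame(g, metric = m, mean = mean(v),
                 cv_percent = if (length(v) > 1) 100 * stats::sd(v) / mean(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  list(subjects = subjects, summary = summ)
}
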