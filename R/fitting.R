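# Staged parameter estimation. Estimator: naive-pooled maximum likelihood with
# a multiplicative (proportional) residual-error model, sigma profiled out.
# Optimization is on log-parameters (positivity by construction) with a
# deterministic multi-start around the initial values.

#' Negative log-likelihood under the multiplicative error model
#'
#' For observations `y_i` with model predictions `f_i`,
#' `y = f (1 + eps)`, `eps ~ N(0, sigma^2)`:
#' `nll = sum(log(sigma f_i)) + sum((y_i - f_i)^2 / (2 sigma^2 f_i^2)) + n/2 log(2 pi)`.
#' When `sigma` is `NULL` it is profiled out at its conditional maximum
#' `sigma_hat^2 = RSS/n` with `RSS = sum(((y - f)/f)^2)`. BLQ records are
#' excluded.
#'
#' @param params A `pk_parameters` object with every structural parameter the
#'   sub-model's dynamics reference.
#' @param dataset Long-format dataset (see [read_dataset()]).
#' @param submodel A [submodel_spec()] selecting the (route, analyte) records.
#' @param sigma Fixed residual sd, or `NULL` to profile.
#' @param n_transit Number of transit compartments.
#' @return The negative log-likelihood, with attributes `residual_sumsq`
#'   (the scale-free proportional RSS), `sigma_hat` and `n`.
#' @export
objective_multiplicative <- function(params, dataset, submodel, sigma = NULL,
                                     n_transit = 3) {
  d <- submodel_observations(dataset, submodel)
  f <- predict_observations(params, d, n_transit)
  if (any(f <= 0)) {
    pk_error("model prediction is not positive at an observation time",
             "deglypk_objective_error")
  }
  y <- d$conc_nmol_per_L
  r <- (y - f) / f
  rss <- sum(r^2)
  n <- length(y)
  nll <- if (is.null(sigma)) {
    s2 <- max(rss / n, 1e-30)
    sum(log(f)) + n / 2 * log(s2) + n / 2 + n / 2 * log(2 * pi)
  } else {
    if (sigma <= 0) pk_error("sigma must be positive", "deglypk_validation_error")
    sum(log(sigma * f)) + rss / (2 * sigma^2) + n / 2 * log(2 * pi)
  }
  structure(nll, residual_sumsq = rss,
            sigma_hat = if (is.null(sigma)) sqrt(rss / n) else sigma, n = n)
}

# Model predictions matched to dataset rows (one ODE solve per dose level).
predict_observations <- function(params, d, n_transit = 3) {
  f <- numeric(nrow(d))
  for (dose_mg in unique(d$dose_mg_per_kg)) {
    sel <- d$dose_mg_per_kg == dose_mg
    route <- unique(d$route[sel])
    tt <- sort(unique(d$time_h[sel]))
    prof <- simulate_profile(params, dose_event(route, dose_mg), tt,
                             n_transit = n_transit,
                             horizon = max(48, max(tt)))
    for (an in unique(d$analyte[sel])) {
      pr <- prof[[tolower(an)]]
      idx <- sel & d$analyte == an
      f[idx] <- pr$conc[match(d$time_h[idx], pr$times)]
    }
  }
  f
}

#' Freeze the biliary split of Rh2 elimination
#'
#' Given the total Rh2 elimination rate constant, the observed biliary
#' excretion fraction and the plasma transformation rate, returns the frozen
#' biliary and unknown-route rate constants:
#' `k_43 = fraction * k_e`, `k_40 = k_e - k_43 - k_45`.
#'
#' @param k_e Total Rh2 elimination rate constant, 1/h.
#' @param biliary_fraction Fraction of Rh2 elimination by bile, in `[0, 1]`
#'   (default 0.276, the reported rat value).
#' @param k_45 Plasma transformation rate constant, 1/h.
#' @return Named vector `c(k_43, k_40)`.
#' @export
derive_frozen_biliary <- function(k_e, biliary_fraction = 0.276, k_45 = 0) {
  if (biliary_fraction < 0 || biliary_fraction > 1) {
    pk_error("biliary_fraction must lie in [0, 1]", "deglypk_validation_error")
  }
  k_43 <- biliary_fraction * k_e
  k_40 <- k_e - k_43 - k_45
  if (k_40 < 0) {
    pk_error(sprintf("infeasible split: k_43 + k_45 = %g exceeds k_e = %g",
                     k_43 + k_45, k_e), "deglypk_infeasible_error")
  }
  c(k_43 = k_43, k_40 = k_40)
}

# Build the full structural parameter vector for a trial theta of one
# sub-model, holding `fixed` and filling placeholders (rate 0, volume 1) for
# parameters outside the sub-model's dynamics. Returns NULL for infeasible
# trials (negative derived k_40).
build_trial_params <- function(spec, theta, fixed, biliary_fraction) {
  base <- stats::setNames(rep(0, length(PK_PARAM_NAMES)), PK_PARAM_NAMES)
  base[PK_VOLUME_NAMES] <- 1
  base <- base[setdiff(names(base), "k_e")]
  base[names(fixed)] <- fixed
  base[names(theta)] <- theta
  if (spec$tag == "A") {
    # only the total elimination rate is identifiable from Rh2 plasma data
    base[["k_40"]] <- theta[["k_e"]]
    base[["k_43"]] <- 0
    base[["k_45"]] <- 0
  } else if (spec$tag %in% c("C", "FULL")) {
    k_e <- if (spec$tag == "C") fixed[["k_e"]] else theta[["k_e"]]
    k_43 <- if ("k_43" %in% names(fixed)) fixed[["k_43"]] else biliary_fraction * k_e
    k_40 <- k_e - k_43 - theta[["k_45"]]
    if (k_40 < 0) return(NULL)
    base[["k_43"]] <- k_43
    base[["k_40"]] <- k_40
  }
  base <- base[setdiff(names(base), "k_e")]
  parameter_set(base)
}

#' Fit one sub-model by naive-pooled maximum likelihood
#'
#' Minimizes [objective_multiplicative()] over the sub-model's estimated
#' parameters (log scale) with the fixed parameters held constant. Relative
#' standard errors (CV%) come from the inverse Hessian of the objective at
#' the optimum; 95% confidence intervals are log-normal.
#'
#' @param spec A [submodel_spec()].
#' @param dataset Long-format dataset containing the sub-model's
#'   (route, analyte) records.
#' @param init Named numeric initial values for every estimated parameter.
#' @param fixed Named numeric values held fixed (required for sub-models C, D).
#' @param biliary_fraction Biliary excretion fraction used to freeze `k_43`
#'   in sub-models C/FULL when `k_43` is not in `fixed`.
#' @param sigma Fixed residual sd or `NULL` (profiled).
#' @param n_starts Number of optimization starts; starts beyond the first
#'   perturb `init` multiplicatively in `[0.5, 2]` (deterministic given the
#'   inputs; the caller's RNG state is untouched).
#' @param n_transit Number of transit compartments.
#' @param lower,upper Box bounds on the natural scale.
#' @return A `fit_result`: `estimates`, `cv_percent`, `ci` (95%), `fixed`,
#'   `objective_value`, `convergence`, `sigma_hat`, `n_obs`.
#' @export
fit_submodel <- function(spec, dataset, init, fixed = NULL,
                         biliary_fraction = 0.276, sigma = NULL,
                         n_starts = 1, n_transit = 3,
                         lower = 1e-6, upper = 1e4) {
  stopifnot(inherits(spec, "submodel_spec"))
  init <- unlist(init)
  if (!all(spec$estimated %in% names(init))) {
    pk_error(paste0("init must name every estimated parameter of sub-model ",
                    spec$tag, ": ", paste(spec$estimated, collapse = ", ")),
             "deglypk_validation_error")
  }
  init <- init[spec$estimated]
  fixed <- unlist(fixed)
  if (spec$tag == "C" && !"k_e" %in% names(fixed)) {
    pk_error("sub-model C needs fixed k_e (from sub-model A)", "deglypk_validation_error")
  }
  d <- submodel_observations(dataset, spec)

  n_par <- length(init)
  lo <- rep(log(lower), n_par)
  hi <- rep(log(upper), n_par)

  # proportional residual vector for weighted least squares
  res_fn <- function(log_theta) {
    theta <- stats::setNames(exp(log_theta), spec$estimated)
    p <- build_trial_params(spec, theta, fixed, biliary_fraction)
    f <- if (is.null(p)) NULL else
      tryCatch(predict_observations(p, d, n_transit), error = function(e) NULL)
    if (is.null(f) || any(f <= 0)) return(rep(1e6, nrow(d)))
    (d$conc_nmol_per_L - f) / f
  }
  # profiled-sigma maximum-likelihood objective (the reported criterion)
  nll_fn <- function(log_theta) {
    theta <- stats::setNames(exp(log_theta), spec$estimated)
    p <- build_trial_params(spec, theta, fixed, biliary_fraction)
    if (is.null(p)) return(1e10)
    val <- tryCatch(
      objective_multiplicative(p, d, spec, sigma = sigma, n_transit = n_transit),
      deglypk_error = function(e) 1e10)
    as.numeric(val)
  }
  run_lm <- function(start, max_iter = 400) {
    suppressWarnings(minpack.lm::nls.lm(
      pmin(pmax(start, lo), hi), fn = res_fn, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           maxfev = 20 * max_iter,
                                           ftol = 1e-16, ptol = 1e-14, gtol = 0)))
  }
  fd_jacobian <- function(par, h = 1e-5) {
    vapply(seq_along(par), function(j) {
      e <- numeric(length(par)); e[j] <- h
      (res_fn(par + e) - res_fn(par - e)) / (2 * h)
    }, numeric(nrow(d)))
  }

  starts <- matrix(log(init), nrow = 1)
  if (n_starts > 1) {
    pert <- with_seed(20220525, {
      matrix(stats::runif((n_starts - 1) * n_par, log(0.5), log(2)),
             nrow = n_starts - 1)
    })
    starts <- rbind(starts, sweep(pert, 2, log(init), "+"))
  }
  # Stage 1: cautious local search on the likelihood. For noisy sparse data
  # the flat valleys of this model make aggressive global steps land on
  # degenerate branches (collapsed compartments), so the estimate stays in
  # the basin of the supplied initial values, as in interactive practice.
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::nlminb(starts[s, ], nll_fn, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1500,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    pk_error("all optimization starts failed", "deglypk_fit_error")
  }
  best_par <- best$par
  lm_ok <- best$convergence == 0
  rss_at <- function(par) sum(res_fn(par)^2)
  consistent <- rss_at(best_par) / nrow(d) < 1e-6

  # Stage 2, only for self-consistent (noise-free) data: Levenberg-Marquardt
  # sharpening of the least-squares solution.
  if (consistent) {
    lmfit <- tryCatch(run_lm(best_par), error = function(e) NULL)
    if (!is.null(lmfit) && lmfit$deviance <= rss_at(best_par)) {
      best_par <- lmfit$par
      lm_ok <- TRUE
    }
    best <- list(deviance = rss_at(best_par))
  }

  # Valley polish: a nearly singular Jacobian means the least-squares surface
  # has a curved, almost-flat valley (a weakly sampled disposition phase).
  # Profile the dominant parameter of the flattest direction with Brent,
  # re-fitting the remaining parameters at each trial value. Only engaged when
  # the residuals are already near zero (consistent data): there the valley
  # has a unique sharp minimum worth locating; with noisy data the along-valley
  # position is data-limited and the local solution is kept.
  if (n_par >= 2 && consistent) {
    J <- fd_jacobian(best_par)
    sv <- tryCatch(svd(J), error = function(e) NULL)
    if (!is.null(sv) && all(is.finite(sv$d)) && sv$d[n_par] > 0 &&
        sv$d[1] / sv$d[n_par] > 1e5) {
      j_star <- which.max(abs(sv$v[, n_par]))
      inner <- best_par[-j_star]
      prof <- function(lv) {
        fit <- suppressWarnings(minpack.lm::nls.lm(
          inner, fn = function(x) {
            full <- append(x, lv, after = j_star - 1L)
            res_fn(full)
          }, lower = lo[-j_star], upper = hi[-j_star],
          control = minpack.lm::nls.lm.control(maxiter = 300, maxfev = 3000,
                                               ftol = 1e-16, ptol = 1e-16,
                                               gtol = 0)))
        inner <<- fit$par
        list(rss = fit$deviance, par = fit$par)
      }
      grid <- best_par[j_star] + seq(-0.6, 0.6, by = 0.1)
      grid <- grid[grid >= lo[j_star] & grid <= hi[j_star]]
      scan <- vapply(grid, function(lv) prof(lv)$rss, numeric(1))
      centre <- grid[which.min(scan)]
      opt1 <- stats::optimize(function(lv) prof(lv)$rss,
                              interval = c(centre - 0.12, centre + 0.12),
                              tol = 1e-10)
      final <- prof(opt1$minimum)
      cand <- append(final$par, opt1$minimum, after = j_star - 1L)
      if (final$rss <= best$deviance) {
        best_par <- cand
        lm_ok <- TRUE
      }
    }
  }

  # Refine under the reported (profiled-sigma) likelihood; for noise-free data
  # this is a no-op at the exact optimum, for noisy data it applies the
  # maximum-likelihood correction to the least-squares solution.
  ml <- tryCatch(
    stats::nlminb(best_par, nll_fn, lower = lo, upper = hi,
                  control = list(iter.max = 300, eval.max = 900, rel.tol = 1e-12)),
    error = function(e) NULL)
  converged <- lm_ok
  if (!is.null(ml) && ml$objective < nll_fn(best_par)) {
    best_par <- ml$par
    converged <- lm_ok || ml$convergence == 0
  }
  est_log <- stats::setNames(best_par, spec$estimated)
  estimates <- exp(est_log)

  # CV% from the inverse Hessian of the likelihood at the optimum.
  se_log <- rep(NA_real_, length(estimates))
  H <- tryCatch(stats::optimHess(best_par, nll_fn), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dg <- diag(V)
      se_log <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  # Confidence intervals from subject-clustered sandwich standard errors:
  # with several subjects pooled under one curve, residuals are correlated
  # within subject (inter-individual variability), which the naive Hessian
  # ignores. Gauss-Newton bread J'J, per-subject score meat, t quantile with
  # (subjects - 1) degrees of freedom.
  se_ci <- se_log
  q <- 1.96
  sw <- tryCatch({
    J <- fd_jacobian(best_par)
    r <- res_fn(best_par)
    subj <- d$subject_id
    m <- length(unique(subj))
    bread <- solve(crossprod(J))
    if (m >= 2) {
      meat <- Reduce(`+`, lapply(unique(subj), function(s) {
        g <- crossprod(J[subj == s, , drop = FALSE], r[subj == s])
        tcrossprod(g)
      }))
      Vs <- bread %*% meat %*% bread * m / (m - 1)
      list(se = sqrt(pmax(diag(Vs), 0)), q = stats::qt(0.975, m - 1))
    } else {
      s2 <- sum(r^2) / max(nrow(d) - n_par, 1)
      list(se = sqrt(pmax(diag(bread) * s2, 0)), q = 1.96)
    }
  }, error = function(e) NULL)
  if (!is.null(sw) && all(is.finite(sw$se))) {
    se_ci <- sw$se
    q <- sw$q
  }
  ci <- cbind(lower = exp(est_log - q * se_ci),
              upper = exp(est_log + q * se_ci))
  rownames(ci) <- spec$estimated
  final_obj <- objective_multiplicative(
    build_trial_params(spec, estimates, fixed, biliary_fraction),
    d, spec, sigma = sigma, n_transit = n_transit)

  out_fixed <- fixed
  if (spec$tag %in% c("C", "FULL")) {
    k_e <- if (spec$tag == "C") fixed[["k_e"]] else estimates[["k_e"]]
    k_43 <- if ("k_43" %in% names(fixed)) fixed[["k_43"]] else biliary_fraction * k_e
    out_fixed[["k_43"]] <- k_43
    out_fixed[["k_40"]] <- k_e - k_43 - estimates[["k_45"]]
  }
  structure(
    list(tag = spec$tag, estimates = estimates,
         cv_percent = stats::setNames(100 * se_log, spec$estimated),
         ci = ci, fixed = out_fixed,
         objective_value = as.numeric(final_obj),
         convergence = converged,
         sigma_hat = attr(final_obj, "sigma_hat"),
         n_obs = attr(final_obj, "n")),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Sub-model %s fit (%d observations, converged: %s)\n",
              x$tag, x$n_obs, x$convergence))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-13s %9.4g  CV%% %s\n", nm, x$estimates[[nm]],
                ifelse(is.finite(x$cv_percent[[nm]]),
                       sprintf("%.1f", x$cv_percent[[nm]]), "NA")))
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(sprintf("%s=%.4g", names(x$fixed), x$fixed),
                          collapse = ", "), "\n")
  }
  cat(sprintf("  -2LL/2 = %.4f, sigma_hat = %.4g\n", x$objective_value, x$sigma_hat))
  invisible(x)
}

#' Staged four-step calibration of the full model
#'
#' Runs the model-reduction estimation sequence: (1) Rh2 disposition
#' (sub-model A) on Rh2 after I.V. Rh2; (2) PPD disposition (sub-model B) on
#' PPD after I.V. PPD; (3) sub-model C on PPD after I.V. Rh2 with the A/B
#' estimates fixed and the biliary pair `k_43`/`k_40` frozen from the
#' reported biliary excretion fraction ([derive_frozen_biliary()]); (4)
#' sub-model D on PPD after P.O. Rh2 with `k_t`/`k_60` fixed from step 3.
#'
#' @param datasets Named list with elements `A`, `B`, `C`, `D` (long-format
#'   datasets; `C`/`D` may be the same object as `A` when one file holds all
#'   groups).
#' @param biliary_fraction Reported biliary excretion fraction (default 0.276).
#' @param init Named list of per-step initial values (see [fit_submodel()]);
#'   defaults are crude data-independent values.
#' @param sigma,n_starts,n_transit Passed to [fit_submodel()].
#' @return The assembled full `pk_parameters`, with attribute `fits` (the
#'   four `fit_result` objects).
#' @export
staged_calibration <- function(datasets, biliary_fraction = 0.276, init = NULL,
                               sigma = NULL, n_starts = 3, n_transit = 3) {
  step_names <- c(A = "Step 1 (sub-model A)", B = "Step 2 (sub-model B)",
                  C = "Step 3 (sub-model C)", D = "Step 4 (sub-model D)")
  for (tag in names(step_names)) {
    if (is.null(datasets[[tag]])) {
      pk_error(paste0("missing dataset for ", step_names[[tag]]),
               "deglypk_staging_error")
    }
  }
  default_init <- list(
    A = c(V_rh2_plasma = 2, k_e = 2, k_47 = 1, k_74 = 0.5),
    B = c(V_ppd_plasma = 0.5, k_50 = 2, k_58 = 10, k_85 = 2),
    C = c(k_45 = 0.1, k_60 = 1, k_t = 0.5),
    D = c(k_13 = 0.3, k_12 = 0.2, k_20 = 5)
  )
  for (tag in names(default_init)) {
    if (is.null(init[[tag]])) init[[tag]] <- default_init[[tag]]
  }
  run_step <- function(tag, fixed) {
    res <- tryCatch(
      fit_submodel(submodel_spec(tag, n_transit), datasets[[tag]],
                   init = init[[tag]], fixed = fixed,
                   biliary_fraction = biliary_fraction, sigma = sigma,
                   n_starts = n_starts, n_transit = n_transit),
      deglypk_error = function(e) {
        pk_error(paste0(step_names[[tag]], " failed: ", conditionMessage(e)),
                 "deglypk_staging_error")
      })
    res
  }
  fit_a <- run_step("A", NULL)
  fit_b <- run_step("B", NULL)
  k_e <- fit_a$estimates[["k_e"]]
  frozen0 <- derive_frozen_biliary(k_e, biliary_fraction, k_45 = 0)
  fit_c <- run_step("C", c(fit_a$estimates[setdiff(names(fit_a$estimates), "k_e")],
                           k_e = k_e, fit_b$estimates,
                           k_43 = unname(frozen0[["k_43"]])))
  frozen <- derive_frozen_biliary(k_e, biliary_fraction,
                                  k_45 = fit_c$estimates[["k_45"]])
  fit_d <- run_step("D", c(fit_b$estimates,
                           k_t = fit_c$estimates[["k_t"]],
                           k_60 = fit_c$estimates[["k_60"]]))
  assembled <- parameter_set(c(
    fit_a$estimates[c("V_rh2_plasma", "k_47", "k_74")],
    fit_b$estimates,
    k_45 = unname(fit_c$estimates[["k_45"]]),
    k_43 = unname(frozen[["k_43"]]), k_40 = unname(frozen[["k_40"]]),
    k_60 = unname(fit_c$estimates[["k_60"]]),
    k_t = unname(fit_c$estimates[["k_t"]]),
    fit_d$estimates
  ))
  attr(assembled, "fits") <- list(A = fit_a, B = fit_b, C = fit_c, D = fit_d)
  assembled
}
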