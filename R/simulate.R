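#' Concentration-time profile container
#'
#' @param analyte `"RH2"` or `"PPD"`.
#' @param times Strictly increasing sampling times, h.
#' @param conc Concentrations, nmol/L; same length as `times`, non-negative.
#' @param dose Optional `dose_event` reference.
#' @param subject Optional subject label.
#' @return A `concentration_profile` object.
#' @export
concentration_profile <- function(analyte, times, conc, dose = NULL, subject = NULL) {
  analyte <- match.arg(analyte, c("RH2", "PPD"))
  if (length(times) != length(conc)) {
    pk_error("times and concentrations must have equal length", "deglypk_validation_error")
  }
  if (length(times) && any(diff(times) <= 0)) {
    pk_error("times must be strictly increasing", "deglypk_validation_error")
  }
  if (any(conc < 0)) {
    pk_error("concentrations must be non-negative", "deglypk_validation_error")
  }
  structure(list(analyte = analyte, times = as.numeric(times),
                 conc = as.numeric(conc), dose = dose, subject = subject),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("%s concentration profile (%d samples, %g-%g h)\n",
              x$analyte, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(analyte = x$analyte, time_h = x$times, conc_nmol_per_L = x$conc,
             stringsAsFactors = FALSE)
}

# Propagator of the linear system: amounts at `times` after placing
# `amount_nmol` in `compartment` at time `dose_time`. The system is linear
# with constant coefficients, so the solution is a matrix exponential; this
# is exact (no truncation error) and exactly dose-linear. States that cannot
# receive mass from the dose compartment are pruned before exponentiation.
solve_amounts <- function(params, dose, times, n_transit = 3) {
  nm <- compartment_names(n_transit)
  A <- rate_matrix(params, n_transit)
  target <- dose_compartment(dose$route)
  keep <- reachable_states(A, target)
  Ak <- A[keep, keep, drop = FALSE]
  amt <- dose_amount_nmol(dose)

  out <- matrix(0, length(times), length(nm), dimnames = list(NULL, nm))
  active <- times >= dose$time
  if (amt > 0 && any(active)) {
    tt <- times[active] - dose$time
    x <- numeric(length(keep)); names(x) <- keep
    x[target] <- amt
    prev_t <- 0
    res <- matrix(0, length(tt), length(keep))
    for (i in seq_along(tt)) {
      dt <- tt[i] - prev_t
      if (dt > 0) {
        x <- drop(as.matrix(Matrix::expm(Ak * dt)) %*% x)
      }
      res[i, ] <- x
      prev_t <- tt[i]
    }
    out[active, keep] <- res
  }
  # guard against tiny negative round-off
  out[out < 0 & out > -1e-9] <- 0
  total <- rowSums(out)
  if (amt > 0 && any(active)) {
    err <- max(abs(total[active] - amt)) / amt
    if (err > 1e-6) {
      pk_error(sprintf("mass balance violated (relative error %g)", err),
               "deglypk_integration_error")
    }
  }
  out
}

# Breadth-first reachability in the directed graph of nonzero off-diagonal
# rate-matrix entries (A[i, j] != 0 means flow j -> i).
reachable_states <- function(A, start) {
  reach <- start
  repeat {
    new <- rownames(A)[rowSums(abs(A[, reach, drop = FALSE])) > 0]
    new <- setdiff(new, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  rownames(A)[rownames(A) %in% reach]
}

check_route_compat <- function(dose, submodel) {
  if (is.null(submodel)) return(invisible(TRUE))
  stopifnot(inherits(submodel, "submodel_spec"))
  if (!is.na(submodel$route) && dose$route != submodel$route) {
    pk_error(sprintf("dose route %s incompatible with sub-model %s (expects %s)",
                     dose$route, submodel$tag, submodel$route),
             "deglypk_config_error")
  }
  invisible(TRUE)
}

#' Simulate noise-free concentration profiles
#'
#' Integrates the compartmental system for a single dose event and returns the
#' central-compartment concentration of both analytes at the requested times
#' (amount divided by the analyte's central volume of distribution).
#'
#' @param params A `pk_parameters` object (all structural parameters set).
#' @param dose A `dose_event`.
#' @param times Sampling times in hours, within `[0, horizon]`.
#' @param submodel Optional `submodel_spec`; used to check route compatibility.
#' @param n_transit Number of transit compartments.
#' @param horizon Largest admissible sampling time, h (default 48).
#' @return List with elements `rh2` and `ppd`, each a
#'   [concentration_profile()], plus an `amounts` attribute holding the full
#'   state matrix (compartments in columns).
#' @export
simulate_profile <- function(params, dose, times, submodel = NULL,
                             n_transit = 3, horizon = 48) {
  stopifnot(inherits(params, "pk_parameters"), inherits(dose, "dose_event"))
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0) || any(times > horizon)) {
    pk_error(sprintf("times must lie in [0, %g] h", horizon), "deglypk_validation_error")
  }
  check_route_compat(dose, submodel)
  amounts <- solve_amounts(params, dose, times, n_transit)
  out <- list(
    rh2 = concentration_profile("RH2", times,
                                amounts[, "a_pl_rh2"] / param(params, "V_rh2_plasma"),
                                dose = dose),
    ppd = concentration_profile("PPD", times,
                                amounts[, "a_pl_ppd"] / param(params, "V_ppd_plasma"),
                                dose = dose)
  )
  attr(out, "amounts") <- amounts
  out
}

# Apply one subject's log-normal IIV multipliers to a parameter set.
# A multiplier on k_e rescales its three components so that
# k_e = k_40 + k_43 + k_45 keeps holding exactly.
apply_iiv <- function(params, eta) {
  if (is.null(eta) || !length(eta)) return(params)
  values <- params$values
  for (nm in names(eta)) {
    mult <- exp(eta[[nm]])
    if (nm == "k_e" && all(c("k_40", "k_43", "k_45") %in% names(values))) {
      values[c("k_40", "k_43", "k_45")] <- values[c("k_40", "k_43", "k_45")] * mult
      values[["k_e"]] <- values[["k_40"]] + values[["k_43"]] + values[["k_45"]]
    } else {
      values[[nm]] <- values[[nm]] * mult
    }
  }
  parameter_set(values, omega = params$omega, sigma = params$sigma)
}

#' Simulate an individual subject with variability
#'
#' Individual parameters follow the exponential inter-individual variability
#' model `theta_i = theta * exp(eta)`, `eta ~ N(0, omega^2)`, and observations
#' follow the multiplicative residual model `y = f * (1 + eps)`,
#' `eps ~ N(0, sigma^2)`, truncated at zero (concentrations cannot be
#' negative). With `omega` and `sigma` both zero the output equals
#' [simulate_profile()] exactly.
#'
#' @inheritParams simulate_profile
#' @param iiv Optional named vector of log-scale IIV draws (`eta`); when
#'   `NULL`, draws are taken from `params$omega` using `seed`.
#' @param seed Integer seed making the subject reproducible (required when any
#'   randomness is in play). The caller's RNG state is left untouched.
#' @return As [simulate_profile()], with attribute `eta` (the IIV draws used).
#' @export
simulate_individual <- function(params, dose, times, submodel = NULL,
                                iiv = NULL, seed = NULL,
                                n_transit = 3, horizon = 48) {
  stopifnot(inherits(params, "pk_parameters"))
  omega <- params$omega
  sigma <- params$sigma
  needs_rng <- (is.null(iiv) && !is.null(omega) && any(omega > 0)) || sigma > 0
  if (needs_rng && is.null(seed)) {
    pk_error("seed required when omega or sigma is positive", "deglypk_validation_error")
  }
  with_seed(if (needs_rng) seed else NULL, {
    eta <- iiv
    if (is.null(eta)) {
      eta <- if (is.null(omega)) numeric(0) else
        stats::setNames(stats::rnorm(length(omega), 0, omega), names(omega))
    }
    prof <- simulate_profile(apply_iiv(params, eta), dose, times,
                             submodel = submodel, n_transit = n_transit,
                             horizon = horizon)
    if (sigma > 0) {
      for (an in c("rh2", "ppd")) {
        f <- prof[[an]]$conc
        y <- f * (1 + stats::rnorm(length(f), 0, sigma))
        prof[[an]]$conc <- pmax(y, 0)
      }
    }
    attr(prof, "eta") <- eta
    prof
  })
}
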