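# Structural parameter vocabulary. k_e is the total Rh2 elimination rate from
# plasma and must equal k_40 + k_43 + k_45 whenever all four are supplied.
PK_PARAM_NAMES <- c(
  "V_rh2_plasma", "V_ppd_plasma",
  "k_e", "k_40", "k_43", "k_45",
  "k_47", "k_74",
  "k_50", "k_58", "k_85",
  "k_t", "k_60",
  "k_12", "k_13", "k_20"
)

PK_VOLUME_NAMES <- c("V_rh2_plasma", "V_ppd_plasma")

# Parameters that may carry inter-individual variability (log-normal).
PK_IIV_NAMES <- setdiff(PK_PARAM_NAMES, c("k_40", "k_43", "k_45"))

pk_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "deglypk_error", "error")))
}

#' Construct and validate a pharmacokinetic parameter set
#'
#' Bundles the rate constants and central-compartment volumes of the
#' Rh2/PPD deglycosylation model together with optional variability terms.
#' All rates are first-order (1/h); volumes are apparent central volumes of
#' distribution (L/kg body weight).
#'
#' The total Rh2 plasma elimination rate `k_e` is the sum of its three
#' components: transformation to PPD in the systemic circulation (`k_45`),
#' biliary excretion (`k_43`) and unidentified loss (`k_40`). When all four
#' values are supplied they must agree to 1e-9 relative tolerance; when `k_e`
#' is omitted it is derived from the components.
#'
#' @param values Named numeric vector or list of structural parameters. Valid
#'   names: `V_rh2_plasma`, `V_ppd_plasma`, `k_e`, `k_40`, `k_43`, `k_45`,
#'   `k_47`, `k_74`, `k_50`, `k_58`, `k_85`, `k_t`, `k_60`, `k_12`, `k_13`,
#'   `k_20`. Unknown names are rejected.
#' @param omega Named numeric vector of inter-individual variability standard
#'   deviations on the log scale (exponential IIV model), or a single number
#'   applied to `k_e`, `k_50`, `k_t` and both volumes. All values must be
#'   non-negative.
#' @param sigma Non-negative multiplicative (proportional) residual error
#'   standard deviation.
#' @return An object of class `pk_parameters`.
#' @examples
#' p <- parameter_set(c(V_rh2_plasma = 2.39, k_e = 4.67, k_47 = 2.08, k_74 = 0.48))
#' param(p, "k_e")
#' @export
parameter_set <- function(values, omega = NULL, sigma = 0) {
  values <- unlist(values)
  if (length(values) == 0L || is.null(names(values)) || any(names(values) == "")) {
    pk_error("parameter values must be a named numeric vector", "deglypk_validation_error")
  }
  unknown <- setdiff(names(values), PK_PARAM_NAMES)
  if (length(unknown)) {
    pk_error(paste0("unknown parameter name(s): ", paste(unknown, collapse = ", ")),
             "deglypk_validation_error")
  }
  if (anyDuplicated(names(values))) {
    pk_error("duplicated parameter names", "deglypk_validation_error")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    pk_error("all parameter values must be finite numbers", "deglypk_validation_error")
  }
  bad <- names(values)[values < 0]
  if (length(bad)) {
    pk_error(paste0("negative value for parameter(s): ", paste(bad, collapse = ", ")),
             "deglypk_validation_error")
  }
  vols <- intersect(names(values), PK_VOLUME_NAMES)
  bad_vol <- vols[values[vols] <= 0]
  if (length(bad_vol)) {
    pk_error(paste0("volume must be strictly positive: ", paste(bad_vol, collapse = ", ")),
             "deglypk_validation_error")
  }
  comp <- c("k_40", "k_43", "k_45")
  if (all(comp %in% names(values))) {
    total <- sum(values[comp])
    if ("k_e" %in% names(values)) {
      ref <- max(abs(values[["k_e"]]), abs(total), .Machine$double.eps)
      if (abs(values[["k_e"]] - total) > 1e-9 * ref) {
        pk_error(sprintf(
          "k_e (%g) inconsistent with k_40 + k_43 + k_45 (%g)", values[["k_e"]], total),
          "deglypk_consistency_error")
      }
    } else {
      values <- c(values, k_e = total)
    }
  }
  if (!is.null(omega)) {
    if (length(omega) == 1L && is.null(names(omega))) {
      omega <- stats::setNames(rep(omega, 5L),
                               c("k_e", "k_50", "k_t", "V_rh2_plasma", "V_ppd_plasma"))
    }
    unknown_o <- setdiff(names(omega), PK_IIV_NAMES)
    if (length(unknown_o)) {
      pk_error(paste0("omega names must be variability-eligible parameters; got: ",
                      paste(unknown_o, collapse = ", ")), "deglypk_validation_error")
    }
    if (any(omega < 0)) pk_error("omega must be non-negative", "deglypk_validation_error")
  }
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    pk_error("sigma must be a single non-negative number", "deglypk_validation_error")
  }
  structure(
    list(values = values[order(match(names(values), PK_PARAM_NAMES))],
         omega = omega, sigma = sigma),
    class = "pk_parameters"
  )
}

#' Extract a parameter value
#'
#' @param params A `pk_parameters` object.
#' @param name Parameter name.
#' @param default Value returned when the parameter is absent.
#' @return A single number.
#' @export
param <- function(params, name, default = NULL) {
  stopifnot(inherits(params, "pk_parameters"))
  if (name %in% names(params$values)) return(unname(params$values[[name]]))
  if (!is.null(default)) return(default)
  pk_error(paste0("parameter not set: ", name), "deglypk_validation_error")
}

#' Named vector of structural parameter values
#'
#' @param params A `pk_parameters` object.
#' @return Named numeric vector.
#' @export
param_values <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  params$values
}

#' Replace or add parameter values, revalidating
#'
#' When any of `k_40`, `k_43`, `k_45` is updated, `k_e` is re-derived from the
#' components so the consistency invariant always holds.
#'
#' @param params A `pk_parameters` object.
#' @param ... Named replacement values.
#' @return A new `pk_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "pk_parameters"))
  repl <- unlist(list(...))
  values <- params$values
  values[names(repl)] <- repl
  if (any(names(repl) %in% c("k_40", "k_43", "k_45")) &&
      all(c("k_40", "k_43", "k_45") %in% names(values))) {
    values[["k_e"]] <- values[["k_40"]] + values[["k_43"]] + values[["k_45"]]
  }
  parameter_set(values, omega = params$omega, sigma = params$sigma)
}

#' Reference rat parameter estimates for the Rh2/PPD model
#'
#' The bundled reference estimates for the deglycosylation model in the rat:
#' two-compartment disposition for each analyte, shared transit/absorption
#' rate `k_t`, gastric hydrolysis `k_12`, and the frozen biliary split
#' (`k_43`, `k_40`) of the total Rh2 elimination rate `k_e` = 4.67 1/h.
#'
#' The variability defaults (`omega`, `sigma`) are working assumptions for
#' simulation and study generation, not estimated quantities: log-normal
#' inter-individual variability of 0.3 on the clearance-like parameters and
#' both volumes, and a 20% proportional residual error.
#'
#' @param omega,sigma Variability settings passed to [parameter_set()].
#' @return A `pk_parameters` object.
#' @export
reference_parameters <- function(omega = 0.3, sigma = 0.2) {
  parameter_set(
    c(V_rh2_plasma = 2.39, k_e = 4.67, k_47 = 2.08, k_74 = 0.48,
      V_ppd_plasma = 0.29, k_50 = 4.88, k_58 = 27.3, k_85 = 3.38,
      k_45 = 0.09, k_43 = 1.29, k_40 = 3.29,
      k_60 = 1.38, k_t = 0.63,
      k_13 = 0.22, k_12 = 0.14, k_20 = 22.2),
    omega = omega, sigma = sigma
  )
}

#' Read a flat parameter configuration file (YAML or JSON)
#'
#' Keys must be structural parameter names, `sigma`, or `omega_<name>` entries
#' (e.g. `omega_k_e: 0.3`); anything else is rejected.
#'
#' @param path File path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return A `pk_parameters` object.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path)) pk_error(paste0("no such file: ", path), "deglypk_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- unlist(raw)
  is_omega <- grepl("^omega_", names(raw))
  is_sigma <- names(raw) == "sigma"
  omega <- raw[is_omega]
  names(omega) <- sub("^omega_", "", names(omega))
  sigma <- if (any(is_sigma)) unname(raw[is_sigma][1]) else 0
  parameter_set(raw[!is_omega & !is_sigma],
                omega = if (length(omega)) omega else NULL,
                sigma = sigma)
}

#' Write a parameter set to a flat YAML configuration file
#'
#' @param params A `pk_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(params, path) {
  stopifnot(inherits(params, "pk_parameters"))
  out <- as.list(params$values)
  if (!is.null(params$omega)) {
    ow <- as.list(params$omega)
    names(ow) <- paste0("omega_", names(ow))
    out <- c(out, ow)
  }
  if (params$sigma > 0) out$sigma <- params$sigma
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Rh2/PPD deglycosylation model parameters\n")
  v <- x$values
  cat(sprintf("  %-13s %s\n", names(v),
              formatC(v, digits = 4, format = "fg")), sep = "")
  if (!is.null(x$omega)) {
    cat("  IIV (log-sd): ",
        paste(sprintf("%s=%g", names(x$omega), x$omega), collapse = ", "), "\n")
  }
  cat("  proportional residual sd:", x$sigma, "\n")
  invisible(x)
}

# Run an expression with a private, seeded RNG stream, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}
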