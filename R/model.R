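# Compartment layout of the full model (n_transit = 3 by default):
#   stomach Rh2 -> (k_12) stomach PPD -> (k_t) plasma PPD
#                \ (k_13)                \ (k_20) loss
#   stomach Rh2 / plasma Rh2 biliary (k_43) -> transit chain T1..Tn -> colon PPD
#   colon PPD -> (k_t) plasma PPD, (k_60) loss
#   plasma Rh2 <-> peripheral Rh2 (k_47/k_74); k_45 -> plasma PPD; k_40 loss
#   plasma PPD <-> peripheral PPD (k_58/k_85); k_50 loss
# Four cumulative-elimination slots close the mass balance.

MOLAR_MASS_RH2 <- 622.87 # g/mol, literature value; overridable per dose event
MOLAR_MASS_PPD <- 460.73

DOSE_ROUTES <- c("IV_RH2", "PO_RH2", "IV_PPD")

#' Compartment (state) names of the deglycosylation model
#'
#' @param n_transit Number of intestinal transit compartments (default 3).
#' @return Character vector: ten amount slots followed by four
#'   cumulative-elimination slots (all nmol per kg body weight).
#' @export
compartment_names <- function(n_transit = 3) {
  stopifnot(n_transit >= 1)
  c("a_sto_rh2", "a_sto_ppd", paste0("a_T", seq_len(n_transit)),
    "a_col_ppd", "a_pl_rh2", "a_pc_rh2", "a_pl_ppd", "a_pc_ppd",
    "cum_elim_rh2_unknown", "cum_elim_ppd_central",
    "cum_elim_ppd_stomach", "cum_elim_ppd_colon")
}

#' Rate matrix of the linear deglycosylation system
#'
#' Builds the constant-coefficient matrix A such that d(state)/dt = A state.
#' Column sums are zero: every outflow lands in another compartment or in a
#' cumulative-elimination slot, so total mass is conserved.
#'
#' @param params A `pk_parameters` object containing every structural
#'   parameter referenced by the full model.
#' @param n_transit Number of transit compartments.
#' @return Square numeric matrix with dimnames from [compartment_names()].
#' @export
rate_matrix <- function(params, n_transit = 3) {
  nm <- compartment_names(n_transit)
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  p <- function(x) param(params, x)
  tr <- paste0("a_T", seq_len(n_transit))

  A["a_sto_rh2", "a_sto_rh2"] <- -(p("k_12") + p("k_13"))
  A["a_sto_ppd", "a_sto_rh2"] <- p("k_12")
  A[tr[1], "a_sto_rh2"] <- p("k_13")

  A["a_sto_ppd", "a_sto_ppd"] <- -(p("k_t") + p("k_20"))
  A["a_pl_ppd", "a_sto_ppd"] <- p("k_t")
  A["cum_elim_ppd_stomach", "a_sto_ppd"] <- p("k_20")

  # biliary output of Rh2 feeds the head of the transit chain
  A[tr[1], "a_pl_rh2"] <- p("k_43")
  for (i in seq_len(n_transit)) {
    A[tr[i], tr[i]] <- -p("k_t")
    if (i < n_transit) A[tr[i + 1], tr[i]] <- p("k_t")
  }
  A["a_col_ppd", tr[n_transit]] <- p("k_t")

  A["a_col_ppd", "a_col_ppd"] <- -(p("k_t") + p("k_60"))
  A["a_pl_ppd", "a_col_ppd"] <- p("k_t")
  A["cum_elim_ppd_colon", "a_col_ppd"] <- p("k_60")

  A["a_pl_rh2", "a_pl_rh2"] <- -(p("k_40") + p("k_43") + p("k_45") + p("k_47"))
  A["a_pc_rh2", "a_pl_rh2"] <- p("k_47")
  A["a_pl_rh2", "a_pc_rh2"] <- p("k_74")
  A["a_pc_rh2", "a_pc_rh2"] <- -p("k_74")
  A["a_pl_ppd", "a_pl_rh2"] <- p("k_45")
  A["cum_elim_rh2_unknown", "a_pl_rh2"] <- p("k_40")

  A["a_pl_ppd", "a_pl_ppd"] <- -(p("k_50") + p("k_58"))
  A["a_pc_ppd", "a_pl_ppd"] <- p("k_58")
  A["a_pl_ppd", "a_pc_ppd"] <- p("k_85")
  A["a_pc_ppd", "a_pc_ppd"] <- -p("k_85")
  A["cum_elim_ppd_central", "a_pl_ppd"] <- p("k_50")

  A
}

#' Time derivative of the model state
#'
#' Pure right-hand side of the compartmental ODE system. Because every loss
#' term accrues into a cumulative-elimination slot, the derivatives sum to
#' zero for any state (closed mass balance).
#'
#' @param state Named numeric vector over [compartment_names()] slots.
#' @param params A `pk_parameters` object.
#' @return Named numeric vector of derivatives, same layout as `state`.
#' @export
model_rhs <- function(state, params) {
  n_transit <- sum(grepl("^a_T", names(state)))
  nm <- compartment_names(n_transit)
  if (!identical(sort(names(state)), sort(nm))) {
    pk_error("state names do not match the model compartments", "deglypk_validation_error")
  }
  drop(rate_matrix(params, n_transit)[names(state), names(state)] %*% state)
}

#' Define a dose event
#'
#' @param route One of `"IV_RH2"` (bolus into Rh2 plasma), `"PO_RH2"` (into
#'   the stomach Rh2 compartment) or `"IV_PPD"` (bolus into PPD plasma).
#' @param dose Dose in mg/kg body weight.
#' @param time Dosing time in hours (default 0).
#' @param molar_mass Molar mass of the dosed analyte in g/mol; defaults to
#'   622.87 (Rh2) or 460.73 (PPD).
#' @return A `dose_event` object.
#' @export
dose_event <- function(route, dose, time = 0, molar_mass = NULL) {
  route <- match.arg(route, DOSE_ROUTES)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    pk_error("dose must be a single non-negative number (mg/kg)", "deglypk_validation_error")
  }
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0) {
    pk_error("dose time must be a single non-negative number (h)", "deglypk_validation_error")
  }
  if (is.null(molar_mass)) {
    molar_mass <- if (route == "IV_PPD") MOLAR_MASS_PPD else MOLAR_MASS_RH2
  }
  stopifnot(molar_mass > 0)
  structure(list(route = route, dose = dose, time = time, molar_mass = molar_mass),
            class = "dose_event")
}

#' Dose amount in nmol per kg body weight
#'
#' Converts mg/kg to nmol/kg: `dose * 1e6 / molar_mass`.
#'
#' @param dose A `dose_event`.
#' @return Amount in nmol/kg.
#' @export
dose_amount_nmol <- function(dose) {
  stopifnot(inherits(dose, "dose_event"))
  dose$dose * 1e6 / dose$molar_mass
}

# Compartment a dose enters.
dose_compartment <- function(route) {
  switch(route, IV_RH2 = "a_pl_rh2", PO_RH2 = "a_sto_rh2", IV_PPD = "a_pl_ppd")
}

#' Sub-model specifications of the staged estimation strategy
#'
#' The full model is reduced to four sub-models fitted in sequence:
#' \describe{
#'   \item{A}{Rh2 disposition (plasma + peripheral) after I.V. Rh2; estimates
#'     `V_rh2_plasma`, `k_e`, `k_47`, `k_74`.}
#'   \item{B}{PPD disposition after I.V. PPD; estimates `V_ppd_plasma`,
#'     `k_50`, `k_58`, `k_85`.}
#'   \item{C}{A + B + biliary excretion, transit chain, colonic transformation
#'     and PPD absorption, fitted to PPD after I.V. Rh2; estimates `k_45`,
#'     `k_60`, `k_t` with `k_43`/`k_40` frozen from the biliary-excretion
#'     fraction (see [derive_frozen_biliary()]).}
#'   \item{D}{B + stomach, transit and colon, fitted to PPD after P.O. Rh2;
#'     estimates `k_13`, `k_12`, `k_20` with `k_t`, `k_60` fixed from C.}
#' }
#'
#' @param tag One of `"A"`, `"B"`, `"C"`, `"D"`, `"FULL"`.
#' @param n_transit Number of transit compartments.
#' @return A `submodel_spec` with elements `tag`, `active_compartments`,
#'   `estimated`, `fixed`, `route` (dose route of the matching dataset) and
#'   `analyte` (observed analyte).
#' @export
submodel_spec <- function(tag, n_transit = 3) {
  if (length(tag) != 1L || !tag %in% c("A", "B", "C", "D", "FULL")) {
    pk_error("unknown sub-model tag (use A, B, C, D or FULL)", "deglypk_validation_error")
  }
  tr <- paste0("a_T", seq_len(n_transit))
  cpt_a <- c("a_pl_rh2", "a_pc_rh2")
  cpt_b <- c("a_pl_ppd", "a_pc_ppd")
  gut <- c(tr, "a_col_ppd")
  sto <- c("a_sto_rh2", "a_sto_ppd")
  est_a <- c("V_rh2_plasma", "k_e", "k_47", "k_74")
  est_b <- c("V_ppd_plasma", "k_50", "k_58", "k_85")
  spec <- switch(tag,
    A = list(active = cpt_a, estimated = est_a, fixed = character(0),
             route = "IV_RH2", analyte = "RH2"),
    B = list(active = cpt_b, estimated = est_b, fixed = character(0),
             route = "IV_PPD", analyte = "PPD"),
    C = list(active = c(cpt_a, cpt_b, gut),
             estimated = c("k_45", "k_60", "k_t"),
             fixed = c(est_a, est_b, "k_43", "k_40"),
             route = "IV_RH2", analyte = "PPD"),
    D = list(active = c(sto, gut, cpt_b),
             estimated = c("k_13", "k_12", "k_20"),
             fixed = c(est_b, "k_t", "k_60"),
             route = "PO_RH2", analyte = "PPD"),
    FULL = list(active = c(sto, gut, cpt_a, cpt_b),
                estimated = c(est_a, est_b, "k_45", "k_60", "k_t",
                              "k_13", "k_12", "k_20"),
                fixed = c("k_43", "k_40"),
                route = NA_character_, analyte = NA_character_)
  )
  structure(list(tag = tag, active_compartments = spec$active,
                 estimated = spec$estimated, fixed = spec$fixed,
                 route = spec$route, analyte = spec$analyte,
                 n_transit = n_transit),
            class = "submodel_spec")
}

#' @export
print.submodel_spec <- function(x, ...) {
  cat("Sub-model", x$tag, "\n")
  cat("  active compartments:", paste(x$active_compartments, collapse = ", "), "\n")
  cat("  estimated:", paste(x$estimated, collapse = ", "), "\n")
  if (length(x$fixed)) cat("  fixed/frozen:", paste(x$fixed, collapse = ", "), "\n")
  if (!is.na(x$route)) cat("  data contract:", x$analyte, "after", x$route, "\n")
  invisible(x)
}
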