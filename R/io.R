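# Long-format dataset plumbing. One CSV dialect (RFC 4180, UTF-8, "." decimal);
# one record per (subject, analyte, time).

DATASET_COLUMNS <- c("subject_id", "group", "route", "analyte",
                     "dose_mg_per_kg", "time_h", "conc_nmol_per_L", "blq")
DATASET_OPTIONAL <- "conc_true_nmol_per_L"
DATASET_ANALYTES <- c("RH2", "PPD")

#' Validate a long-format concentration dataset
#'
#' Checks the schema (column set, enumerations, uniqueness of the
#' (subject, analyte, time) key, non-negative times and concentrations) and
#' returns the data frame with canonical column order.
#'
#' @param dataset A data frame.
#' @return The validated data frame.
#' @export
validate_dataset <- function(dataset) {
  if (!is.data.frame(dataset)) {
    pk_error("dataset must be a data frame", "deglypk_schema_error")
  }
  missing_cols <- setdiff(DATASET_COLUMNS, names(dataset))
  if (length(missing_cols)) {
    pk_error(paste0("dataset is missing column(s): ",
                    paste(missing_cols, collapse = ", ")), "deglypk_schema_error")
  }
  extra <- setdiff(names(dataset), c(DATASET_COLUMNS, DATASET_OPTIONAL))
  if (length(extra)) {
    pk_error(paste0("unexpected dataset column(s): ", paste(extra, collapse = ", ")),
             "deglypk_schema_error")
  }
  if (!all(dataset$route %in% DOSE_ROUTES)) {
    pk_error("route must be one of IV_RH2, PO_RH2, IV_PPD", "deglypk_schema_error")
  }
  if (!all(dataset$analyte %in% DATASET_ANALYTES)) {
    pk_error("analyte must be RH2 or PPD", "deglypk_schema_error")
  }
  if (any(dataset$time_h < 0)) {
    pk_error("negative time_h in dataset", "deglypk_validation_error")
  }
  if (any(!dataset$blq & dataset$conc_nmol_per_L < 0)) {
    pk_error("negative concentration in non-BLQ record", "deglypk_validation_error")
  }
  key <- paste(dataset$subject_id, dataset$analyte, dataset$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    pk_error("duplicate (subject_id, analyte, time_h) key", "deglypk_integrity_error")
  }
  dataset[, c(DATASET_COLUMNS, intersect(DATASET_OPTIONAL, names(dataset)))]
}

#' Read a concentration dataset from CSV
#'
#' The header must carry exactly the schema columns `subject_id`, `group`,
#' `route`, `analyte`, `dose_mg_per_kg`, `time_h`, `conc_nmol_per_L`, `blq`
#' (optionally `conc_true_nmol_per_L`, the noise-free shadow value written by
#' the synthetic-study generator). `blq` accepts TRUE/FALSE; an empty
#' concentration with `blq = TRUE` is read as 0.
#'
#' @param path CSV file path.
#' @return Validated data frame, row order preserved.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) pk_error(paste0("no such file: ", path), "deglypk_io_error")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("blq" %in% names(d)) d$blq <- as.logical(d$blq)
  if ("conc_nmol_per_L" %in% names(d) && "blq" %in% names(d)) {
    blank <- is.na(d$conc_nmol_per_L) & d$blq
    d$conc_nmol_per_L[blank] <- 0
  }
  validate_dataset(d)
}

#' Write a concentration dataset to CSV
#'
#' Canonical form: unquoted fields, no row names, logical `blq` as TRUE/FALSE.
#' `write_dataset(read_dataset(p), p2)` reproduces a canonical file
#' byte-for-byte.
#'
#' @param dataset Data frame passing [validate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dataset <- validate_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Subset a dataset to one sub-model's (route, analyte) contract, dropping BLQ.
submodel_observations <- function(dataset, submodel) {
  dataset <- validate_dataset(dataset)
  d <- dataset[dataset$route == submodel$route &
                 dataset$analyte == submodel$analyte & !dataset$blq, , drop = FALSE]
  if (!nrow(d)) {
    pk_error(sprintf("no quantifiable %s observations after %s for sub-model %s",
                     submodel$analyte, submodel$route, submodel$tag),
             "deglypk_data_error")
  }
  d
}
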