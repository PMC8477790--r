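MSI_LEVELS <- c("MSI", "MSI-L", "MSS", "Unknown")
RESPONSE_LEVELS <- c("responder", "nonresponder", "unknown")

#' Validate a sample-annotation tibble
#'
#' Annotations carry, per sample: microsatellite status (`MSI`, `MSI-L`,
#' `MSS`, `Unknown`), optional survival time in days with an event indicator,
#' an optional response label and a cohort tag. Survival time and event must
#' be present or absent together.
#'
#' @param ann A data frame with at least `sample_id` and `msi_status`.
#' @return The annotations as a tibble with canonical column types.
#' @export
validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  req <- c("sample_id", "msi_status")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table lacks required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated sample id(s) in annotations: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad_msi <- setdiff(unique(as.character(ann$msi_status)), MSI_LEVELS)
  if (length(bad_msi) > 0) {
    abort(sprintf(
      "unknown msi_status token(s) %s; accepted tokens: %s",
      paste(sQuote(bad_msi), collapse = ", "), paste(MSI_LEVELS, collapse = ", ")
    ))
  }
  if (!"surv_time" %in% names(ann)) ann$surv_time <- NA_real_
  if (!"surv_event" %in% names(ann)) ann$surv_event <- NA
  ann$surv_time <- as.numeric(ann$surv_time)
  ann$surv_event <- as.logical(ann$surv_event)
  mismatch <- xor(is.na(ann$surv_time), is.na(ann$surv_event))
  if (any(mismatch)) {
    abort(paste0(
      "surv_time and surv_event must be present together; offending sample(s): ",
      paste(head(ann$sample_id[mismatch], 5), collapse = ", ")
    ))
  }
  if (any(ann$surv_time < 0, na.rm = TRUE)) abort("surv_time must be nonnegative")
  if (!"response" %in% names(ann)) ann$response <- "unknown"
  ann$response[is.na(ann$response)] <- "unknown"
  bad_resp <- setdiff(unique(as.character(ann$response)), RESPONSE_LEVELS)
  if (length(bad_resp) > 0) {
    abort(sprintf(
      "unknown response token(s) %s; accepted tokens: %s",
      paste(sQuote(bad_resp), collapse = ", "), paste(RESPONSE_LEVELS, collapse = ", ")
    ))
  }
  if (!"cohort" %in% names(ann)) ann$cohort <- NA_character_
  dplyr::select(
    ann, "sample_id", "msi_status", "surv_time", "surv_event", "response", "cohort",
    dplyr::everything()
  )
}

#' Read sample annotations from TSV
#'
#' @param path TSV with columns `sample_id`, `msi_status` and optionally
#'   `surv_time`, `surv_event`, `response`, `cohort`. Empty cells and the
#'   literal `NA` mark absent optional values.
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_annotations(df)
}

#' Write sample annotations to TSV
#'
#' @param ann A validated annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
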