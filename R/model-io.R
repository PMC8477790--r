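MODEL_SCHEMA_VERSION <- "1.0"

#' Save a fitted model to JSON
#'
#' The serialization is plain JSON with an explicit `schema_version` field so
#' saved models are human-inspectable and diffable. Numeric fields are
#' written at full double precision; reloading reproduces scores exactly to
#' numeric-text precision.
#'
#' @param model A validated [tmepre_model()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "tmepre_model")) abort("model must be a tmepre_model")
  ser_sig <- function(sig) {
    list(
      genes = sig$genes,
      mu = unname(sig$mu), sigma = unname(sig$sigma),
      centroid_pos = unname(sig$centroid_pos), centroid_neg = unname(sig$centroid_neg),
      cutoff = sig$cutoff, positive_label = sig$positive_label
    )
  }
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    tme1 = ser_sig(model$tme1),
    tme2 = ser_sig(model$tme2),
    marker_cd8a = model$marker_cd8a,
    marker_pd1 = model$marker_pd1,
    marker_tim3 = model$marker_tim3,
    infiltration_percentile = model$infiltration_percentile,
    validation_low_quantile = model$validation_low_quantile,
    validation_high_quantile = model$validation_high_quantile,
    cd8_restricted_genes = model$cd8_restricted_genes
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path Path to a JSON file written by [save_model()].
#' @return A validated [tmepre_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("cannot parse model file ", path, ": ", conditionMessage(e)))
  )
  ver <- payload$schema_version
  if (is.null(ver) || !identical(as.character(ver), MODEL_SCHEMA_VERSION)) {
    abort(sprintf(
      "model schema version mismatch: file has %s, this package reads %s",
      ver %||% "<none>", MODEL_SCHEMA_VERSION
    ))
  }
  de_sig <- function(s) {
    centroid_signature(
      genes = s$genes, mu = s$mu, sigma = s$sigma,
      centroid_pos = s$centroid_pos, centroid_neg = s$centroid_neg,
      cutoff = s$cutoff, positive_label = s$positive_label
    )
  }
  tmepre_model(
    tme1 = de_sig(payload$tme1), tme2 = de_sig(payload$tme2),
    marker_cd8a = payload$marker_cd8a,
    marker_pd1 = payload$marker_pd1,
    marker_tim3 = payload$marker_tim3,
    infiltration_percentile = payload$infiltration_percentile,
    validation_low_quantile = payload$validation_low_quantile,
    validation_high_quantile = payload$validation_high_quantile,
    cd8_restricted_genes = payload$cd8_restricted_genes
  )
}
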