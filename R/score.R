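#' Score samples with both model components
#'
#' @param model A [tmepre_model()].
#' @param expr Expression matrix containing every signature gene.
#' @return A tibble with `sample_id`, `tme1_score`, `tme2_score`.
#' @export
score_samples <- function(model, expr) {
  validate_expression_matrix(expr)
  s1 <- score_signature(model$tme1, expr)
  s2 <- score_signature(model$tme2, expr)
  if (!all(is.finite(s1)) || !all(is.finite(s2))) abort("non-finite score computed")
  tibble(sample_id = colnames(expr), tme1_score = unname(s1), tme2_score = unname(s2))
}

new_predictions <- function(tbl) {
  structure(tbl, class = c("tmepre_predictions", class(tibble())))
}

#' Classify a training-platform cohort with the fitted cutoffs
#'
#' A sample is a predicted responder iff both component scores reach the
#' fitted cutoffs: sufficient CD8+ T-cell infiltration and no terminal
#' exhaustion pattern. Nonresponders carry a mechanism label: insufficient
#' infiltration when the infiltration score is below its cutoff, terminal
#' exhaustion when infiltration suffices but the response score falls short.
#'
#' @param model A [tmepre_model()].
#' @param scores Tibble from [score_samples()].
#' @param annotations Annotation tibble for the scored samples.
#' @return A list with `predictions` (tibble of sample_id, scores,
#'   predicted, mechanism) and `summary` (a [summarize_cohort()] tibble).
#' @export
classify_training_cohort <- function(model, scores, annotations) {
  ann <- validate_annotations(annotations)
  missing_s <- setdiff(ann$sample_id, scores$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("scores missing for sample(s): ", paste(head(missing_s, 5), collapse = ", ")))
  }
  pred <- scores |>
    dplyr::mutate(
      predicted = ifelse(
        .data$tme1_score >= model$tme1$cutoff & .data$tme2_score >= model$tme2$cutoff,
        "responder", "nonresponder"
      ),
      mechanism = dplyr::case_when(
        .data$tme1_score < model$tme1$cutoff ~ "insufficient_infiltration",
        .data$tme2_score < model$tme2$cutoff ~ "terminal_exhaustion",
        TRUE ~ "none"
      )
    )
  pred <- new_predictions(pred)
  list(predictions = pred, summary = summarize_cohort(pred, ann))
}

#' Classify a validation cohort with the within-cohort quartile rule
#'
#' Validation cohorts come from other platforms, so the fitted cutoffs do
#' not transfer; within-cohort quantiles are used instead. A sample is a
#' predicted nonresponder iff its infiltration score lies in the lowest
#' quartile, or lies in the highest quartile while its response score falls
#' below the cohort median. All other samples are predicted responders.
#' Quantiles use the same order-statistic convention as
#' [percentile_cutoff()] ("above" is strictly greater), so the rule depends
#' only on score ranks.
#'
#' @param model A [tmepre_model()] (supplies the quartile bounds).
#' @param scores Tibble from [score_samples()]; at least 4 samples.
#' @return A predictions tibble with `predicted` and `mechanism`.
#' @export
classify_validation_cohort <- function(model, scores) {
  if (nrow(scores) < 4) abort("validation cohort needs at least 4 samples")
  q_low <- percentile_cutoff(scores$tme1_score, model$validation_low_quantile)
  q_high <- percentile_cutoff(scores$tme1_score, model$validation_high_quantile)
  med2 <- percentile_cutoff(scores$tme2_score, 0.5)
  pred <- scores |>
    dplyr::mutate(
      low_inf = .data$tme1_score <= q_low,
      high_inf = .data$tme1_score > q_high,
      predicted = ifelse(
        .data$low_inf | (.data$high_inf & .data$tme2_score < med2),
        "nonresponder", "responder"
      ),
      mechanism = dplyr::case_when(
        .data$low_inf ~ "insufficient_infiltration",
        .data$high_inf & .data$tme2_score < med2 ~ "terminal_exhaustion",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(-"low_inf", -"high_inf")
  new_predictions(pred)
}

#' Read the exhaustion component out on purified CD8+ T cells
#'
#' Restricts the TME2 signature to the genes primarily expressed by CD8+
#' T cells (defaults to the model's configured nine-gene subset) and
#' recomputes the nearest-centroid score on that restriction: centroids and
#' standardization are subset to the restricted genes. Higher scores mean
#' progenitor-exhausted-like, i.e. still anti-PD1-responsive.
#'
#' @param model A [tmepre_model()].
#' @param expr Expression matrix of purified-cell profiles.
#' @param genes Gene subset; must intersect the TME2 signature. Genes not in
#'   the signature are dropped with a warning.
#' @return A tibble with `sample_id` and `score`.
#' @export
cd8_restricted_readout <- function(model, expr, genes = NULL) {
  validate_expression_matrix(expr)
  genes <- genes %||% model$cd8_restricted_genes
  keep <- intersect(genes, model$tme2$genes)
  if (length(keep) == 0) {
    abort("requested gene subset has empty intersection with the TME2 signature")
  }
  dropped <- setdiff(genes, keep)
  if (length(dropped) > 0) {
    warn(paste0(
      "subset gene(s) not in the TME2 signature, dropped: ",
      paste(dropped, collapse = ", ")
    ))
  }
  sig <- model$tme2
  restricted <- centroid_signature(
    genes = keep,
    mu = sig$mu[keep], sigma = sig$sigma[keep],
    centroid_pos = sig$centroid_pos[keep], centroid_neg = sig$centroid_neg[keep],
    cutoff = NA_real_, positive_label = sig$positive_label
  )
  tibble(sample_id = colnames(expr), score = unname(score_signature(restricted, expr)))
}

#' Relative range coverage of a score subset
#'
#' The ratio of the score range within a subgroup (e.g. MSS tumors) to the
#' range over the whole cohort. A value near 1 means the subgroup uses the
#' score's full dynamic range.
#'
#' @param scores_subset Scores of the subgroup (a subset of `scores_all`).
#' @param scores_all Scores of the full cohort (at least 2 distinct values).
#' @return A single number in [0, 1] when the subset is contained in the
#'   full set.
#' @export
omega_range_coverage <- function(scores_subset, scores_all) {
  if (length(scores_subset) == 0 || length(scores_all) < 2) {
    abort("need a nonempty subset and at least 2 cohort scores")
  }
  denom <- max(scores_all) - min(scores_all)
  if (denom == 0) abort("zero score range in the full cohort")
  (max(scores_subset) - min(scores_subset)) / denom
}
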