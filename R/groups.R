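#' Empirical percentile cutoff
#'
#' Returns the k-th smallest value with k = ceiling(p * n). "Above the
#' cutoff" always means strictly greater downstream. Under this convention
#' the 40th percentile of 131 distinct marker values leaves exactly 78
#' samples strictly above — the group size the training contrast uses.
#'
#' @param values Nonempty finite numeric vector.
#' @param p Percentile in (0, 1).
#' @return The cutoff value (a single number).
#' @export
percentile_cutoff <- function(values, p) {
  if (length(values) == 0) abort("percentile_cutoff: empty value vector")
  if (!all(is.finite(values))) abort("percentile_cutoff: values must be finite")
  if (!(p > 0 && p < 1)) abort("percentile_cutoff: p must lie in (0, 1)")
  k <- ceiling(p * length(values))
  sort(values)[k]
}

group_labels <- function(sample_ids, label) {
  tibble(sample_id = sample_ids, label = label)
}

#' Define the infiltration training contrast
#'
#' The CD8A cutoff is the `infiltration_percentile` (default 40th) empirical
#' percentile of CD8A expression among MSI tumors only. MSI tumors strictly
#' above the cutoff form the high-infiltration positive group; MSS tumors
#' strictly below form the negative group. Everything else — MSI at or below
#' the cutoff, MSS at or above, MSI-L and Unknown samples — is excluded.
#'
#' @param expr Expression matrix containing the marker gene.
#' @param annotations Annotation tibble for the same samples.
#' @param marker CD8A-like marker gene id.
#' @param percentile Percentile in (0, 1); default 0.40.
#' @return A list with `groups` (tibble of sample_id, label in
#'   POS/NEG/EXCLUDED) and the numeric `cutoff`.
#' @export
define_infiltration_groups <- function(expr, annotations, marker = "CD8A",
                                       percentile = 0.40) {
  validate_expression_matrix(expr)
  ann <- validate_annotations(annotations)
  if (!marker %in% rownames(expr)) {
    abort(sprintf("marker gene '%s' absent from expression matrix", marker))
  }
  missing_ann <- setdiff(ann$sample_id, colnames(expr))
  if (length(missing_ann) > 0) {
    abort(paste0("annotated samples absent from matrix: ", paste(head(missing_ann, 5), collapse = ", ")))
  }
  marker_expr <- expr[marker, ann$sample_id]
  msi <- ann$msi_status == "MSI"
  if (!any(msi)) abort("no MSI samples; the infiltration cutoff is defined on MSI tumors")
  cutoff <- percentile_cutoff(marker_expr[msi], percentile)
  label <- dplyr::case_when(
    msi & marker_expr > cutoff ~ "POS",
    ann$msi_status == "MSS" & marker_expr < cutoff ~ "NEG",
    TRUE ~ "EXCLUDED"
  )
  if (!any(label == "POS")) abort("empty POS group: no MSI sample above the infiltration cutoff")
  if (!any(label == "NEG")) abort("empty NEG group: no MSS sample below the infiltration cutoff")
  list(groups = group_labels(ann$sample_id, label), cutoff = cutoff)
}

#' Define the exhaustion training contrast
#'
#' Within the high-infiltration MSI samples, the medians of the PD1 (PDCD1)
#' and TIM3 (HAVCR2) markers are the cutoffs. Samples with both markers
#' strictly above their medians show the co-expression pattern of multiple
#' early inhibitory receptors — terminally exhausted, the contrast NEG class.
#' Samples with both strictly below are the still-responsive POS class, so a
#' higher score on the fitted signature means an anti-PD1-responsive
#' microenvironment. Mixed samples (or ties at a median) are excluded.
#'
#' @param expr Expression matrix.
#' @param infiltration_pos Character vector of high-infiltration sample ids.
#' @param marker_pd1,marker_tim3 Marker gene ids.
#' @return A list with `groups` (over `infiltration_pos`) and the two
#'   median cutoffs (`cutoff_pd1`, `cutoff_tim3`).
#' @export
define_exhaustion_groups <- function(expr, infiltration_pos,
                                     marker_pd1 = "PDCD1", marker_tim3 = "HAVCR2") {
  validate_expression_matrix(expr)
  if (length(infiltration_pos) == 0) abort("infiltration POS set is empty")
  for (m in c(marker_pd1, marker_tim3)) {
    if (!m %in% rownames(expr)) abort(sprintf("marker gene '%s' absent from expression matrix", m))
  }
  missing_s <- setdiff(infiltration_pos, colnames(expr))
  if (length(missing_s) > 0) {
    abort(paste0("samples absent from matrix: ", paste(head(missing_s, 5), collapse = ", ")))
  }
  pd1 <- expr[marker_pd1, infiltration_pos]
  tim3 <- expr[marker_tim3, infiltration_pos]
  cut_pd1 <- median(pd1)
  cut_tim3 <- median(tim3)
  label <- dplyr::case_when(
    pd1 < cut_pd1 & tim3 < cut_tim3 ~ "POS",
    pd1 > cut_pd1 & tim3 > cut_tim3 ~ "NEG",
    TRUE ~ "EXCLUDED"
  )
  if (!any(label == "POS")) abort("empty POS (responsive) exhaustion group")
  if (!any(label == "NEG")) abort("empty NEG (terminally exhausted) exhaustion group")
  list(
    groups = group_labels(infiltration_pos, label),
    cutoff_pd1 = cut_pd1, cutoff_tim3 = cut_tim3
  )
}
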