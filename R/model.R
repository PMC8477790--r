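#' Construct a centroid signature
#'
#' A centroid signature is a fitted nearest-centroid scorer: an ordered gene
#' list, per-gene standardization parameters estimated on the pooled training
#' groups, the two standardized class centroids, and a score cutoff. The
#' continuous score of a sample is
#' \deqn{(\lVert z - c_{neg}\rVert - \lVert z - c_{pos}\rVert) / m}
#' over the m signature genes, where z is the standardized expression vector;
#' higher scores mean closer to the positive class.
#'
#' @param genes Character vector of signature gene ids (nonempty, unique).
#' @param mu,sigma Per-gene standardization mean and (strictly positive) SD.
#' @param centroid_pos,centroid_neg Standardized class-mean vectors.
#' @param cutoff Score threshold; `score >= cutoff` classifies positive.
#' @param positive_label Human-readable meaning of the positive class.
#' @return An object of class `centroid_signature`.
#' @export
centroid_signature <- function(genes, mu, sigma, centroid_pos, centroid_neg,
                               cutoff = NA_real_, positive_label = "POS") {
  genes <- as.character(genes)
  if (length(genes) == 0) abort("a centroid signature needs at least one gene")
  if (anyDuplicated(genes)) abort("duplicated genes in signature")
  lens <- c(length(mu), length(sigma), length(centroid_pos), length(centroid_neg))
  if (any(lens != length(genes))) {
    abort("mu, sigma and centroids must have one entry per signature gene")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("sigma must be strictly positive for every signature gene")
  }
  structure(
    list(
      genes = genes,
      mu = stats::setNames(as.numeric(mu), genes),
      sigma = stats::setNames(as.numeric(sigma), genes),
      centroid_pos = stats::setNames(as.numeric(centroid_pos), genes),
      centroid_neg = stats::setNames(as.numeric(centroid_neg), genes),
      cutoff = as.numeric(cutoff),
      positive_label = positive_label
    ),
    class = "centroid_signature"
  )
}

#' @export
print.centroid_signature <- function(x, ...) {
  cat(sprintf(
    "<centroid_signature> %d genes, positive class = %s, cutoff = %s\n",
    length(x$genes), x$positive_label,
    if (is.na(x$cutoff)) "unset" else format(x$cutoff, digits = 4)
  ))
  cat("  genes:", paste(head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) "..." else "", "\n")
  invisible(x)
}

#' Default CD8-expressed subset of the exhaustion signature
#'
#' Nine genes used to read the exhaustion component out on purified CD8+
#' T-cell expression data: seven genes highly expressed by CD8+ T cells in
#' human hematopoiesis reference data plus the two inhibitory-receptor
#' markers that define terminal exhaustion.
#'
#' @return A character vector of nine gene symbols.
#' @export
default_cd8_genes <- function() {
  c("CCL5", "CD2", "CD48", "CD84", "FAM78A", "HCST", "IL21R", "HAVCR2", "PDCD1")
}

#' Assemble a two-component TMEPRE model
#'
#' Bundles the infiltration signature (TME1, scoring how permissive the tumor
#' microenvironment is to CD8+ T-cell infiltration) and the exhaustion
#' signature (TME2, scoring whether infiltrating CD8+ T cells can still
#' respond to checkpoint blockade) with the marker genes and decision-rule
#' quantiles.
#'
#' @param tme1,tme2 Fitted [centroid_signature()] objects.
#' @param marker_cd8a,marker_pd1,marker_tim3 Marker gene symbols.
#' @param infiltration_percentile Percentile of the CD8A marker among MSI
#'   tumors that splits high from low infiltration (default 0.40).
#' @param validation_low_quantile,validation_high_quantile TME1 quantiles
#'   bounding the extreme quartiles in the validation decision rule.
#' @param cd8_restricted_genes Gene subset for the purified-cell read-out.
#' @return An object of class `tmepre_model`.
#' @export
tmepre_model <- function(tme1, tme2,
                         marker_cd8a = "CD8A", marker_pd1 = "PDCD1", marker_tim3 = "HAVCR2",
                         infiltration_percentile = 0.40,
                         validation_low_quantile = 0.25,
                         validation_high_quantile = 0.75,
                         cd8_restricted_genes = default_cd8_genes()) {
  if (!inherits(tme1, "centroid_signature") || !inherits(tme2, "centroid_signature")) {
    abort("tme1 and tme2 must be centroid_signature objects")
  }
  if (!(validation_low_quantile > 0 && validation_low_quantile < validation_high_quantile &&
    validation_high_quantile < 1)) {
    abort("need 0 < validation_low_quantile < validation_high_quantile < 1")
  }
  if (!(infiltration_percentile > 0 && infiltration_percentile < 1)) {
    abort("infiltration_percentile must lie in (0, 1)")
  }
  if (marker_cd8a %in% tme1$genes) {
    abort(sprintf("marker gene %s must not appear in the infiltration signature", marker_cd8a))
  }
  structure(
    list(
      tme1 = tme1, tme2 = tme2,
      marker_cd8a = marker_cd8a, marker_pd1 = marker_pd1, marker_tim3 = marker_tim3,
      infiltration_percentile = infiltration_percentile,
      validation_low_quantile = validation_low_quantile,
      validation_high_quantile = validation_high_quantile,
      cd8_restricted_genes = as.character(cd8_restricted_genes)
    ),
    class = "tmepre_model"
  )
}

#' @export
print.tmepre_model <- function(x, ...) {
  cat("<tmepre_model>\n")
  cat(sprintf(
    "  TME1 infiltration: %d genes, cutoff %s (marker %s, percentile %.2f)\n",
    length(x$tme1$genes), format(x$tme1$cutoff, digits = 4), x$marker_cd8a,
    x$infiltration_percentile
  ))
  cat(sprintf(
    "  TME2 response:     %d genes, cutoff %s (markers %s, %s)\n",
    length(x$tme2$genes), format(x$tme2$cutoff, digits = 4), x$marker_pd1, x$marker_tim3
  ))
  cat(sprintf(
    "  validation rule quantiles: %.2f / %.2f; CD8-restricted subset: %d genes\n",
    x$validation_low_quantile, x$validation_high_quantile, length(x$cd8_restricted_genes)
  ))
  invisible(x)
}

#' @describeIn tmepre_model One row per signature gene across both components,
#'   with standardization parameters and centroids.
#' @param x A `tmepre_model`.
#' @param ... Unused.
#' @method tidy tmepre_model
#' @export
tidy.tmepre_model <- function(x, ...) {
  sig_tbl <- function(sig, component) {
    tibble(
      component = component,
      gene_id = sig$genes,
      mu = unname(sig$mu),
      sigma = unname(sig$sigma),
      centroid_pos = unname(sig$centroid_pos),
      centroid_neg = unname(sig$centroid_neg)
    )
  }
  dplyr::bind_rows(sig_tbl(x$tme1, "TME1"), sig_tbl(x$tme2, "TME2"))
}

#' @describeIn tmepre_model One-row model summary (signature sizes, cutoffs,
#'   markers, decision-rule quantiles).
#' @method glance tmepre_model
#' @export
glance.tmepre_model <- function(x, ...) {
  tibble(
    n_genes_tme1 = length(x$tme1$genes),
    n_genes_tme2 = length(x$tme2$genes),
    cutoff_tme1 = x$tme1$cutoff,
    cutoff_tme2 = x$tme2$cutoff,
    marker_cd8a = x$marker_cd8a,
    marker_pd1 = x$marker_pd1,
    marker_tim3 = x$marker_tim3,
    infiltration_percentile = x$infiltration_percentile,
    validation_low_quantile = x$validation_low_quantile,
    validation_high_quantile = x$validation_high_quantile
  )
}
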