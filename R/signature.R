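#' Vectorized Welch two-sample t-test over genes
#'
#' Computes the unequal-variance t statistic and two-sided p-value for every
#' gene between two sample groups. A gene with zero variance in both groups
#' and equal means gets p = 1 by convention; zero pooled standard error with
#' unequal means gives p = 0 (infinite t). Vectorized because stability
#' selection calls it hundreds of times.
#'
#' @param expr Expression matrix.
#' @param pos_ids,neg_ids Sample ids of the two groups (each of size >= 2).
#' @return A tibble with `gene_id`, `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(expr, pos_ids, neg_ids) {
  if (length(pos_ids) < 2 || length(neg_ids) < 2) {
    abort("welch_t: both groups need at least 2 samples")
  }
  x <- expr[, pos_ids, drop = FALSE]
  y <- expr[, neg_ids, drop = FALSE]
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  same <- degenerate & (m1 == m2)
  diff <- degenerate & (m1 != m2)
  tstat[same] <- 0
  p[same] <- 1
  df[degenerate] <- NA_real_
  tstat[diff] <- sign(m1[diff] - m2[diff]) * Inf
  p[diff] <- 0
  tibble(gene_id = rownames(expr), statistic = unname(tstat), df = unname(df), p_value = unname(p))
}

#' Stability-selection parameters
#'
#' @param n_rounds Number of cross-validation rounds (default 200).
#' @param n_folds Folds per round (default 10).
#' @param top_k Genes counted as "hits" per round (default 60).
#' @param min_frequency Minimum fraction of rounds a gene must be a hit to be
#'   selected (default 0.80).
#' @param excluded_genes Genes removed from candidacy before ranking (the
#'   infiltration marker is always excluded from its own contrast).
#' @param seed Integer seed for the fold shuffles.
#' @return A `stability_params` list.
#' @export
stability_params <- function(n_rounds = 200, n_folds = 10, top_k = 60,
                             min_frequency = 0.80, excluded_genes = character(),
                             seed = 1L) {
  if (n_rounds < 1 || top_k < 1) abort("n_rounds and top_k must be at least 1")
  if (n_folds < 2) abort("n_folds must be at least 2")
  if (!(min_frequency > 0 && min_frequency <= 1)) abort("min_frequency must lie in (0, 1]")
  structure(
    list(
      n_rounds = as.integer(n_rounds), n_folds = as.integer(n_folds),
      top_k = as.integer(top_k), min_frequency = min_frequency,
      excluded_genes = as.character(excluded_genes), seed = as.integer(seed)
    ),
    class = "stability_params"
  )
}

# Deterministic ranking: ascending p, ties broken by larger |t|, then gene id.
rank_top_genes <- function(tt, top_k) {
  ord <- order(tt$p_value, -abs(tt$statistic), tt$gene_id)
  tt$gene_id[ord[seq_len(min(top_k, nrow(tt)))]]
}

#' Stability selection by repeated cross-validated t-test ranking
#'
#' For each round, the pooled POS and NEG samples are shuffled into
#' `n_folds` stratified folds; one fold (cycling through rounds) is held
#' out, a Welch t-test is run on the retained samples, genes are ranked by
#' ascending p-value, and the per-round top-`top_k` set is recorded. Genes
#' ranked in the top `top_k` in at least `min_frequency` of the rounds are
#' selected. With the defaults this is the 200-round, 10-fold, top-60,
#' 80%-frequency rule used to derive both signatures.
#'
#' @param expr Expression matrix.
#' @param groups Group-label tibble (sample_id, label in POS/NEG/EXCLUDED).
#' @param params A [stability_params()].
#' @return A `selection_report`: a list with `frequencies` (tibble of
#'   gene_id, frequency, selected), `selected` (ordered by descending
#'   frequency) and `params`.
#' @export
stability_select <- function(expr, groups, params = stability_params()) {
  validate_expression_matrix(expr)
  pos <- groups$sample_id[groups$label == "POS"]
  neg <- groups$sample_id[groups$label == "NEG"]
  if (length(pos) < params$n_folds || length(neg) < params$n_folds) {
    abort(sprintf(
      "stability_select: each group needs at least n_folds = %d samples (POS has %d, NEG has %d)",
      params$n_folds, length(pos), length(neg)
    ))
  }
  candidates <- setdiff(rownames(expr), params$excluded_genes)
  if (length(candidates) == 0) abort("no candidate genes after exclusions")
  sub <- expr[candidates, , drop = FALSE]

  hits <- stats::setNames(integer(length(candidates)), candidates)
  set.seed(params$seed)
  for (r in seq_len(params$n_rounds)) {
    held <- ((r - 1L) %% params$n_folds) + 1L
    fold_pos <- sample(rep_len(seq_len(params$n_folds), length(pos)))
    fold_neg <- sample(rep_len(seq_len(params$n_folds), length(neg)))
    train_pos <- pos[fold_pos != held]
    train_neg <- neg[fold_neg != held]
    tt <- welch_t(sub, train_pos, train_neg)
    top <- rank_top_genes(tt, params$top_k)
    hits[top] <- hits[top] + 1L
  }
  freq <- hits / params$n_rounds
  tbl <- tibble(
    gene_id = candidates,
    frequency = unname(freq),
    selected = unname(freq >= params$min_frequency)
  )
  selected <- tbl$gene_id[tbl$selected][order(-tbl$frequency[tbl$selected], tbl$gene_id[tbl$selected])]
  structure(
    list(frequencies = tbl, selected = selected, params = params),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d/%d genes selected (top %d in >= %.0f%% of %d rounds)\n",
    length(x$selected), nrow(x$frequencies), x$params$top_k,
    100 * x$params$min_frequency, x$params$n_rounds
  ))
  invisible(x)
}

#' @describeIn stability_select Per-gene selection frequencies as a tibble.
#' @param x A `selection_report`.
#' @param ... Unused.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  dplyr::arrange(x$frequencies, dplyr::desc(.data$frequency), .data$gene_id)
}

#' Fit a nearest-centroid signature
#'
#' Standardization mean/SD per gene come from the pooled POS and NEG
#' training samples; the centroids are the standardized group means. The
#' continuous score of a sample is the difference of Euclidean distances to
#' the two centroids, divided by the number of genes, so higher scores mean
#' closer to the POS class.
#'
#' @param expr Expression matrix.
#' @param groups Group-label tibble.
#' @param genes Selected signature genes (nonempty).
#' @param positive_label Meaning of the POS class for reporting.
#' @return A [centroid_signature()] without a cutoff.
#' @export
fit_centroid <- function(expr, groups, genes, positive_label = "POS") {
  if (length(genes) == 0) abort("fit_centroid: empty gene list")
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g) > 0) {
    abort(paste0("signature genes absent from matrix: ", paste(head(missing_g, 5), collapse = ", ")))
  }
  pos <- groups$sample_id[groups$label == "POS"]
  neg <- groups$sample_id[groups$label == "NEG"]
  if (length(pos) == 0 || length(neg) == 0) abort("fit_centroid: both groups must be nonempty")
  train <- c(pos, neg)
  sub <- expr[genes, train, drop = FALSE]
  mu <- rowMeans(sub)
  sigma <- apply(sub, 1, sd)
  if (any(sigma == 0)) {
    abort(paste0(
      "zero training variance for gene(s): ",
      paste(head(genes[sigma == 0], 5), collapse = ", "),
      " (drop them upstream)"
    ))
  }
  z <- (sub - mu) / sigma
  centroid_signature(
    genes = genes, mu = mu, sigma = sigma,
    centroid_pos = rowMeans(z[, pos, drop = FALSE]),
    centroid_neg = rowMeans(z[, neg, drop = FALSE]),
    positive_label = positive_label
  )
}

score_signature <- function(sig, expr) {
  missing_g <- setdiff(sig$genes, rownames(expr))
  if (length(missing_g) > 0) {
    abort(paste0(
      "signature genes absent from matrix: ",
      paste(missing_g, collapse = ", ")
    ))
  }
  z <- (expr[sig$genes, , drop = FALSE] - sig$mu) / sig$sigma
  d_pos <- sqrt(colSums((z - sig$centroid_pos)^2))
  d_neg <- sqrt(colSums((z - sig$centroid_neg)^2))
  (d_neg - d_pos) / length(sig$genes)
}

#' Optimize the classification cutoff for maximal sensitivity
#'
#' Returns the largest threshold under which every POS training score still
#' classifies positive (score >= cutoff), i.e. the minimum POS training
#' score. Training sensitivity is 1 (no false negatives) and specificity is
#' the highest attainable under that constraint.
#'
#' @param pos_scores,neg_scores Training scores of the two classes.
#' @return The cutoff (a single number).
#' @export
optimize_cutoff <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    abort("optimize_cutoff: both score sets must be nonempty")
  }
  min(pos_scores)
}

#' Derive the full two-component model from a training cohort
#'
#' Runs the whole derivation: the infiltration contrast (40th-percentile
#' CD8A rule on MSI vs MSS), stability selection with the CD8A marker
#' excluded, nearest-centroid fit and cutoff optimization for TME1; then the
#' exhaustion contrast (PD1/TIM3 medians within high-infiltration MSI
#' tumors), stability selection, centroid fit and cutoff for TME2.
#'
#' @param expr Expression matrix with the three marker genes.
#' @param annotations Annotation tibble (MSI and MSS samples present).
#' @param params_tme1,params_tme2 [stability_params()] for each component.
#' @param marker_cd8a,marker_pd1,marker_tim3 Marker gene ids.
#' @param infiltration_percentile CD8A percentile for the infiltration rule.
#' @param validation_low_quantile,validation_high_quantile Decision-rule
#'   quantiles stored in the model.
#' @param cd8_restricted_genes Gene subset for the purified-cell read-out.
#' @return A list with `model` (the [tmepre_model()]), the two
#'   `selection_report`s (`report_tme1`, `report_tme2`) and the group
#'   constructions (`infiltration`, `exhaustion`).
#' @export
build_tmepre <- function(expr, annotations,
                         params_tme1 = stability_params(seed = 101L),
                         params_tme2 = stability_params(seed = 202L),
                         marker_cd8a = "CD8A", marker_pd1 = "PDCD1", marker_tim3 = "HAVCR2",
                         infiltration_percentile = 0.40,
                         validation_low_quantile = 0.25,
                         validation_high_quantile = 0.75,
                         cd8_restricted_genes = default_cd8_genes()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  inf <- stage("infiltration groups", define_infiltration_groups(
    expr, annotations,
    marker = marker_cd8a, percentile = infiltration_percentile
  ))
  params_tme1$excluded_genes <- union(params_tme1$excluded_genes, marker_cd8a)
  rep1 <- stage("TME1 stability selection", stability_select(expr, inf$groups, params_tme1))
  if (length(rep1$selected) == 0) abort("[TME1 stability selection] no gene passed the frequency threshold")
  sig1 <- stage("TME1 centroid fit", fit_centroid(
    expr, inf$groups, rep1$selected,
    positive_label = "high_infiltration"
  ))
  s1 <- score_signature(sig1, expr)
  pos1 <- inf$groups$sample_id[inf$groups$label == "POS"]
  neg1 <- inf$groups$sample_id[inf$groups$label == "NEG"]
  sig1$cutoff <- optimize_cutoff(s1[pos1], s1[neg1])

  exh <- stage("exhaustion groups", define_exhaustion_groups(
    expr, pos1,
    marker_pd1 = marker_pd1, marker_tim3 = marker_tim3
  ))
  rep2 <- stage("TME2 stability selection", stability_select(expr, exh$groups, params_tme2))
  if (length(rep2$selected) == 0) abort("[TME2 stability selection] no gene passed the frequency threshold")
  sig2 <- stage("TME2 centroid fit", fit_centroid(
    expr, exh$groups, rep2$selected,
    positive_label = "responsive"
  ))
  s2 <- score_signature(sig2, expr)
  pos2 <- exh$groups$sample_id[exh$groups$label == "POS"]
  neg2 <- exh$groups$sample_id[exh$groups$label == "NEG"]
  sig2$cutoff <- optimize_cutoff(s2[pos2], s2[neg2])

  model <- tmepre_model(
    tme1 = sig1, tme2 = sig2,
    marker_cd8a = marker_cd8a, marker_pd1 = marker_pd1, marker_tim3 = marker_tim3,
    infiltration_percentile = infiltration_percentile,
    validation_low_quantile = validation_low_quantile,
    validation_high_quantile = validation_high_quantile,
    cd8_restricted_genes = cd8_restricted_genes
  )
  list(model = model, report_tme1 = rep1, report_tme2 = rep2, infiltration = inf, exhaustion = exh)
}
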