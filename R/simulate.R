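#' Configure a synthetic colorectal-cancer cohort
#'
#' The simulator emulates the statistical structure the model derivation
#' assumes: a marker gene (CD8A) and a planted infiltration program shifted
#' up in infiltrated tumors, two inhibitory-receptor markers (PDCD1, HAVCR2)
#' and a planted exhaustion program additionally shifted up in tumors whose
#' infiltrating T cells are terminally exhausted, and i.i.d. Gaussian noise
#' genes in log2 space. Exhaustion is nested within infiltration. Defaults
#' mirror the cohort the method was developed on: 131 MSI and 284 MSS tumors.
#'
#' @param n_msi,n_mss Numbers of MSI and MSS samples.
#' @param n_genes Total number of genes, including the three markers and the
#'   planted programs.
#' @param n_infiltration_genes,n_exhaustion_genes Sizes of the planted
#'   programs (markers not counted).
#' @param effect_size_infiltration,effect_size_exhaustion Mean log2 shifts of
#'   the planted programs (and their markers) in affected samples.
#' @param noise_sd Per-gene Gaussian noise SD in log2 units.
#' @param frac_msi_infiltrated,frac_mss_infiltrated Probabilities that an
#'   MSI (resp. MSS) tumor carries the infiltration program.
#' @param frac_infiltrated_exhausted Probability that an infiltrated tumor's
#'   T cells are terminally exhausted.
#' @param exhaustion_gene_ids Optional names for the planted exhaustion
#'   genes; by default the first seven are the CD8-expressed symbols of
#'   [default_cd8_genes()] so the restricted read-out can be exercised on
#'   derived models.
#' @param seed Integer seed; the simulator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_msi = 131, n_mss = 284, n_genes = 1000,
                       n_infiltration_genes = 20, n_exhaustion_genes = 20,
                       effect_size_infiltration = 3, effect_size_exhaustion = 3,
                       noise_sd = 1,
                       frac_msi_infiltrated = 0.6, frac_mss_infiltrated = 0.1,
                       frac_infiltrated_exhausted = 0.5,
                       exhaustion_gene_ids = NULL, seed = 1L) {
  cfg <- list(
    n_msi = as.integer(n_msi), n_mss = as.integer(n_mss), n_genes = as.integer(n_genes),
    n_infiltration_genes = as.integer(n_infiltration_genes),
    n_exhaustion_genes = as.integer(n_exhaustion_genes),
    effect_size_infiltration = effect_size_infiltration,
    effect_size_exhaustion = effect_size_exhaustion,
    noise_sd = noise_sd,
    frac_msi_infiltrated = frac_msi_infiltrated,
    frac_mss_infiltrated = frac_mss_infiltrated,
    frac_infiltrated_exhausted = frac_infiltrated_exhausted,
    exhaustion_gene_ids = exhaustion_gene_ids,
    seed = as.integer(seed)
  )
  if (cfg$n_msi < 1 || cfg$n_mss < 0) abort("need at least one MSI sample")
  if (cfg$noise_sd <= 0) abort("noise_sd must be positive")
  probs <- c(cfg$frac_msi_infiltrated, cfg$frac_mss_infiltrated, cfg$frac_infiltrated_exhausted)
  if (any(probs < 0 | probs > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$n_infiltration_genes + cfg$n_exhaustion_genes + 3L > cfg$n_genes) {
    abort("n_genes must cover the planted programs plus the three marker genes")
  }
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(cfg) {
  markers <- c("CD8A", "PDCD1", "HAVCR2")
  inf <- sprintf("TINF%03d", seq_len(cfg$n_infiltration_genes))
  if (is.null(cfg$exhaustion_gene_ids)) {
    named <- setdiff(default_cd8_genes(), c("PDCD1", "HAVCR2"))
    n_named <- min(length(named), cfg$n_exhaustion_genes)
    exh <- c(
      named[seq_len(n_named)],
      if (cfg$n_exhaustion_genes > n_named) {
        sprintf("TEXH%03d", seq.int(n_named + 1L, cfg$n_exhaustion_genes))
      }
    )
  } else {
    exh <- as.character(cfg$exhaustion_gene_ids)
    if (length(exh) != cfg$n_exhaustion_genes) {
      abort("exhaustion_gene_ids must have length n_exhaustion_genes")
    }
  }
  n_bg <- cfg$n_genes - length(markers) - length(inf) - length(exh)
  bg <- sprintf("BG%05d", seq_len(n_bg))
  list(markers = markers, infiltration = inf, exhaustion = exh, background = bg)
}

#' Simulate a cohort with planted ground truth
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (genes-by-samples matrix), `annotations`
#'   (tibble) and `truth` (per-sample latent infiltration/exhaustion states
#'   and the planted gene ids).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ids <- sim_gene_ids(config)
  genes <- c(ids$markers, ids$infiltration, ids$exhaustion, ids$background)
  samples <- c(
    sprintf("MSI_%03d", seq_len(config$n_msi)),
    sprintf("MSS_%03d", seq_len(config$n_mss))
  )
  msi_status <- rep(c("MSI", "MSS"), c(config$n_msi, config$n_mss))

  baseline <- rnorm(length(genes), mean = 7, sd = 2)
  expr <- baseline + matrix(
    rnorm(length(genes) * length(samples), sd = config$noise_sd),
    nrow = length(genes)
  )
  dimnames(expr) <- list(genes, samples)

  p_inf <- ifelse(msi_status == "MSI", config$frac_msi_infiltrated, config$frac_mss_infiltrated)
  infiltrated <- runif(length(samples)) < p_inf
  exhausted <- infiltrated & (runif(length(samples)) < config$frac_infiltrated_exhausted)

  inf_rows <- c("CD8A", ids$infiltration)
  exh_rows <- c("PDCD1", "HAVCR2", ids$exhaustion)
  expr[inf_rows, infiltrated] <- expr[inf_rows, infiltrated] + config$effect_size_infiltration
  expr[exh_rows, exhausted] <- expr[exh_rows, exhausted] + config$effect_size_exhaustion

  annotations <- validate_annotations(tibble(
    sample_id = samples, msi_status = msi_status, cohort = "synthetic"
  ))
  truth <- list(
    infiltrated = stats::setNames(infiltrated, samples),
    exhausted = stats::setNames(exhausted, samples),
    infiltration_genes = ids$infiltration,
    exhaustion_genes = ids$exhaustion,
    marker_genes = ids$markers
  )
  list(expr = expr, annotations = annotations, truth = truth)
}

#' Simulate purified progenitor/terminally exhausted CD8+ T cells
#'
#' Emulates expression profiles of CD8+ T cells sorted into progenitor
#' exhausted (still anti-PD1 responsive) and terminally exhausted states:
#' the terminal group has the inhibitory receptors PDCD1/HAVCR2 and the
#' CD8-expressed exhaustion-signature genes shifted up.
#'
#' @param n_per_group Samples per group (at least 2).
#' @param effect Log2 shift of the exhaustion genes in the terminal group.
#' @param seed Integer seed.
#' @param cd8_genes Genes carrying the shift (default [default_cd8_genes()]).
#' @param n_background Additional pure-noise genes.
#' @param noise_sd Gaussian noise SD in log2 units.
#' @return A list with `expr` and `groups` (tibble of sample_id, group).
#' @export
simulate_purified_tcells <- function(n_per_group, effect, seed = 1L,
                                     cd8_genes = default_cd8_genes(),
                                     n_background = 200, noise_sd = 1) {
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  set.seed(as.integer(seed))
  genes <- unique(c(cd8_genes, sprintf("BG%05d", seq_len(n_background))))
  samples <- c(
    sprintf("PROG_%03d", seq_len(n_per_group)),
    sprintf("TERM_%03d", seq_len(n_per_group))
  )
  group <- rep(c("progenitor", "terminal"), each = n_per_group)
  baseline <- rnorm(length(genes), mean = 7, sd = 2)
  expr <- baseline + matrix(rnorm(length(genes) * length(samples), sd = noise_sd),
    nrow = length(genes)
  )
  dimnames(expr) <- list(genes, samples)
  expr[cd8_genes, group == "terminal"] <- expr[cd8_genes, group == "terminal"] + effect
  list(expr = expr, groups = tibble(sample_id = samples, group = group))
}

#' Attach simulated survival outcomes to predictions
#'
#' Event times are exponential with a hazard `hr_true` times higher in
#' predicted nonresponders than in predicted responders. Censoring is
#' independent: each sample is censored with probability `censor_rate`, and a
#' censored sample's recorded time is uniform on (0, its event time).
#'
#' @param annotations Annotation tibble covering all predicted samples.
#' @param predicted Tibble with `sample_id` and `predicted`
#'   ("responder"/"nonresponder"), e.g. from [classify_validation_cohort()].
#' @param hr_true True hazard ratio (nonresponder vs responder), positive.
#' @param censor_rate Probability a sample is censored, in [0, 1].
#' @param seed Integer seed.
#' @param base_rate Responder event hazard per day (default corresponds to a
#'   two-year median survival).
#' @return The annotations with `surv_time` (days) and `surv_event` filled in.
#' @export
simulate_survival <- function(annotations, predicted, hr_true, censor_rate = 0.3,
                              seed = 1L, base_rate = log(2) / 730) {
  if (hr_true <= 0) abort("hr_true must be positive")
  if (censor_rate < 0 || censor_rate > 1) abort("censor_rate must lie in [0, 1]")
  ann <- validate_annotations(annotations)
  missing_pred <- setdiff(ann$sample_id, predicted$sample_id)
  if (length(missing_pred) > 0) {
    abort(paste0(
      "every sample needs a predicted label; missing: ",
      paste(head(missing_pred, 5), collapse = ", ")
    ))
  }
  set.seed(as.integer(seed))
  lab <- predicted$predicted[match(ann$sample_id, predicted$sample_id)]
  rate <- ifelse(lab == "nonresponder", base_rate * hr_true, base_rate)
  t_event <- rexp(nrow(ann), rate = rate)
  censored <- runif(nrow(ann)) < censor_rate
  ann$surv_time <- ifelse(censored, runif(nrow(ann)) * t_event, t_event)
  ann$surv_event <- !censored
  ann
}
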