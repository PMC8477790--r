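#' Two-group log-rank test
#'
#' Standard log-rank test of survival separation between two groups. The
#' one-sided p-value is oriented toward the hypothesis that `worse` (default
#' "nonresponder", else the second group level) has worse survival: when the
#' observed-minus-expected events in that group are positive, the one-sided
#' p is half the two-sided p; otherwise its complement.
#'
#' @param times Follow-up times.
#' @param events Logical (or 0/1) event indicators.
#' @param groups Two-level group labels.
#' @param worse Level hypothesized to have worse survival.
#' @return A tibble with `statistic` (chi-square, 1 df), `p_two_sided`,
#'   `p_one_sided`, and per-group observed/expected event counts in
#'   `n1`, `n2`, `obs_worse`, `exp_worse`.
#' @export
logrank_test <- function(times, events, groups, worse = NULL) {
  events <- as.logical(events)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) abort("logrank_test: exactly two groups required")
  if (sum(events) == 0) abort("logrank_test: no events observed")
  worse <- worse %||% (if ("nonresponder" %in% levels(groups)) "nonresponder" else levels(groups)[2])
  if (!worse %in% levels(groups)) abort(sprintf("group level '%s' not present", worse))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- sd$chisq
  p2 <- pchisq(stat, df = 1, lower.tail = FALSE)
  i_worse <- which(levels(groups) == worse)
  direction <- sd$obs[i_worse] - sd$exp[i_worse]
  p1 <- if (direction >= 0) p2 / 2 else 1 - p2 / 2
  tibble(
    statistic = stat, p_two_sided = p2, p_one_sided = p1,
    n1 = sum(groups == levels(groups)[1]), n2 = sum(groups == levels(groups)[2]),
    obs_worse = sd$obs[i_worse], exp_worse = sd$exp[i_worse]
  )
}

#' Univariate Cox proportional-hazards fit for a binary covariate
#'
#' Partial-likelihood maximization with Efron tie handling. A monotone
#' likelihood (complete separation of events between groups) is reported via
#' the `infinite` flag rather than an error.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param covariate Two-level covariate; the hazard ratio is for the second
#'   level relative to the first (alphabetical unless a factor is supplied).
#' @return A tibble with `hazard_ratio`, `beta`, `se`, `infinite`, `n`,
#'   `n_event`.
#' @export
cox_hr <- function(times, events, covariate) {
  events <- as.logical(events)
  covariate <- if (is.factor(covariate)) droplevels(covariate) else factor(covariate)
  if (nlevels(covariate) != 2) abort("cox_hr: covariate must have exactly two levels present")
  if (sum(events) == 0) abort("cox_hr: no events observed")
  x <- as.integer(covariate) - 1L
  infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        infinite <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (abs(beta) > 15) infinite <- TRUE
  tibble(
    hazard_ratio = exp(beta), beta = beta, se = se, infinite = infinite,
    n = length(times), n_event = sum(events)
  )
}

#' Combine independent p-values by the Stouffer Z-transform method
#'
#' Each p-value is mapped to a normal quantile z = qnorm(1 - p); the
#' combined p is 1 - pnorm(sum(z) / sqrt(k)), unweighted. The inputs are
#' consumed as-is (one-sided-style), which is the reading under which the
#' three validation-cohort survival p-values (0.056, 0.115, 0.003) combine
#' to 0.0007.
#'
#' @param pvalues Numeric vector of p-values, each strictly inside (0, 1).
#' @return The combined p-value (a single number).
#' @export
stouffer_combine <- function(pvalues) {
  if (length(pvalues) == 0) abort("stouffer_combine: need at least one p-value")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues >= 1)) {
    abort("stouffer_combine: all p-values must lie strictly inside (0, 1)")
  }
  z <- qnorm(1 - pvalues)
  1 - pnorm(sum(z) / sqrt(length(pvalues)))
}

#' Pearson correlation of two score vectors, overall and per stratum
#'
#' Used to compare the infiltration score against external reference scores
#' (e.g. deconvolution-based cytotoxic-lymphocyte counts).
#'
#' @param score_a,score_b Equal-length finite numeric vectors.
#' @param strata Optional stratum labels (e.g. MSI status); strata with
#'   fewer than 3 samples are skipped.
#' @return A tibble with `stratum` ("overall" first), `n`, `r`.
#' @export
correlate_scores <- function(score_a, score_b, strata = NULL) {
  if (length(score_a) != length(score_b)) abort("score vectors must have equal length")
  if (length(score_a) < 3) abort("need at least 3 samples")
  if (!all(is.finite(score_a)) || !all(is.finite(score_b))) abort("scores must be finite")
  if (sd(score_a) == 0 || sd(score_b) == 0) abort("zero variance in a score vector")
  out <- tibble(stratum = "overall", n = length(score_a), r = cor(score_a, score_b))
  if (!is.null(strata)) {
    per <- tibble(a = score_a, b = score_b, stratum = as.character(strata)) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::filter(dplyr::n() >= 3) |>
      dplyr::summarise(n = dplyr::n(), r = cor(.data$a, .data$b), .groups = "drop")
    out <- dplyr::bind_rows(out, per)
  }
  out
}

#' Summarize predictions per MSI stratum
#'
#' Counts and one-decimal percentages (rounded half up, as printed in
#' clinical reports) of predicted responders and of the two nonresponder
#' mechanisms, per microsatellite stratum. Empty strata are omitted with a
#' notice.
#'
#' @param predictions Predictions tibble with `sample_id`, `predicted`,
#'   `mechanism`.
#' @param annotations Annotation tibble with `msi_status` for every
#'   predicted sample.
#' @return A tibble with one row per stratum: `msi_status`, `n`,
#'   `n_responder`, `n_nonresponder`, `n_insufficient_infiltration`,
#'   `n_terminal_exhaustion` and matching `pct_*` columns.
#' @export
summarize_cohort <- function(predictions, annotations) {
  ann <- validate_annotations(annotations)
  missing_s <- setdiff(predictions$sample_id, ann$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("annotations missing for sample(s): ", paste(head(missing_s, 5), collapse = ", ")))
  }
  empty <- setdiff(unique(ann$msi_status), unique(ann$msi_status[ann$sample_id %in% predictions$sample_id]))
  if (length(empty) > 0) {
    inform(paste0("stratum with no predictions omitted: ", paste(empty, collapse = ", ")))
  }
  predictions |>
    dplyr::inner_join(dplyr::select(ann, "sample_id", "msi_status"), by = "sample_id") |>
    dplyr::group_by(.data$msi_status) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_responder = sum(.data$predicted == "responder"),
      n_nonresponder = sum(.data$predicted == "nonresponder"),
      n_insufficient_infiltration = sum(.data$mechanism == "insufficient_infiltration"),
      n_terminal_exhaustion = sum(.data$mechanism == "terminal_exhaustion"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_responder = round_half_up(100 * .data$n_responder / .data$n),
      pct_nonresponder = round_half_up(100 * .data$n_nonresponder / .data$n),
      pct_insufficient_infiltration = round_half_up(100 * .data$n_insufficient_infiltration / .data$n),
      pct_terminal_exhaustion = round_half_up(100 * .data$n_terminal_exhaustion / .data$n)
    )
}

#' Survival read-out for a predicted cohort
#'
#' Bundles the Cox hazard ratio (nonresponder vs responder), the log-rank
#' test and the Kaplan-Meier curves for a cohort with predictions and
#' survival annotations.
#'
#' @param predictions Predictions tibble.
#' @param annotations Annotation tibble with `surv_time`/`surv_event` for
#'   the predicted samples.
#' @return A `tmepre_survival` object; see [tidy.tmepre_survival()] for the
#'   KM curves and [glance.tmepre_survival()] for the statistics.
#' @export
survival_readout <- function(predictions, annotations) {
  ann <- validate_annotations(annotations)
  dat <- predictions |>
    dplyr::inner_join(
      dplyr::select(ann, "sample_id", "surv_time", "surv_event"),
      by = "sample_id"
    ) |>
    dplyr::filter(!is.na(.data$surv_time))
  if (nrow(dat) == 0) abort("no samples with survival annotations")
  if (length(unique(dat$predicted)) != 2) {
    abort("survival read-out needs both predicted classes present")
  }
  grp <- factor(dat$predicted, levels = c("responder", "nonresponder"))
  lr <- logrank_test(dat$surv_time, dat$surv_event, grp, worse = "nonresponder")
  cx <- cox_hr(dat$surv_time, dat$surv_event, grp)
  km <- survival::survfit(survival::Surv(dat$surv_time, dat$surv_event) ~ grp)
  structure(list(logrank = lr, cox = cx, km = km, data = dat), class = "tmepre_survival")
}

#' @export
print.tmepre_survival <- function(x, ...) {
  cat(sprintf(
    "<tmepre_survival> n = %d (%d events); HR = %s; log-rank p = %.4g\n",
    x$cox$n, x$cox$n_event,
    if (x$cox$infinite) "inf (monotone likelihood)" else format(x$cox$hazard_ratio, digits = 3),
    x$logrank$p_two_sided
  ))
  invisible(x)
}

#' @describeIn survival_readout Kaplan-Meier step curves as a tibble
#'   (`group`, `time`, `n_risk`, `n_event`, `survival`).
#' @param x A `tmepre_survival` object.
#' @param ... Unused.
#' @method tidy tmepre_survival
#' @export
tidy.tmepre_survival <- function(x, ...) {
  km <- x$km
  grp <- sub("^grp=", "", rep(names(km$strata), km$strata))
  tibble(
    group = grp, time = km$time, n_risk = km$n.risk,
    n_event = km$n.event, survival = km$surv
  )
}

#' @describeIn survival_readout One-row summary: hazard ratio, beta, se,
#'   log-rank statistic and p-values, sample and event counts.
#' @method glance tmepre_survival
#' @export
glance.tmepre_survival <- function(x, ...) {
  tibble(
    hazard_ratio = x$cox$hazard_ratio, beta = x$cox$beta, se = x$cox$se,
    infinite_hr = x$cox$infinite,
    logrank_statistic = x$logrank$statistic,
    p_two_sided = x$logrank$p_two_sided, p_one_sided = x$logrank$p_one_sided,
    n = x$cox$n, n_event = x$cox$n_event
  )
}
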