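# Shared fixtures and independent oracles, built in code at test time.

# Small cohort for fast unit tests; full-scale cohorts are built inline
# where a test needs them.
small_cohort <- function(seed = 11L, ...) {
  simulate_cohort(sim_config(
    n_msi = 40, n_mss = 60, n_genes = 150,
    n_infiltration_genes = 10, n_exhaustion_genes = 10,
    seed = seed, ...
  ))
}

# Reduced stability parameters sized for the small cohort.
small_params <- function(seed = 1L, ...) {
  stability_params(n_rounds = 50, n_folds = 5, top_k = 25, seed = seed, ...)
}

# One small derived model, memoized across tests in a file run.
cached_model_env <- new.env(parent = emptyenv())
small_model <- function() {
  if (is.null(cached_model_env$fit)) {
    sim <- simulate_cohort(sim_config(
      n_msi = 80, n_mss = 120, n_genes = 300,
      n_infiltration_genes = 15, n_exhaustion_genes = 15, seed = 7L
    ))
    cached_model_env$fit <- build_tmepre(
      sim$expr, sim$annotations,
      params_tme1 = stability_params(n_rounds = 60, n_folds = 5, top_k = 40, seed = 71L),
      params_tme2 = stability_params(n_rounds = 60, n_folds = 5, top_k = 40, seed = 72L)
    )
    cached_model_env$sim <- sim
  }
  cached_model_env
}

# Independent log-rank oracle: explicit hypergeometric observed-minus-expected
# sums at each distinct event time (never calls the survival package).
oracle_logrank_chisq <- function(times, events, groups) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == lv[1])
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & groups == lv[1])
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Independent Cox oracle for untied data: numeric maximization of the exact
# partial likelihood written out sample by sample.
oracle_cox_beta <- function(times, events, x) {
  stopifnot(!anyDuplicated(times[events]))
  negll <- function(beta) {
    ll <- 0
    for (i in which(events)) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    -ll
  }
  stats::optimize(negll, interval = c(-8, 8), tol = 1e-9)$minimum
}

# Hand-constructed restricted signature over the nine CD8-expressed genes:
# terminal-exhaustion (NEG) centroid high, responsive (POS) centroid low.
toy_cd8_model <- function() {
  g9 <- default_cd8_genes()
  extra <- c("KMO", "FCGR1A")
  genes <- c(g9, extra)
  sig2 <- centroid_signature(
    genes = genes,
    mu = rep(7, length(genes)), sigma = rep(1, length(genes)),
    centroid_pos = rep(-0.8, length(genes)), centroid_neg = rep(0.8, length(genes)),
    cutoff = 0, positive_label = "responsive"
  )
  sig1 <- centroid_signature(
    genes = c("TINF001", "TINF002"),
    mu = c(7, 7), sigma = c(1, 1),
    centroid_pos = c(1, 1), centroid_neg = c(-1, -1),
    cutoff = 0, positive_label = "high_infiltration"
  )
  tmepre_model(tme1 = sig1, tme2 = sig2)
}
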