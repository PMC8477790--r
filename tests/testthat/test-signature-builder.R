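test_that("vectorized Welch t matches the scalar reference per gene", {
  set.seed(31)
  expr <- matrix(rnorm(20 * 12, 7), 20, 12,
    dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12))
  )
  expr[1:3, 1:6] <- expr[1:3, 1:6] + 2
  pos <- colnames(expr)[1:6]
  neg <- colnames(expr)[7:12]
  tt <- welch_t(expr, pos, neg)
  for (i in seq_len(nrow(expr))) {
    ref <- stats::t.test(expr[i, pos], expr[i, neg])
    expect_equal(tt$statistic[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$p_value[i], ref$p.value, tolerance = 1e-10)
    expect_equal(tt$df[i], unname(ref$parameter), tolerance = 1e-10)
  }

  simple <- matrix(c(5, 6, 7, 1, 2, 3), 1, dimnames = list("g", sprintf("x%d", 1:6)))
  ref <- stats::t.test(c(5, 6, 7), c(1, 2, 3))
  got <- welch_t(simple, c("x1", "x2", "x3"), c("x4", "x5", "x6"))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Welch t handles degenerate variances and rejects tiny groups", {
  expr <- rbind(
    flat = rep(3, 8),
    shifted_flat = rep(c(1, 2), each = 4)
  )
  colnames(expr) <- sprintf("s%d", 1:8)
  tt <- welch_t(expr, colnames(expr)[1:4], colnames(expr)[5:8])
  expect_identical(tt$p_value[tt$gene_id == "flat"], 1)
  expect_identical(tt$p_value[tt$gene_id == "shifted_flat"], 0)
  expect_error(welch_t(expr, "s1", colnames(expr)[5:8]), "at least 2")
})

test_that("Welch t is calibrated on simulated null genes", {
  set.seed(33)
  expr <- matrix(rnorm(1000 * 40, 7), 1000, 40,
    dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:40))
  )
  tt <- welch_t(expr, colnames(expr)[1:20], colnames(expr)[21:40])
  rate <- mean(tt$p_value < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("stability selection recovers planted genes and is deterministic", {
  sim <- simulate_cohort(sim_config(
    n_msi = 60, n_mss = 90, n_genes = 220,
    n_infiltration_genes = 20, n_exhaustion_genes = 10,
    effect_size_infiltration = 3, seed = 35
  ))
  inf <- define_infiltration_groups(sim$expr, sim$annotations)
  params <- stability_params(n_rounds = 50, n_folds = 10, top_k = 40,
    excluded_genes = "CD8A", seed = 350
  )
  rep1 <- stability_select(sim$expr, inf$groups, params)
  expect_true(all(sim$truth$infiltration_genes %in% rep1$selected))
  expect_false("CD8A" %in% rep1$frequencies$gene_id)

  rep2 <- stability_select(sim$expr, inf$groups, params)
  expect_identical(rep1$frequencies, rep2$frequencies)

  # every round marks exactly top_k genes
  expect_identical(
    sum(rep1$frequencies$frequency) * params$n_rounds,
    as.numeric(params$top_k * params$n_rounds)
  )

  expect_error(
    stability_select(sim$expr, inf$groups, stability_params(n_folds = 200)),
    "at least n_folds"
  )
})

test_that("planted-gene recovery is monotone in effect size", {
  recovery <- vapply(c(0, 1.5, 3), function(eff) {
    sim <- simulate_cohort(sim_config(
      n_msi = 60, n_mss = 90, n_genes = 220,
      n_infiltration_genes = 20, effect_size_infiltration = eff, seed = 36
    ))
    inf <- define_infiltration_groups(sim$expr, sim$annotations)
    rep1 <- stability_select(
      sim$expr, inf$groups,
      stability_params(n_rounds = 40, n_folds = 10, top_k = 40,
        excluded_genes = "CD8A", seed = 360
      )
    )
    mean(sim$truth$infiltration_genes %in% rep1$selected)
  }, numeric(1))
  expect_true(all(diff(recovery) >= 0))
  expect_identical(recovery[3], 1)
})

test_that("nearest-centroid scores match hand-worked arithmetic", {
  # two genes, explicit training data
  expr <- rbind(
    gA = c(1, 3, 5, 7),
    gB = c(2, 2, 6, 6)
  )
  colnames(expr) <- c("n1", "n2", "p1", "p2")
  groups <- tibble::tibble(
    sample_id = colnames(expr),
    label = c("NEG", "NEG", "POS", "POS")
  )
  sig <- fit_centroid(expr, groups, c("gA", "gB"))

  mu_a <- mean(c(1, 3, 5, 7)); sd_a <- sd(c(1, 3, 5, 7))
  mu_b <- mean(c(2, 2, 6, 6)); sd_b <- sd(c(2, 2, 6, 6))
  test_sample <- c(gA = 4.5, gB = 3)
  z <- c((4.5 - mu_a) / sd_a, (3 - mu_b) / sd_b)
  cpos <- c(mean((c(5, 7) - mu_a) / sd_a), mean((c(6, 6) - mu_b) / sd_b))
  cneg <- c(mean((c(1, 3) - mu_a) / sd_a), mean((c(2, 2) - mu_b) / sd_b))
  expected <- (sqrt(sum((z - cneg)^2)) - sqrt(sum((z - cpos)^2))) / 2

  test_expr <- matrix(test_sample, ncol = 1, dimnames = list(c("gA", "gB"), "t1"))
  got <- tmepre:::score_signature(sig, test_expr)
  expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("centroid scores are symmetric, antisymmetric under label swap, and order-invariant", {
  fit <- small_model()
  sig <- fit$fit$model$tme1
  at_pos <- matrix(sig$mu + sig$sigma * sig$centroid_pos, ncol = 1,
    dimnames = list(sig$genes, "atpos")
  )
  at_neg <- matrix(sig$mu + sig$sigma * sig$centroid_neg, ncol = 1,
    dimnames = list(sig$genes, "atneg")
  )
  s_pos <- tmepre:::score_signature(sig, at_pos)
  s_neg <- tmepre:::score_signature(sig, at_neg)
  expect_gt(s_pos, 0)
  expect_lt(s_neg, 0)
  expect_equal(unname(s_pos), unname(-s_neg), tolerance = 1e-12)

  sim <- fit$sim
  inf <- fit$fit$infiltration
  swapped <- inf$groups
  swapped$label[swapped$label == "POS"] <- "TMP"
  swapped$label[swapped$label == "NEG"] <- "POS"
  swapped$label[swapped$label == "TMP"] <- "NEG"
  sig_swap <- fit_centroid(sim$expr, swapped, sig$genes)
  expect_equal(
    tmepre:::score_signature(sig_swap, sim$expr),
    -tmepre:::score_signature(sig, sim$expr),
    tolerance = 1e-12
  )

  reordered <- rev(sig$genes)
  sig_re <- fit_centroid(sim$expr, inf$groups, reordered)
  expect_equal(
    tmepre:::score_signature(sig_re, sim$expr),
    tmepre:::score_signature(sig, sim$expr),
    tolerance = 1e-12
  )
})

test_that("fit_centroid refuses zero-variance genes", {
  expr <- rbind(gA = c(1, 2, 3, 4), gB = rep(5, 4))
  colnames(expr) <- sprintf("s%d", 1:4)
  groups <- tibble::tibble(sample_id = colnames(expr), label = c("POS", "POS", "NEG", "NEG"))
  expect_error(fit_centroid(expr, groups, c("gA", "gB")), "gB")
})

test_that("cutoff optimization maximizes sensitivity first", {
  # enumeration oracle: the largest threshold with training sensitivity 1
  enum_best <- function(pos, neg) {
    cand <- sort(unique(c(pos, neg)))
    max(cand[vapply(cand, function(c) all(pos >= c), logical(1))])
  }
  pos <- c(0.5, 0.8); neg <- c(-0.7, -0.2)
  expect_identical(optimize_cutoff(pos, neg), enum_best(pos, neg))
  expect_identical(optimize_cutoff(pos, neg), 0.5)
  expect_true(all(neg < 0.5)) # specificity 1 here

  # fully overlapping groups: sensitivity still 1, specificity may drop to 0
  pos2 <- c(-1, 0, 1); neg2 <- c(-0.5, 0.5, 2)
  cut2 <- optimize_cutoff(pos2, neg2)
  expect_identical(cut2, enum_best(pos2, neg2))
  expect_true(all(pos2 >= cut2))

  expect_identical(optimize_cutoff(0.3, c(-1, 2)), 0.3)
  expect_error(optimize_cutoff(numeric(), 1), "nonempty")
})

test_that("full derivation excludes CD8A and stays within planted programs", {
  fit <- small_model()
  model <- fit$fit$model
  sim <- fit$sim
  expect_false("CD8A" %in% model$tme1$genes)
  expect_gt(length(model$tme1$genes), 0)
  expect_gt(length(model$tme2$genes), 0)

  # with top_k kept below the number of truly differential genes, every
  # per-round top set consists of planted genes only, so the selected
  # infiltration signature stays inside the planted programs (the nested
  # exhaustion program is differential for this contrast too)
  clean <- simulate_cohort(sim_config(
    n_msi = 80, n_mss = 120, n_genes = 300,
    n_infiltration_genes = 15, n_exhaustion_genes = 15,
    effect_size_infiltration = 4, effect_size_exhaustion = 4, seed = 37
  ))
  clean_fit <- build_tmepre(
    clean$expr, clean$annotations,
    params_tme1 = stability_params(n_rounds = 50, n_folds = 5, top_k = 20, seed = 371),
    params_tme2 = stability_params(n_rounds = 50, n_folds = 5, top_k = 20, seed = 372)
  )
  planted <- c(
    clean$truth$infiltration_genes, clean$truth$exhaustion_genes,
    clean$truth$marker_genes
  )
  expect_true(all(clean_fit$model$tme1$genes %in% setdiff(planted, "CD8A")))

  # training cutoffs classify every training-positive sample positive
  sc <- score_samples(model, sim$expr)
  inf_pos <- fit$fit$infiltration$groups$sample_id[fit$fit$infiltration$groups$label == "POS"]
  expect_true(all(sc$tme1_score[match(inf_pos, sc$sample_id)] >= model$tme1$cutoff))
})
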