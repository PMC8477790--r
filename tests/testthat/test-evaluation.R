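test_that("log-rank test matches the hand-computed hypergeometric oracle", {
  times <- c(1, 2, 3, 4)
  events <- c(TRUE, TRUE, TRUE, TRUE)
  groups <- c("A", "A", "B", "B")
  got <- logrank_test(times, events, groups, worse = "A")
  expect_equal(got$statistic, oracle_logrank_chisq(times, events, groups), tolerance = 1e-10)
  expect_equal(got$p_two_sided, pchisq(got$statistic, 1, lower.tail = FALSE), tolerance = 1e-12)

  set.seed(51)
  t2 <- rexp(30); e2 <- runif(30) < 0.8; g2 <- rep(c("A", "B"), 15)
  got2 <- logrank_test(t2, e2, g2)
  expect_equal(got2$statistic, oracle_logrank_chisq(t2, e2, g2), tolerance = 1e-8)

  # identical groups: statistic 0, p 1
  ti <- c(1, 2, 3, 1, 2, 3)
  gi <- rep(c("A", "B"), each = 3)
  same <- logrank_test(ti, rep(TRUE, 6), gi)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_two_sided, 1, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(TRUE, TRUE), c("A", "A")), "two groups")
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c("A", "B")), "no events")
})

test_that("one-sided log-rank p is oriented toward the worse group", {
  set.seed(52)
  times <- c(rexp(25, 3), rexp(25, 1)) # group W dies faster
  events <- rep(TRUE, 50)
  groups <- rep(c("W", "V"), each = 25)
  res <- logrank_test(times, events, groups, worse = "W")
  expect_lt(res$p_one_sided, 0.5)
  expect_equal(res$p_one_sided, res$p_two_sided / 2, tolerance = 1e-12)
  flipped <- logrank_test(times, events, groups, worse = "V")
  expect_gt(flipped$p_one_sided, 0.5)
  expect_equal(flipped$p_one_sided + res$p_one_sided, 1, tolerance = 1e-12)
})

test_that("Cox fit matches grid maximization of the partial likelihood", {
  times <- c(1.1, 2.4, 3.0, 4.7, 5.2, 6.9)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  x <- c(1, 0, 1, 0, 1, 0)
  got <- cox_hr(times, events, factor(c("a", "b")[x + 1], levels = c("a", "b")))
  expect_equal(got$beta, oracle_cox_beta(times, events, x), tolerance = 1e-4)
  expect_equal(got$hazard_ratio, exp(got$beta), tolerance = 1e-12)
  expect_false(got$infinite)

  set.seed(53)
  t2 <- rexp(20) * exp(-0.8 * rep(0:1, 10))
  e2 <- rep(TRUE, 20)
  x2 <- rep(0:1, 10)
  got2 <- cox_hr(t2, e2, factor(c("lo", "hi")[x2 + 1], levels = c("lo", "hi")))
  expect_equal(got2$beta, oracle_cox_beta(t2, e2, x2), tolerance = 1e-4)
})

test_that("Cox and log-rank agree in direction; separation flags infinite HR", {
  set.seed(54)
  for (s in 1:5) {
    times <- rexp(40, rate = exp(0.7 * rep(0:1, 20)))
    events <- runif(40) < 0.85
    if (sum(events) == 0) next
    g <- factor(rep(c("ref", "idx"), 20), levels = c("ref", "idx"))
    cx <- cox_hr(times, events, g)
    lr <- logrank_test(times, events, g, worse = "idx")
    expect_identical(cx$beta > 0, lr$obs_worse > lr$exp_worse)
  }

  # complete separation: all indexed-group events precede the others
  times <- c(1, 2, 3, 10, 11, 12)
  events <- rep(TRUE, 6)
  g <- factor(rep(c("idx", "ref"), each = 3), levels = c("ref", "idx"))
  sep <- cox_hr(times, events, g)
  expect_true(sep$infinite)
})

test_that("Stouffer combination matches closed-form arithmetic and is monotone", {
  expect_equal(stouffer_combine(0.5), 0.5, tolerance = 1e-12)
  expect_equal(
    stouffer_combine(c(0.025, 0.025)),
    1 - pnorm(2 * qnorm(0.975) / sqrt(2)),
    tolerance = 1e-12
  )
  # symmetric in its arguments
  expect_identical(
    stouffer_combine(c(0.01, 0.2, 0.6)),
    stouffer_combine(c(0.6, 0.01, 0.2))
  )
  # monotone increasing in each argument
  base <- c(0.05, 0.2, 0.4)
  for (i in 1:3) {
    bumped <- base
    bumped[i] <- bumped[i] + 0.1
    expect_gt(stouffer_combine(bumped), stouffer_combine(base))
  }
  expect_error(stouffer_combine(c(0.5, 1)), "strictly inside")
  expect_error(stouffer_combine(numeric()), "at least one")
})

test_that("score correlations are exact for affine pairs and error on zero variance", {
  set.seed(55)
  a <- rnorm(60)
  strata <- rep(c("MSI", "MSS"), 30)
  res <- correlate_scores(a, 2 * a + 1, strata)
  expect_equal(res$r, rep(1, 3), tolerance = 1e-12)
  expect_setequal(res$stratum, c("overall", "MSI", "MSS"))

  ok <- vapply(1:60, function(s) {
    set.seed(s)
    abs(correlate_scores(rnorm(400), rnorm(400))$r) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  expect_error(correlate_scores(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("cohort summary reproduces printed percentage arithmetic", {
  mk <- function(prefix, n_resp, n_insuf, n_exh, msi) {
    n <- n_resp + n_insuf + n_exh
    tibble::tibble(
      sample_id = sprintf("%s%03d", prefix, seq_len(n)),
      predicted = rep(c("responder", "nonresponder"), c(n_resp, n_insuf + n_exh)),
      mechanism = rep(
        c("none", "insufficient_infiltration", "terminal_exhaustion"),
        c(n_resp, n_insuf, n_exh)
      ),
      msi_status = msi
    )
  }
  pred <- dplyr::bind_rows(
    mk("mss", 30, 246, 8, "MSS"),
    mk("msi", 88, 21, 22, "MSI")
  )
  ann <- tibble::tibble(sample_id = pred$sample_id, msi_status = pred$msi_status)
  s <- summarize_cohort(dplyr::select(pred, -"msi_status"), ann)

  mss <- s[s$msi_status == "MSS", ]
  expect_identical(mss$n, 284L)
  expect_identical(mss$pct_responder, 10.6)
  expect_identical(mss$pct_insufficient_infiltration, 86.6)
  expect_identical(mss$pct_terminal_exhaustion, 2.8)

  msi <- s[s$msi_status == "MSI", ]
  expect_identical(msi$n, 131L)
  expect_identical(msi$pct_responder, 67.2)
  expect_identical(msi$pct_insufficient_infiltration, 16.0)
  expect_identical(msi$pct_terminal_exhaustion, 16.8)

  # a stratum without predictions is omitted with a notice
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(sample_id = "x1", msi_status = "MSI-L"))
  expect_message(s2 <- summarize_cohort(dplyr::select(pred, -"msi_status"), ann2), "MSI-L")
  expect_false("MSI-L" %in% s2$msi_status)
})

test_that("survival read-out bundles coherent statistics and tidy KM curves", {
  set.seed(56)
  pred <- tibble::tibble(
    sample_id = sprintf("p%03d", 1:80),
    predicted = rep(c("responder", "nonresponder"), each = 40),
    mechanism = rep(c("none", "insufficient_infiltration"), each = 40)
  )
  ann <- tibble::tibble(
    sample_id = pred$sample_id, msi_status = "MSI",
    surv_time = rexp(80, rate = ifelse(pred$predicted == "nonresponder", 3, 1)),
    surv_event = TRUE
  )
  sr <- survival_readout(pred, ann)
  gl <- glance(sr)
  expect_gt(gl$hazard_ratio, 1)
  expect_lt(gl$p_one_sided, 0.5)
  km <- tidy(sr)
  expect_setequal(unique(km$group), c("responder", "nonresponder"))
  # survival curves start at 1 and never increase
  for (g in unique(km$group)) {
    s <- km$survival[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
  expect_s3_class(autoplot(sr), "ggplot")
})
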