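test_that("product-limit estimator reproduces hand-computed curves", {
  # all censored: S stays 1
  k0 <- km_estimate(c(5, 10, 20), c(0, 0, 0))
  expect_equal(km_surv(k0, c(1, 15, 100)), c(1, 1, 1))

  # n = 2: death at 10, censored at 20
  k1 <- km_estimate(c(10, 20), c(1, 0))
  expect_equal(km_surv(k1, 10), 0.5)
  expect_equal(km_surv(k1, 9), 1)

  # n = 4: deaths at 5 and 15, censored at 10; risk set shrinks 4 -> 2
  k2 <- km_estimate(c(5, 10, 15, 20), c(1, 0, 1, 0))
  expect_equal(km_surv(k2, 5), 0.75)
  expect_equal(km_surv(k2, 15), 0.375)
  expect_equal(k2$n_risk, c(4, 2))

  expect_error(km_estimate(c(0, 5), c(1, 1)), "positive")
})

test_that("with no censoring the KM curve is the empirical survival function", {
  set.seed(801)
  t <- sample(1:50, 20, replace = TRUE)
  k <- km_estimate(t, rep(1, 20))
  for (x in c(1, 5, 17, 50)) {
    expect_equal(km_surv(k, x), mean(t > x))
  }
})

test_that("KM matches the survival package on random censored tables", {
  skip_if_not_installed("survival")
  set.seed(802)
  for (r in 1:50) {
    n <- sample(5:40, 1)
    t <- sample(1:30, n, replace = TRUE)
    e <- stats::rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    mine <- km_estimate(t, e)
    fit <- survival::survfit(survival::Surv(t, e) ~ 1)
    idx <- fit$n.event > 0
    expect_equal(mine$time, fit$time[idx], tolerance = 1e-9)
    expect_equal(mine$surv, fit$surv[idx], tolerance = 1e-9)
  }
})

test_that("the analysis horizon censors late follow-up", {
  k <- km_estimate(c(100, 2000, 2500), c(1, 1, 1), horizon = 1825)
  expect_equal(k$time, 100)          # post-horizon deaths become censorings
  expect_equal(km_surv(k, 1825), 2/3)
})

test_that("log-rank test: null identity, hand value, symmetry, power", {
  # identical groups: statistic ~ 0, p ~ 1
  t <- c(5, 8, 12, 20); e <- c(1, 1, 0, 1)
  lr0 <- logrank_test(t, e, t, e)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # toy 6-patient table: all group-1 deaths precede group-2 deaths;
  # hand computation of the O-E and hypergeometric variance terms:
  # times 1..6, at time k the risk set has 7-k subjects, E1 accumulates
  # n1/(n), V accumulates n1*n2/n^2
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 1))
  n1 <- c(3, 2, 1, 0, 0, 0); n <- 6:1
  E1 <- sum(n1 / n)
  V <- sum(n1 * (n - n1) / n^2)
  expect_equal(lr$observed, 3)
  expect_equal(lr$expected, E1, tolerance = 1e-12)
  expect_equal(lr$statistic, (3 - E1)^2 / V, tolerance = 1e-12)

  # group swap leaves the statistic unchanged
  set.seed(803)
  t1 <- stats::rexp(30, 1 / 100); t2 <- stats::rexp(30, 1 / 50)
  e1 <- stats::rbinom(30, 1, 0.8); e2 <- stats::rbinom(30, 1, 0.8)
  a <- logrank_test(t1, e1, t2, e2)
  b <- logrank_test(t2, e2, t1, e1)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  expect_error(logrank_test(t1, rep(0, 30), t2, rep(0, 30)), "zero events")
})

test_that("log-rank agrees with the survival package and detects HR = 3", {
  skip_if_not_installed("survival")
  set.seed(804)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    t1 <- stats::rexp(n, 1 / 300); t2 <- stats::rexp(n, 1 / 150)
    e1 <- stats::rbinom(n, 1, 0.8); e2 <- stats::rbinom(n, 1, 0.8)
    if (sum(e1) + sum(e2) == 0) next
    mine <- logrank_test(t1, e1, t2, e2)
    sd <- survival::survdiff(
      survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(n, n)))
    expect_equal(mine$statistic, sd$chisq, tolerance = 1e-8)
  }

  # planted exponential HR = 3 with 85 per arm: p < 0.01 in >= 90% of runs
  set.seed(805)
  sig <- replicate(200, {
    tA <- stats::rexp(85, log(2) / 900)
    tB <- stats::rexp(85, 3 * log(2) / 900)
    eA <- stats::rbinom(85, 1, 0.85); eB <- stats::rbinom(85, 1, 0.85)
    logrank_test(tA, eA, tB, eB)$p_value < 0.01
  })
  expect_gte(mean(sig), 0.90)
})

test_that("expression stratification: median rule, scan rule, degenerate input", {
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:10),
                       time_days = c(900, 800, 700, 850, 950,
                                     200, 150, 300, 250, 100),
                       event = rep(1, 10),
                       gX = 1:10, check.names = FALSE)
  st <- stratify_by_expression(cohort, "gX", rule = "median")
  expect_equal(sum(st$high), 5)
  expect_equal(sum(st$low), 5)

  st2 <- stratify_by_expression(cohort, "gX", rule = "scan")
  expect_equal(st2$n_cutoffs_tried, 13)
  # patients 6..10 (high expression) die early: scan should split there
  expect_true(all(which(st2$high) %in% 6:10))

  cohort$gY <- 5
  expect_error(stratify_by_expression(cohort, "gY"), "cannot stratify")
})

test_that("survival screen ranks the planted prognostic gene first", {
  set.seed(806)
  n <- 170
  genes <- c("PROG", sprintf("NULL%02d", 1:20))
  expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, NULL))
  high <- expr["PROG", ] > stats::median(expr["PROG", ])
  rate <- log(2) / 900 * ifelse(high, 3, 1)
  tdays <- pmax(1, round(stats::rexp(n, rate)))
  cohort <- data.frame(patient_id = sprintf("p%03d", 1:n),
                       time_days = tdays,
                       event = stats::rbinom(n, 1, 0.85))
  cohort <- cbind(cohort, as.data.frame(t(expr)))
  de <- data.frame(gene_id = genes, direction = "up",
                   stringsAsFactors = FALSE)
  out <- survival_screen(de, cohort)
  expect_equal(out$gene_id[1], "PROG")
  expect_true(all(c("p_scan_adjusted", "n_cutoffs_tried") %in% names(out)))
  # scan disclosure: adjusted p never below the nominal p
  expect_true(all(out$p_scan_adjusted >= out$p_value - 1e-15))

  # the scan's groups recover the planted assignment for >= 90% of patients
  st <- stratify_by_expression(cohort, "PROG", rule = "scan", horizon = 1825)
  expect_gte(mean(st$high == high), 0.90)

  # empty DE list: empty table
  empty <- survival_screen(de[0, ], cohort)
  expect_equal(nrow(empty), 0)
})

test_that("scanned minimum p-values are anti-conservative on a null cohort", {
  set.seed(807)
  n <- 120
  genes <- sprintf("N%02d", 1:30)
  expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, NULL))
  cohort <- data.frame(patient_id = sprintf("p%03d", 1:n),
                       time_days = pmax(1, round(stats::rexp(n, log(2) / 900))),
                       event = stats::rbinom(n, 1, 0.85))
  cohort <- cbind(cohort, as.data.frame(t(expr)))
  de <- data.frame(gene_id = genes, direction = "down",
                   stringsAsFactors = FALSE)
  out <- survival_screen(de, cohort)
  # no signal, yet scanning 13 cutoffs inflates the small-p fraction well
  # above the nominal 5%; the disclosure fields must be present on every row
  expect_gt(mean(out$p_value < 0.05), 0.05)
  expect_true(all(out$n_cutoffs_tried == 13))
})
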