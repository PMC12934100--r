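test_that("product-limit estimator matches hand-computed curves", {
  # two subjects, events at 1 and 2: S = 0.5 after t=1, 0 after t=2
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$n_risk, c(2, 1))
  expect_equal(km$survival, c(0.5, 0))

  # all censored: curve stays at 1 (no event rows)
  kmc <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_equal(nrow(kmc), 0)

  # single subject with an event at 5: step from 1 to 0
  km1 <- km_estimate(5, 1)
  expect_equal(km1$survival, 0)
  expect_equal(km1$time, 5)

  # censored subjects at an event time stay at risk for that event
  kmt <- km_estimate(c(2, 2, 4), c(1, 0, 1))
  expect_equal(kmt$n_risk, c(3, 1))
  expect_equal(kmt$survival, c(2 / 3, 0))

  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(41)
  time <- rexp(40, 0.1)
  km <- km_estimate(time, rep(1, 40))
  for (j in seq_len(nrow(km)))
    expect_equal(km$survival[j], mean(time > km$time[j]))
})

test_that("KM matches survfit on censored data", {
  skip_if_not_installed("survival")
  set.seed(15)
  time <- round(rexp(60, 0.08), 1)
  event <- rbinom(60, 1, 0.7)
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  idx <- match(km$time, sf$time)
  expect_equal(km$survival, sf$surv[idx], tolerance = 1e-12)
  expect_equal(km$n_risk, sf$n.risk[idx])
})

test_that("log-rank statistic reproduces the hand-computed O/E/V table", {
  # group A events at 1,2; group B events at 3,4; no censoring.
  # Risk sets: t=1 (4 at risk, 2 A), t=2 (3, 1 A), t=3 (2, 0 A), t=4 (1, 0 A)
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  # statistic = (7/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_equal(unname(lr$observed), c(2, 2))
  expect_equal(unname(lr$expected), c(5 / 6, 4 - 5 / 6), tolerance = 1e-12)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))

  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(rep(c(1, 3, 7), 2), rep(1, 6),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)

  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)), "two groups")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("A", "B"), 2)),
               "at least one event")
})

test_that("log-rank is scale-invariant, label-symmetric, and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(27)
  for (i in 1:10) {
    n <- 30
    time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.8)
    group <- sample(rep(c("a", "b"), n / 2))
    if (sum(event) == 0) event[1] <- 1
    lr <- logrank_test(time, event, group)
    expect_equal(logrank_test(time * 7.3, event, group)$statistic,
                 lr$statistic, tolerance = 1e-12)
    relabeled <- ifelse(group == "a", "z", "y")
    expect_equal(logrank_test(time, event, relabeled)$statistic,
                 lr$statistic, tolerance = 1e-12)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-9)
  }
})

test_that("log-rank has high power at a strong hazard ratio", {
  rejected <- 0
  for (s in 1:50) {
    cfg <- sim_config(seed = s, n_dormant = 50, n_proliferative = 50,
                      hazard_ratio = 3, censor_rate = 0.2)
    ph <- setNames(rep(c("dormant", "proliferative"), each = 50),
                   sprintf("S%03d", 1:100))
    clin <- simulate_clinical(cfg, ph)
    rejected <- rejected +
      (logrank_test(clin$time, clin$event, clin$phenotype)$p < 0.05)
  }
  expect_gte(rejected / 50, 0.9)
})

test_that("chi-square matches closed forms and the 2x2 z-test identity", {
  expect_equal(response_chisq(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(response_chisq(matrix(c(5, 5, 5, 5), 2))$p, 1)
  res <- response_chisq(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  set.seed(53)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    r <- response_chisq(tab)
    expect_gte(r$statistic, 0)
    # permutation invariance
    expect_equal(response_chisq(tab[2:1, 2:1])$statistic, r$statistic)
    # squared two-proportion z-test equals the 2x2 chi-square
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
    p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
    pp <- (tab[1, 1] + tab[2, 1]) / (n1 + n2)
    zstat <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(r$statistic, zstat^2, tolerance = 1e-9)
  }
  expect_error(response_chisq(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(response_chisq(matrix(1:3, 1)), "2x2")
})

test_that("dormant samples respond less often in the simulated cohort", {
  cfg <- sim_config(seed = 99, n_dormant = 60, n_proliferative = 60,
                    censor_rate = 0)
  ph <- setNames(rep(c("dormant", "proliferative"), each = 60),
                 sprintf("S%03d", 1:120))
  clin <- simulate_clinical(cfg, ph)
  tab <- response_table(clin$phenotype, clin$response)
  rate_d <- tab["dormant", "responder"] / sum(tab["dormant", ])
  rate_p <- tab["proliferative", "responder"] / sum(tab["proliferative", ])
  expect_lt(rate_d, rate_p)
})
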