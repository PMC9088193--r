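test_that("Kaplan-Meier matches the empirical survival function and hand product-limit", {
  # no censoring: KM = empirical survival
  km <- km_estimate(make_surv(1:4, rep(1, 4)))
  expect_equal(km$all$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$all$median, 2)

  # all censored: curve constant 1, median undefined
  km0 <- km_estimate(make_surv(c(3, 8, 12, 20, 40), rep(0, 5)))
  expect_equal(nrow(km0$all$curve), 0)
  expect_equal(km_survival_at(km0$all, c(1, 10, 100)), c(1, 1, 1))
  expect_true(is.na(km0$all$median))

  # hand product-limit with censoring: deaths at 2 and 5, censored at 3
  km2 <- km_estimate(make_surv(c(2, 3, 5), c(1, 0, 1)))
  expect_equal(km2$all$curve$surv, c(1 - 1/3, (1 - 1/3) * (1 - 1/1)))
  expect_equal(km_survival_at(km2$all, 4), 2/3)

  expect_error(km_estimate(make_surv(1, 1)[0, ]), "empty")
})

test_that("log-rank test agrees with a direct risk-set oracle and a permutation test", {
  # identical survival in both groups: statistic 0, p = 1
  s <- make_surv(c(1, 3, 7, 1, 3, 7), c(1, 0, 1, 1, 0, 1))
  lr0 <- log_rank_test(s, rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)

  # fully separated groups: statistic equals the oracle, p < 0.05, and the
  # observed assignment is the most extreme of all 20 label permutations
  time <- c(1, 2, 3, 10, 11, 12); event <- rep(1, 6)
  g <- c(1, 1, 1, 0, 0, 0)
  s2 <- make_surv(time, event)
  lr <- log_rank_test(s2, g)
  expect_equal(lr$statistic, oracle_logrank2(time, event, g), tolerance = 1e-12)
  expect_lt(lr$p, 0.05)
  combos <- utils::combn(6, 3)
  perm_stats <- apply(combos, 2, function(idx) {
    gp <- rep(0, 6); gp[idx] <- 1
    oracle_logrank2(time, event, gp)
  })
  expect_equal(max(perm_stats), lr$statistic, tolerance = 1e-12)
  expect_lte(mean(perm_stats >= lr$statistic - 1e-9), 0.1)

  # one group fully censored, the other with events: finite, p in (0, 1]
  s3 <- make_surv(c(5, 6, 7, 8, 2, 3), c(0, 0, 0, 0, 1, 1))
  lr3 <- log_rank_test(s3, c(1, 1, 1, 1, 2, 2))
  expect_true(is.finite(lr3$statistic))
  expect_true(lr3$p > 0 && lr3$p <= 1)

  expect_error(log_rank_test(s2, rep("a", 6)), "2 groups")
  expect_equal(log_rank_test(make_surv(1:4, rep(0, 4)), c(1, 1, 2, 2))$p, 1)
})

test_that("cox_fit maximizes the Efron partial likelihood and enforces its contracts", {
  set.seed(11)
  time <- c(3, 5, 7, 10, 14, 19, 23, 31, 40, 55)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 0, 0, 1)
  s <- make_surv(time, event)
  fit <- cox_fit(matrix(x, ncol = 1), s)
  beta_hat <- stats::optimize(function(b) oracle_efron_loglik(b, time, event, x),
                              c(-5, 5), maximum = TRUE, tol = 1e-12)$maximum
  expect_equal(unname(fit$coefficients[1]), beta_hat, tolerance = 1e-6)

  # definitional identities on a random multivariate fit
  xm <- cbind(a = rnorm(30), b = rbinom(30, 1, 0.5))
  s30 <- make_surv(rexp(30, 1/20) + 0.5, rbinom(30, 1, 0.7))
  f2 <- cox_fit(xm, s30)
  expect_equal(f2$hazard_ratios, exp(f2$coefficients))
  expect_true(all(f2$ci_lower <= f2$hazard_ratios & f2$hazard_ratios <= f2$ci_upper))

  # zero-variance covariate: error by contract, null effect on request
  x0 <- matrix(0, nrow = 10, ncol = 1, dimnames = list(NULL, "flat"))
  expect_error(cox_fit(x0, s), "flat")
  expect_warning(f0 <- cox_fit(x0, s, on_constant = "zero"), "flat")
  expect_equal(unname(f0$coefficients[1]), 0)
  expect_equal(unname(f0$hazard_ratios[1]), 1)

  # perfect separation: flagged and capped
  xs <- c(rep(1, 5), rep(0, 5))   # all early deaths in group 1
  ss <- make_surv(c(1:5, 50:54), c(rep(1, 5), rep(0, 5)))
  w <- capture_warnings(fs <- cox_fit(matrix(xs, ncol = 1), ss))
  expect_true(any(grepl("separation|capped", w)))
  expect_true(fs$separation[1])
  expect_lte(abs(fs$coefficients[1]), 15)

  expect_error(cox_fit(matrix(c(NA, rnorm(9)), ncol = 1), s), "missing")
  expect_error(cox_fit(matrix(rnorm(4), ncol = 1),
                       make_surv(1:4, c(1, 0, 0, 0))), "2 events")
})

test_that("concordance index matches exhaustive pair enumeration and is symmetric", {
  # risk = reversed time rank, no censoring: perfect concordance
  time <- c(5, 1, 9, 3, 7)
  s <- make_surv(time, rep(1, 5))
  expect_equal(concordance_index(-time, s)$c_index, 1)
  # constant risk: all ties
  expect_equal(concordance_index(rep(2, 5), s)$c_index, 0.5)

  # censored fixture vs brute force
  ev <- c(1, 1, 0, 1, 1)
  risk <- c(0.3, 2.1, 1.0, -0.5, 0.9)
  sc <- make_surv(time, ev)
  expect_equal(concordance_index(risk, sc)$c_index,
               oracle_cindex(risk, time, ev))
  # complementarity without risk ties
  expect_equal(concordance_index(risk, sc)$c_index +
                 concordance_index(-risk, sc)$c_index, 1)

  # seeded bootstrap is reproducible
  b1 <- concordance_index(risk, sc, bootstrap_B = 50, seed = 3)
  b2 <- concordance_index(risk, sc, bootstrap_B = 50, seed = 3)
  expect_equal(b1$bootstrap_values, b2$bootstrap_values)
  expect_true(is.finite(b1$bootstrap_mean) && b1$bootstrap_sd >= 0)
})

test_that("calibration table bins by prediction and reports KM at the horizon", {
  set.seed(21)
  s <- make_surv(rexp(40, 1/30) + 1, rbinom(40, 1, 0.8))
  # identical predictions, one group: mean predicted vs overall KM
  ct <- calibration_table(rep(0.7, 40), s, horizon = 20, n_groups = 1)
  km <- km_estimate(s)
  expect_equal(ct$mean_predicted, 0.7)
  expect_equal(ct$km_observed, km_survival_at(km$all, 20))

  # event-free bin observed at 1
  s2 <- make_surv(rep(50, 10), rep(0, 10))
  ct2 <- calibration_table(rep(1, 10), s2, horizon = 20, n_groups = 1)
  expect_equal(ct2$km_observed, 1)

  # horizon beyond the bin's follow-up: undefined
  ct3 <- calibration_table(rep(0.5, 10), s2, horizon = 100, n_groups = 1)
  expect_true(is.na(ct3$km_observed))

  # bins are equal-size and ordered by prediction
  ct4 <- calibration_table(seq(0, 1, length.out = 40), s, horizon = 20,
                           n_groups = 4)
  expect_equal(ct4$n, rep(10, 4))
  expect_true(all(diff(ct4$mean_predicted) > 0))
  expect_error(calibration_table(rep(1.2, 40), s, 20), "probabilities")
})
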