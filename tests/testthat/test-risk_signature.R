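# small training instance with 3 informative pairs used by several blocks
make_signature_fixture <- function(seed = 17, n = 150,
                                   betas = c(1.5, -1.2, 1.0)) {
  set.seed(seed)
  z <- matrix(rbinom(3 * n, 1, 0.5), nrow = 3,
              dimnames = list(c("A|B", "C|D", "E|F"), sprintf("s%03d", 1:n)))
  lp <- drop(crossprod(z, betas))
  surv <- sim_weibull_surv(lp)
  surv$sample_id <- colnames(z)
  igp <- structure(list(pairs = data.frame(gene_a = c("A", "C", "E"),
                                           gene_b = c("B", "D", "F")),
                        sample_ids = colnames(z), scores = z),
                   class = "igp_matrix")
  list(igp = igp, surv = surv)
}

test_that("the penalized fit approaches the unpenalized Cox solution as lambda -> 0", {
  fx <- make_signature_fixture(n = 60, betas = c(0.9, -0.8, 0.6))
  sig <- fit_signature(fx$igp, fx$surv, lambda = 1e-8)
  ref <- cox_fit(t(fx$igp$scores), fx$surv)
  expect_equal(nrow(sig$pairs), 3L)
  idx <- match(igpsurv:::pair_keys(sig$pairs), names(ref$coefficients))
  expect_equal(sig$betas, unname(ref$coefficients[idx]), tolerance = 1e-3)
})

test_that("full shrinkage raises the empty-signature error", {
  fx <- make_signature_fixture()
  expect_error(fit_signature(fx$igp, fx$surv, lambda = 50), "empty signature")
})

test_that("cross-validated fitting is seeded and reproducible", {
  fx <- make_signature_fixture()
  s1 <- fit_signature(fx$igp, fx$surv, cv_folds = 5, cv_repeats = 3, seed = 4,
                      lambda_rule = "min")
  s2 <- fit_signature(fx$igp, fx$surv, cv_folds = 5, cv_repeats = 3, seed = 4,
                      lambda_rule = "min")
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$betas, s2$betas)
  expect_identical(s1$cutoff, s2$cutoff)
  expect_true(all(s1$betas != 0))
  expect_equal(s1$cutoff, stats::median(s1$risk_training))
})

test_that("risk_score is the exact linear form over binary pair indicators", {
  model <- new_signature(data.frame(gene_a = c("A", "C"), gene_b = c("B", "D")),
                         betas = c(0.5, -0.3), cutoff = 0)
  mk <- function(s1, s2) structure(
    list(pairs = model$pairs, sample_ids = c("x", "y"),
         scores = matrix(c(s1, s2), nrow = 2,
                         dimnames = list(c("A|B", "C|D"), c("x", "y")))),
    class = "igp_matrix")
  igp <- mk(c(0L, 0L), c(1L, 1L))   # x: both 0; y: both 1
  rs <- risk_score(model, igp)
  expect_equal(unname(rs), c(0, 0.2))
  # missing pair: hard error, no imputation
  igp_missing <- structure(list(pairs = model$pairs[1, ], sample_ids = "x",
                                scores = matrix(1L, 1, 1,
                                                dimnames = list("A|B", "x"))),
                           class = "igp_matrix")
  expect_error(risk_score(model, igp_missing), "C\\|D")
})

test_that("median dichotomization sends cutoff ties to the low-risk group", {
  expect_equal(as.character(dichotomize(c(1, 1 + 1e-9, 0.5), cutoff = 1)),
               c("low", "high", "low"))
  # odd n with distinct scores: group sizes differ by at most 1
  sc <- c(3.2, 1.1, 5.4, 2.2, 4.1)
  g <- dichotomize(sc, stats::median(sc))
  expect_lte(abs(sum(g == "low") - sum(g == "high")), 1L)
  expect_error(dichotomize(1:3, NA), "finite")
})

test_that("LASSO selection recovers planted driver pairs among null candidates", {
  ok <- 0L
  for (r in 1:10) {
    set.seed(700 + r)
    n <- 400; p <- 100
    z <- matrix(rbinom(p * n, 1, 0.5), nrow = p)
    gam <- c(rep(1, 5), rep(0, p - 5))
    lp <- drop(crossprod(z, gam))
    surv <- sim_weibull_surv(lp)
    ga <- sprintf("A%03d", 1:p); gb <- sprintf("B%03d", 1:p)
    dimnames(z) <- list(paste(ga, gb, sep = "|"), surv$sample_id)
    igp <- structure(list(pairs = data.frame(gene_a = ga, gene_b = gb),
                          sample_ids = surv$sample_id, scores = z),
                     class = "igp_matrix")
    sig <- tryCatch(fit_signature(igp, surv, cv_folds = 5, cv_repeats = 2,
                                  seed = r),
                    error = function(e) NULL)
    if (is.null(sig)) next
    sel <- match(igpsurv:::pair_keys(sig$pairs), rownames(z))
    drivers <- sum(sel <= 5)
    false_sel <- sum(sel > 5)
    if (drivers >= 4 && false_sel <= 5) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("group hazard ratio near exp(2) is recovered by signature evaluation", {
  hits <- 0L
  model <- new_signature(data.frame(gene_a = "A", gene_b = "B"),
                         betas = 1, cutoff = 0.5)
  for (r in 1:50) {
    set.seed(800 + r)
    n <- 400
    z <- matrix(rbinom(n, 1, 0.5), nrow = 1)
    surv <- sim_weibull_surv(2 * drop(z))
    dimnames(z) <- list("A|B", surv$sample_id)
    igp <- structure(list(pairs = model$pairs, sample_ids = surv$sample_id,
                          scores = z), class = "igp_matrix")
    ev <- evaluate_signature(model, igp, surv)
    hr <- unname(ev$group_fit$hazard_ratios[1])
    if (hr >= 5.0 && hr <= 11.0) hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90% of seeds
})

test_that("validation cohorts are scored with the training cutoff unchanged", {
  fx <- make_signature_fixture()
  sig <- fit_signature(fx$igp, fx$surv, lambda = 0.01)
  # a validation cohort with shifted score distribution
  set.seed(52)
  zval <- matrix(rbinom(3 * 40, 1, 0.8), nrow = 3,
                 dimnames = list(rownames(fx$igp$scores), sprintf("v%02d", 1:40)))
  igp_val <- structure(list(pairs = fx$igp$pairs, sample_ids = colnames(zval),
                            scores = zval), class = "igp_matrix")
  surv_val <- sim_weibull_surv(rep(0, 40)); surv_val$sample_id <- colnames(zval)
  ev <- evaluate_signature(sig, igp_val, surv_val)
  expect_identical(ev$groups, dichotomize(risk_score(sig, igp_val), sig$cutoff))
})

test_that("a permuted signature keeps multivariate type-I error near nominal", {
  rej <- 0L
  for (r in 1:200) {
    set.seed(900 + r)
    n <- 100
    x <- cbind(risk = rnorm(n), age = rnorm(n, 50, 10))
    surv <- sim_weibull_surv(0.02 * x[, "age"] - 1)
    f <- cox_fit(x, surv)
    if (f$p_values[["risk"]] < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 200, 0.01)
  expect_lt(rej / 200, 0.10)
})
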