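test_that("vectorized screen statistics reproduce survdiff and coxph exactly", {
  set.seed(42)
  n <- 80
  time <- round(rexp(n, 1/40), 1) + 0.1      # rounding induces tied times
  event <- rbinom(n, 1, 0.6)
  scores <- matrix(rbinom(25 * n, 1, rep(runif(25, 0.2, 0.8), n)), nrow = 25)
  lr <- igpsurv:::logrank_binary_many(scores, time, event)
  cx <- igpsurv:::cox_binary_many(scores, time, event)
  for (i in seq_len(25)) {
    g <- scores[i, ]
    sd_ref <- survival::survdiff(survival::Surv(time, event) ~ g)
    cf_ref <- survival::coxph(survival::Surv(time, event) ~ g, ties = "efron")
    expect_equal(lr$statistic[i], unname(sd_ref$chisq), tolerance = 1e-9)
    expect_equal(cx$beta[i], unname(stats::coef(cf_ref)), tolerance = 1e-6)
    expect_equal(cx$se[i], unname(sqrt(stats::vcov(cf_ref)[1, 1])),
                 tolerance = 1e-6)
  }
})

test_that("screen_cohort flags planted pairs and skips constant ones", {
  cfg <- sim_config(n_cohorts = 1, n_samples = 200, n_genes = 6, n_planted = 1,
                    planted_gamma = 1, ordering_noise = 0, seed = 99)
  sim <- generate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  pairs <- enumerate_pairs(rownames(co$expression))
  igp <- binarize(co$expression, pairs)
  scr <- screen_cohort(igp, co$survival)
  planted_key <- paste(cfg$planted$gene_a, cfg$planted$gene_b, sep = "|")
  row <- scr[paste(scr$gene_a, scr$gene_b, sep = "|") == planted_key, ]
  expect_true(row$prognostic)
  expect_gt(row$hr, 1)

  # constant pair: score identical for all samples -> never prognostic
  const_igp <- structure(list(pairs = data.frame(gene_a = "A", gene_b = "B"),
                              sample_ids = co$survival$sample_id,
                              scores = matrix(1L, 1, 200)),
                         class = "igp_matrix")
  scr0 <- screen_cohort(const_igp, co$survival)
  expect_false(scr0$prognostic[1])

  expect_error(screen_cohort(igp, survival_data(co$survival$sample_id,
                                                co$survival$time,
                                                rep(0, 200))), "zero events")
})

test_that("planted hazard ratio of e is recovered with high power at n = 200", {
  hits <- 0L
  for (r in 1:100) {
    cfg <- sim_config(n_cohorts = 1, n_samples = 200, n_genes = 2,
                      n_planted = 1, planted_gamma = 1, ordering_noise = 0,
                      clinical_effects = c(grade = 0, codel_intact = 0),
                      seed = 5000 + r)
    sim <- generate_cohorts(cfg)
    co <- sim$cohorts[[1]]
    igp <- binarize(co$expression, cfg$planted[, 1:2])
    scr <- screen_cohort(igp, co$survival)
    if (scr$prognostic[1] && scr$hr[1] >= 2.0 && scr$hr[1] <= 3.7)
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("prognostic intersection requires every cohort", {
  f1 <- frag(c("A", "A", "B"), c("B", "C", "C"), hr = c(2, 2, 2),
             prognostic = c(TRUE, TRUE, TRUE))
  f2 <- frag(c("A", "A", "B"), c("B", "C", "C"), hr = c(2, 2, 2),
             prognostic = c(TRUE, FALSE, TRUE))
  f3 <- frag(c("A", "A", "B"), c("B", "C", "C"), hr = c(2, 2, 2),
             prognostic = c(TRUE, TRUE, FALSE))
  inter <- intersect_prognostic(list(f1, f2, f3))
  expect_equal(inter, data.frame(gene_a = "A", gene_b = "B"))
})

test_that("controversial pairs are those whose per-cohort HRs straddle 1", {
  pairs <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"))
  frags <- list(frag(c("A", "A"), c("B", "C"), hr = c(1.8, 1.8)),
                frag(c("A", "A"), c("B", "C"), hr = c(2.2, 0.6)),
                frag(c("A", "A"), c("B", "C"), hr = c(1.5, 1.5)))
  rc <- remove_controversial(pairs, frags)
  expect_equal(rc$kept$gene_b, "B")
  expect_equal(rc$kept$consensus_direction, "unfavorable")
  expect_equal(rc$removed$gene_b, "C")
  # all-favorable pair
  frags2 <- lapply(c(0.4, 0.7, 0.9), function(h) frag("A", "B", hr = h))
  rc2 <- remove_controversial(pairs[1, ], frags2)
  expect_equal(rc2$kept$consensus_direction, "favorable")
  # idempotence: re-applying to the survivors removes nothing
  rc3 <- remove_controversial(rc$kept[, 1:2], frags)
  expect_equal(nrow(rc3$removed), 0L)
  expect_equal(rc3$kept$consensus_direction, rc$kept$consensus_direction)
})

test_that("pair classification partitions UPPs and FPPs", {
  pairs <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                      consensus_direction = c("unfavorable", "favorable",
                                              "unfavorable"))
  cls <- classify_pairs(pairs)
  expect_equal(unname(cls$counts), c(2L, 1L, 3L))
  all_up <- pairs; all_up$consensus_direction <- "unfavorable"
  expect_equal(nrow(classify_pairs(all_up)$fpp), 0L)
  empty <- pairs[0, ]
  expect_equal(unname(classify_pairs(empty)$counts), c(0L, 0L, 0L))
})

test_that("gene roles follow the pair-direction voting rule", {
  # single UPP (A,B): A high is adverse -> A unfavorable, B favorable
  upp <- data.frame(gene_a = "A", gene_b = "B",
                    consensus_direction = "unfavorable")
  roles <- assign_gene_roles(upp)
  expect_equal(roles$role[roles$gene == "A"], "UG")
  expect_equal(roles$role[roles$gene == "B"], "FG")
  # gene_a of one UPP and one FPP: both votes -> TSG
  mixed <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                      consensus_direction = c("unfavorable", "favorable"))
  roles2 <- assign_gene_roles(mixed)
  expect_equal(roles2$role[roles2$gene == "A"], "TSG")

  # partition identity on random pair sets
  set.seed(8)
  for (r in 1:20) {
    g <- sprintf("G%02d", 1:15)
    pr <- enumerate_pairs(g)
    pr <- pr[sample(nrow(pr), 30), ]
    pr$consensus_direction <- sample(c("unfavorable", "favorable"), 30,
                                     replace = TRUE)
    rl <- assign_gene_roles(pr)
    expect_equal(nrow(rl), length(unique(c(pr$gene_a, pr$gene_b))))
    expect_equal(sum(rl$role == "FG") + sum(rl$role == "UG") +
                   sum(rl$role == "TSG"), nrow(rl))
    expect_true(all(rl$degree >= 1))
  }
})

test_that("pair network degrees count incident pairs and recover planted hubs", {
  pairs <- data.frame(gene_a = c("A", "A", "A"), gene_b = c("B", "C", "D"))
  net <- build_pair_network(pairs)
  expect_equal(net$degrees$degree[net$degrees$gene == "A"], 3L)
  expect_equal(sum(net$degrees$degree), 2L * nrow(pairs))

  # hub-planted generator: the hub gene has the top degree in the final pairs
  cfg <- sim_config(n_cohorts = 2, n_samples = 250, n_genes = 20, n_planted = 0,
                    hubs = data.frame(n_partners = 6, gamma = 1.2),
                    ordering_noise = 0, seed = 77)
  sim <- generate_cohorts(cfg)
  pairs_all <- enumerate_pairs(rownames(sim$cohorts[[1]]$expression))
  frags <- lapply(sim$cohorts, function(co)
    screen_cohort(binarize(co$expression, pairs_all), co$survival))
  inter <- intersect_prognostic(frags)
  final <- remove_controversial(inter, frags)$kept
  net2 <- build_pair_network(final)
  expect_equal(net2$degrees$gene[1], cfg$hubs[[1]]$gene)
})
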