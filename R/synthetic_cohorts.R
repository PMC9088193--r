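#' Configuration for the synthetic multi-cohort generator
#'
#' Defines the ground-truth model the generator emulates: per-sample
#' latent pair-ordering indicators drive a Weibull proportional-hazards
#' survival model together with clinical covariates; each cohort sees the
#' same gene universe through its own strictly increasing platform
#' transform; censoring is independent uniform.
#'
#' Planted pairs occupy disjoint genes at the head of the universe
#' (G0001, G0002 for the first pair, and so on), followed by the genes of
#' any planted hubs; remaining genes are i.i.d. background.
#'
#' @param n_cohorts number of cohorts (>= 1).
#' @param n_samples samples per cohort (recycled to `n_cohorts`).
#' @param n_genes size of the shared gene universe.
#' @param n_planted number of planted prognostic pairs.
#' @param planted_gamma true log hazard ratios of the planted pair
#'   indicators (recycled to `n_planted`); default alternates +1/-1
#'   (unfavorable/favorable orderings of equal strength).
#' @param hubs optional data frame `n_partners`, `gamma`: each row plants
#'   a hub gene whose ordering state against all its partners is driven
#'   by one latent indicator with the given log-HR.
#' @param prevalence Bernoulli prevalence of each latent indicator.
#' @param clinical_effects named log-HRs `grade` (WHO III vs II) and
#'   `codel_intact` (1p/19q intact vs codeleted).
#' @param weibull_shape,weibull_scale baseline Weibull hazard (months);
#'   defaults give a baseline median survival of about 44 months,
#'   a lower-grade-glioma-like scale.
#' @param censoring uniform censoring window in months, `c(min, max)`.
#' @param ordering_noise probability (in \[0, 0.5)) that a planted
#'   ordering is flipped in a sample (platform/measurement noise).
#' @param platforms per-cohort strictly increasing transform tags among
#'   `"identity"`, `"log2"`, `"affine"`, `"rank_gauss"` (recycled).
#' @param latent_mode `"independent"` (default; each cohort is a distinct
#'   patient sample from the same population) or `"shared"` (one latent
#'   draw and one expression matrix viewed through different platform
#'   transforms — used for invariance checks).
#' @param seed master integer seed; all randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 3L, n_samples = 200L, n_genes = 60L,
                       n_planted = 10L,
                       planted_gamma = rep(c(1, -1), length.out = max(n_planted, 1L)),
                       hubs = NULL, prevalence = 0.5,
                       clinical_effects = c(grade = 0.7, codel_intact = 0.5),
                       weibull_shape = 1.2, weibull_scale = 60,
                       censoring = c(12, 120), ordering_noise = 0.05,
                       platforms = c("identity", "log2", "affine", "rank_gauss"),
                       latent_mode = c("independent", "shared"), seed = 1L) {
  latent_mode <- match.arg(latent_mode)
  stopifnot(n_cohorts >= 1L, n_genes >= 2L, weibull_shape > 0,
            weibull_scale > 0, length(censoring) == 2L,
            censoring[1] > 0, censoring[2] > censoring[1],
            ordering_noise >= 0, ordering_noise < 0.5,
            prevalence > 0, prevalence < 1)
  n_samples <- rep_len(as.integer(n_samples), n_cohorts)
  genes <- sprintf("G%04d", seq_len(n_genes))
  used <- 0L
  planted <- NULL
  if (n_planted > 0L) {
    gamma <- rep_len(planted_gamma, n_planted)
    if (2L * n_planted > n_genes) stop("sim_config: not enough genes for planted pairs")
    planted <- data.frame(gene_a = genes[2L * seq_len(n_planted) - 1L],
                          gene_b = genes[2L * seq_len(n_planted)],
                          gamma = gamma, stringsAsFactors = FALSE)
    used <- 2L * n_planted
  }
  hub_spec <- NULL
  if (!is.null(hubs)) {
    hub_spec <- lapply(seq_len(nrow(hubs)), function(i) {
      m <- as.integer(hubs$n_partners[i])
      idx <- used + seq_len(m + 1L)
      if (max(idx) > n_genes) stop("sim_config: not enough genes for hubs")
      used <<- used + m + 1L
      list(gene = genes[idx[1]], partners = genes[idx[-1]],
           gamma = hubs$gamma[i])
    })
  }
  structure(list(n_cohorts = n_cohorts, n_samples = n_samples,
                 n_genes = n_genes, genes = genes, planted = planted,
                 hubs = hub_spec, prevalence = prevalence,
                 clinical_effects = clinical_effects,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 censoring = censoring, ordering_noise = ordering_noise,
                 platforms = rep_len(platforms, n_cohorts),
                 latent_mode = latent_mode, seed = as.integer(seed)),
            class = "sim_config")
}

apply_platform <- function(x, tag, affine_a = 2.5, affine_b = 10) {
  out <- switch(tag,
                identity = x,
                log2 = log2(x + 1),
                affine = affine_a * x + affine_b,
                rank_gauss = apply(x, 2, function(col)
                  stats::qnorm((rank(col, ties.method = "average") - 0.5) /
                                 length(col))),
                stop("apply_platform: unknown platform tag ", tag))
  dimnames(out) <- dimnames(x)
  out
}

# draw latent indicators + clinical + survival for n samples
draw_latents <- function(config, n, ids) {
  K <- if (is.null(config$planted)) 0L else nrow(config$planted)
  H <- length(config$hubs)
  z <- matrix(stats::rbinom((K + H) * n, 1L, config$prevalence),
              nrow = K + H, ncol = n)
  rn <- character(0)
  if (K > 0L) rn <- paste(config$planted$gene_a, config$planted$gene_b, sep = "|")
  if (H > 0L) rn <- c(rn, paste0("hub:", vapply(config$hubs, `[[`, "", "gene")))
  rownames(z) <- rn
  colnames(z) <- ids
  grade <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "III", "II")
  codel <- ifelse(stats::rbinom(n, 1, 0.4) == 1, "codel", "intact")
  idh <- ifelse(stats::rbinom(n, 1, 0.8) == 1, "mutant", "wildtype")
  age <- round(pmin(pmax(stats::rnorm(n, 45, 12), 18), 85))
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male")
  gam <- c(if (K > 0L) config$planted$gamma else numeric(0),
           if (H > 0L) vapply(config$hubs, `[[`, 0, "gamma") else numeric(0))
  lp <- drop(crossprod(z, gam)) +
    config$clinical_effects[["grade"]] * (grade == "III") +
    config$clinical_effects[["codel_intact"]] * (codel == "intact")
  u <- stats::runif(n)
  t_event <- config$weibull_scale * (-log(u) * exp(-lp))^(1 / config$weibull_shape)
  cens <- stats::runif(n, config$censoring[1], config$censoring[2])
  time <- pmin(t_event, cens)
  event <- as.numeric(t_event <= cens)
  clinical <- data.frame(sample_id = ids, grade = grade, codel_1p19q = codel,
                         idh = idh, age = age, sex = sex,
                         stringsAsFactors = FALSE)
  list(z = z, lp = lp, clinical = clinical,
       surv = survival_data(ids, time, event))
}

# build an expression matrix consistent with latent indicators under the
# configured ordering noise; background is log-normal(3, 1)
draw_expression <- function(config, z, ids) {
  n <- length(ids)
  expr <- matrix(stats::rlnorm(config$n_genes * n, meanlog = 3, sdlog = 1),
                 nrow = config$n_genes, ncol = n,
                 dimnames = list(config$genes, ids))
  K <- if (is.null(config$planted)) 0L else nrow(config$planted)
  if (K > 0L) {
    for (k in seq_len(K)) {
      a <- config$planted$gene_a[k]; b <- config$planted$gene_b[k]
      flip <- stats::rbinom(n, 1L, config$ordering_noise)
      want <- xor(z[k, ] == 1L, flip == 1L)      # realized a > b ordering
      have <- expr[a, ] > expr[b, ]
      sw <- want != have
      tmp <- expr[a, sw]; expr[a, sw] <- expr[b, sw]; expr[b, sw] <- tmp
    }
  }
  for (h in seq_along(config$hubs)) {
    hub <- config$hubs[[h]]
    zh <- z[K + h, ]
    for (p in hub$partners) {
      flip <- stats::rbinom(n, 1L, config$ordering_noise)
      hub_higher <- xor(zh == 1L, flip == 1L)
      mult <- ifelse(hub_higher, stats::runif(n, 0.4, 0.9),
                     stats::runif(n, 1.1, 2.5))
      expr[p, ] <- expr[hub$gene, ] * mult
    }
  }
  expr
}

#' Generate synthetic multi-cohort expression, clinical and survival data
#'
#' For each sample, latent Bernoulli indicators of planted pair orderings
#' (and hub states) determine both the expression orderings (flipped with
#' probability `ordering_noise`) and, through a Weibull
#' proportional-hazards model with clinical effects, the survival time;
#' censoring is independent uniform. Each cohort's expression is passed
#' through its platform transform, which changes values but not
#' within-sample orderings.
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (per cohort: `expression`, `survival`,
#'   `clinical`), `ground_truth` (per cohort `z`, `lp`; plus `planted`,
#'   `hubs`, `weibull`, and `true_survival(t, lp)` = the closed-form
#'   generating survival function), and the `config`.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cohorts <- vector("list", config$n_cohorts)
  gt <- list(planted = config$planted, hubs = config$hubs,
             weibull = c(shape = config$weibull_shape,
                         scale = config$weibull_scale),
             per_cohort = vector("list", config$n_cohorts))
  shape <- config$weibull_shape; scale <- config$weibull_scale
  gt$true_survival <- function(t, lp) exp(-(t / scale)^shape * exp(lp))
  if (config$latent_mode == "shared") {
    n <- config$n_samples[1]
    ids <- sprintf("S%04d", seq_len(n))
    lat <- draw_latents(config, n, ids)
    expr0 <- draw_expression(config, lat$z, ids)
  }
  for (ci in seq_len(config$n_cohorts)) {
    if (config$latent_mode == "independent") {
      n <- config$n_samples[ci]
      ids <- sprintf("C%d_S%04d", ci, seq_len(n))
      lat <- draw_latents(config, n, ids)
      expr0 <- draw_expression(config, lat$z, ids)
    }
    cohorts[[ci]] <- list(
      expression = apply_platform(expr0, config$platforms[ci]),
      survival = lat$surv, clinical = lat$clinical)
    gt$per_cohort[[ci]] <- list(z = lat$z, lp = lat$lp)
  }
  names(cohorts) <- sprintf("cohort%d", seq_len(config$n_cohorts))
  names(gt$per_cohort) <- names(cohorts)
  list(cohorts = cohorts, ground_truth = gt, config = config)
}

#' Generate a small qPCR-like validation cohort
#'
#' Same latent survival model, with expression mapped to a bounded
#' positive 2^(-dCt)-like scale (per-sample scaling to a 0-16 range) and
#' quantized at a detection floor so that a configurable fraction of
#' values tie at the floor — emulating the heavy low-end ties of
#' qPCR-scale data. The untransformed parent cohort is returned alongside
#' for tie-effect audits.
#'
#' @param config a [sim_config()] (its first-cohort settings are used).
#' @param n samples in the cohort (default 36, a typical in-house
#'   validation series).
#' @param tie_rate target fraction of expression values tied at the
#'   detection floor (0 = none).
#' @return list with `expression`, `survival`, `clinical`,
#'   `tie_fraction` (realized), `floor` and `parent_expression`.
#' @export
make_qpcr_cohort <- function(config, n = 36L, tie_rate = 0.3) {
  stopifnot(inherits(config, "sim_config"), tie_rate >= 0, tie_rate <= 1)
  set.seed(config$seed + 104729L)   # distinct documented sub-stream
  ids <- sprintf("Q_S%04d", seq_len(n))
  lat <- draw_latents(config, n, ids)
  expr0 <- draw_expression(config, lat$z, ids)
  qx <- apply(expr0, 2, function(col) 16 * col / max(col))
  dimnames(qx) <- dimnames(expr0)
  floor_val <- 0
  if (tie_rate > 0) {
    floor_val <- stats::quantile(qx, tie_rate, names = FALSE)
    qx[qx < floor_val] <- floor_val
  }
  list(expression = qx, survival = lat$surv, clinical = lat$clinical,
       tie_fraction = mean(qx == floor_val) * (tie_rate > 0),
       floor = floor_val, parent_expression = expr0)
}
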