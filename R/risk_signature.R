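#' Fit the LASSO-Cox gene-pair signature
#'
#' L1-penalized Cox regression over the final prognostic pairs
#' ([glmnet::glmnet()] with `family = "cox"`), with the penalty chosen by
#' repeated k-fold cross-validation of the partial-likelihood deviance:
#' fold assignments are re-drawn `cv_repeats` times from the seed and the
#' CV curves averaged before applying the `lambda_rule` ("1se" = largest
#' lambda within one averaged standard error of the minimum; "min" =
#' minimizer). Pairs with nonzero coefficients at the chosen penalty form
#' the signature; the risk-score cutoff is the median training risk.
#'
#' @param igp an `igp_matrix` restricted to the final prognostic pairs
#'   (training cohort).
#' @param surv a [survival_data] table for the training cohort.
#' @param cv_folds folds per cross-validation (default 10).
#' @param cv_repeats number of fold re-assignments averaged (default 100).
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param seed integer seed for the fold assignments.
#' @param lambda optional fixed penalty; when supplied, cross-validation
#'   is skipped and the path coefficient at this lambda is used (a value
#'   near 0 approaches the unpenalized Cox fit).
#' @return An object of class `igp_signature`: list with `pairs`,
#'   `betas`, `lambda`, `lambda_rule`, `cv_folds`, `cv_repeats`, `seed`,
#'   `cutoff` and `risk_training` (per-sample training risk scores).
#' @export
fit_signature <- function(igp, surv, cv_folds = 10L, cv_repeats = 100L,
                          lambda_rule = c("1se", "min"), seed = 1L,
                          lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  surv <- as_survival_data(surv)
  shared <- intersect(igp$sample_ids, surv$sample_id)
  igp <- igp_samples(igp, shared)
  surv <- subset_surv(surv, shared)
  if (sum(surv$event) < 2) stop("fit_signature: need at least 2 events")
  if (nrow(igp$pairs) < 1L) stop("fit_signature: no candidate pairs")
  x <- t(igp$scores)
  storage.mode(x) <- "double"
  y <- survival::Surv(surv$time, surv$event)
  if (is.null(lambda)) {
    path <- glmnet::glmnet(x, y, family = "cox")
    lam_seq <- path$lambda
    cvms <- matrix(NA_real_, nrow = length(lam_seq), ncol = cv_repeats)
    cvsds <- cvms
    for (r in seq_len(cv_repeats)) {
      set.seed(seed + r - 1L)
      foldid <- sample(rep_len(seq_len(cv_folds), nrow(x)))
      cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                              lambda = lam_seq)
      idx <- match(cv$lambda, lam_seq)
      cvms[idx, r] <- cv$cvm
      cvsds[idx, r] <- cv$cvsd
    }
    cvm <- rowMeans(cvms, na.rm = TRUE)
    cvsd <- rowMeans(cvsds, na.rm = TRUE)
    ok <- is.finite(cvm)
    i_min <- which(ok)[which.min(cvm[ok])]
    if (lambda_rule == "min") {
      lambda_use <- lam_seq[i_min]
    } else {
      within_1se <- ok & cvm <= cvm[i_min] + cvsd[i_min]
      lambda_use <- max(lam_seq[within_1se])
    }
    fit <- path
  } else {
    lambda_use <- lambda
    fit <- glmnet::glmnet(x, y, family = "cox",
                          lambda = sort(c(exp(seq(log(max(lambda, 1e-4) * 100),
                                                  log(max(lambda * 0.5, 1e-10)),
                                                  length.out = 50)), lambda),
                                        decreasing = TRUE))
  }
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda_use, exact = TRUE,
                                         x = x, y = y))
  nz <- which(beta != 0)
  if (length(nz) == 0L)
    stop("fit_signature: empty signature (all coefficients zero at the ",
         "chosen lambda); consider lambda_rule = \"min\" or a smaller lambda")
  model <- new_signature(igp$pairs[nz, c("gene_a", "gene_b"), drop = FALSE],
                         beta[nz], cutoff = NA_real_)
  model$lambda <- lambda_use
  model$lambda_rule <- if (is.null(lambda)) lambda_rule else "fixed"
  model$cv_folds <- if (is.null(lambda)) cv_folds else NA_integer_
  model$cv_repeats <- if (is.null(lambda)) cv_repeats else NA_integer_
  model$seed <- seed
  risk <- risk_score(model, igp)
  model$cutoff <- stats::median(risk)
  model$risk_training <- risk
  model
}

#' Construct a signature from an explicit pair/coefficient list
#'
#' Lets a published signature (pairs plus LASSO-Cox coefficients and a
#' training-median cutoff) be applied to new cohorts without refitting.
#'
#' @param pairs data frame with `gene_a`, `gene_b` (canonical
#'   orientation).
#' @param betas numeric nonzero coefficients, one per pair.
#' @param cutoff risk-score cutoff (training median).
#' @return an `igp_signature` object.
#' @export
new_signature <- function(pairs, betas, cutoff = NA_real_) {
  if (nrow(pairs) != length(betas))
    stop("new_signature: one coefficient per pair required")
  if (any(betas == 0)) stop("new_signature: coefficients must be nonzero")
  structure(list(pairs = data.frame(gene_a = pairs$gene_a,
                                    gene_b = pairs$gene_b,
                                    stringsAsFactors = FALSE),
                 betas = as.numeric(betas), cutoff = cutoff),
            class = "igp_signature")
}

#' @export
print.igp_signature <- function(x, ...) {
  cat(sprintf("igp_signature: %d pairs, cutoff %.4g\n",
              nrow(x$pairs), x$cutoff))
  print(data.frame(pair = pair_keys(x$pairs), beta = x$betas))
  invisible(x)
}

#' Per-sample risk score
#'
#' Risk = sum over signature pairs of beta_k x score(pair_k), the linear
#' form of the fitted penalized Cox model over the binary pair
#' indicators. Because the inputs are ordering indicators, the score is
#' directly comparable across platforms.
#'
#' @param model an `igp_signature`.
#' @param igp an `igp_matrix` containing every signature pair (no
#'   imputation: a missing pair is an error).
#' @return named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, igp) {
  idx <- match(pair_keys(model$pairs), pair_keys(igp$pairs))
  if (anyNA(idx))
    stop("risk_score: signature pairs missing from IGP matrix: ",
         paste(pair_keys(model$pairs)[is.na(idx)], collapse = ", "))
  drop(crossprod(igp$scores[idx, , drop = FALSE], model$betas))[igp$sample_ids]
}

#' Median dichotomization of risk scores
#'
#' High risk iff score strictly exceeds the cutoff; ties at the cutoff go
#' to the low-risk group.
#'
#' @param scores numeric risk scores.
#' @param cutoff risk-score cutoff (training median).
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("dichotomize: cutoff must be finite")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Evaluate a signature on a cohort
#'
#' Applies the training risk formula and the (unchanged) training cutoff,
#' then reports Kaplan-Meier curves, the log-rank test, the high-vs-low
#' Cox hazard ratio with 95% CI, and a Cox fit of the continuous score.
#' With a clinical table, a multivariate Cox model adjusts the signature
#' for the supplied covariates, and per-level stratified analyses are run
#' within each clinical factor (subgroups without events are skipped with
#' a warning).
#'
#' @param model an `igp_signature` with a finite cutoff.
#' @param igp an `igp_matrix` for the cohort.
#' @param surv a [survival_data] table.
#' @param clinical optional data frame (rownames or `sample_id` column)
#'   of covariates; factors are expanded per level, numerics entered
#'   directly.
#' @return list with `risk`, `groups`, `km`, `logrank`, `group_fit`
#'   (Cox of high vs low), `continuous_fit`, and when clinical data is
#'   given `multivariate_fit` and `stratified` (per factor level).
#' @export
evaluate_signature <- function(model, igp, surv, clinical = NULL) {
  if (!is.finite(model$cutoff)) stop("evaluate_signature: model has no cutoff")
  surv <- as_survival_data(surv)
  shared <- intersect(igp$sample_ids, surv$sample_id)
  igp <- igp_samples(igp, shared)
  surv <- subset_surv(surv, shared)
  risk <- risk_score(model, igp)
  groups <- dichotomize(risk, model$cutoff)
  out <- list(risk = risk, groups = groups)
  out$km <- km_estimate(surv, groups)
  out$logrank <- log_rank_test(surv, groups)
  gx <- matrix(as.numeric(groups == "high"), ncol = 1,
               dimnames = list(NULL, "high_risk"))
  out$group_fit <- cox_fit(gx, surv)
  out$continuous_fit <- cox_fit(matrix(risk, ncol = 1,
                                       dimnames = list(NULL, "risk_score")),
                                surv)
  if (!is.null(clinical)) {
    cl <- clinical
    if ("sample_id" %in% names(cl)) {
      rownames(cl) <- cl$sample_id
      cl$sample_id <- NULL
    }
    cl <- cl[shared, , drop = FALSE]
    cc <- stats::complete.cases(cl)
    xmat <- stats::model.matrix(~ ., data = cl[cc, , drop = FALSE])[, -1, drop = FALSE]
    xmat <- cbind(high_risk = as.numeric(groups == "high")[cc], xmat)
    out$multivariate_fit <- cox_fit(xmat, surv[cc, , drop = FALSE])
    strat <- list()
    for (v in names(cl)) {
      if (!(is.factor(cl[[v]]) || is.character(cl[[v]]))) next
      for (lev in unique(stats::na.omit(cl[[v]]))) {
        idx <- !is.na(cl[[v]]) & cl[[v]] == lev
        key <- paste(v, lev, sep = "=")
        si <- surv[idx, , drop = FALSE]
        gi <- droplevels(groups[idx])
        if (sum(si$event) == 0 || nlevels(gi) < 2) {
          warning("evaluate_signature: subgroup ", key,
                  " skipped (no events or single risk group)")
          next
        }
        strat[[key]] <- list(n = sum(idx),
                             logrank = log_rank_test(si, gi),
                             km = km_estimate(si, gi))
      }
    }
    out$stratified <- strat
  }
  out
}
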