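# covariate encoder shared by fit and predict: numerics pass through,
# factors/characters become treatment-coded 0/1 dummies with the first
# (sorted) level as reference; encodings are frozen in the model so
# external cohorts are scored identically.
encode_covariates <- function(data, encodings = NULL) {
  if (is.null(encodings)) {
    encodings <- lapply(data, function(col) {
      if (is.numeric(col)) list(type = "numeric")
      else list(type = "factor", levels = sort(unique(as.character(col))))
    })
  }
  cols <- list()
  for (v in names(encodings)) {
    if (!v %in% names(data)) stop("encode_covariates: missing covariate ", v)
    enc <- encodings[[v]]
    col <- data[[v]]
    if (enc$type == "numeric") {
      if (!is.numeric(col)) stop("encode_covariates: ", v, " must be numeric")
      cols[[v]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      unknown <- setdiff(unique(col), enc$levels)
      if (length(unknown) > 0)
        stop("encode_covariates: unknown level for ", v, ": ",
             paste(unknown, collapse = ", "))
      for (lev in enc$levels[-1])
        cols[[paste(v, lev, sep = "=")]] <- as.numeric(col == lev)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  list(x = x, encodings = encodings)
}

#' Fit a Cox nomogram
#'
#' Multivariate Cox model over the supplied covariates (typically the
#' binary signature risk group, 1p/19q status and WHO grade), with a
#' Breslow baseline survival evaluated at fixed horizons and a 0-100
#' points mapping: covariate level x contributes
#' `100 * (beta * x - min(beta * x)) / max_range` points, where
#' `max_range` is the largest observed `beta * x` range over covariates,
#' so the strongest covariate spans exactly 0-100 and total points is an
#' affine function of the Cox linear predictor.
#'
#' @param covariates data frame of covariates (numeric or factor/
#'   character columns); rows aligned with `surv`, complete cases only.
#' @param surv a [survival_data] table.
#' @param horizons months at which baseline survival is tabulated
#'   (default 12, 24, 36, 60 = 1/2/3/5 years).
#' @return object of class `igp_nomogram` with `fit` (a [cox_fit]),
#'   `betas`, `encodings`, `baseline` (data frame `horizon`, `s0`,
#'   centered at the covariate means; `NA` beyond follow-up),
#'   `lp_center`, points-mapping constants and per-column observed
#'   ranges.
#' @export
fit_nomogram <- function(covariates, surv, horizons = c(12, 24, 36, 60)) {
  surv <- as_survival_data(surv)
  if (nrow(covariates) != nrow(surv)) stop("fit_nomogram: row mismatch")
  if (anyNA(covariates)) stop("fit_nomogram: complete cases only")
  enc <- encode_covariates(covariates)
  fit <- cox_fit(enc$x, surv)
  beta <- fit$coefficients
  lp <- drop(enc$x %*% beta)
  lp_center <- mean(lp)
  bh <- survival::basehaz(fit$model, centered = FALSE)
  s0_at <- vapply(horizons, function(h) {
    if (h > max(surv$time)) return(NA_real_)
    below <- bh$time <= h
    H <- if (any(below)) bh$hazard[max(which(below))] else 0
    exp(-H * exp(lp_center))       # baseline centered at the mean predictor
  }, numeric(1))
  contrib <- sweep(enc$x, 2, beta, "*")
  ref <- apply(contrib, 2, min)
  rng <- apply(contrib, 2, max) - ref
  denom <- max(rng)
  if (denom <= 0) denom <- 1      # all-zero model: every level maps to 0 points
  structure(list(fit = fit, betas = beta, encodings = enc$encodings,
                 baseline = data.frame(horizon = horizons, s0 = s0_at),
                 lp_center = lp_center, point_ref = ref,
                 point_denom = denom, horizons = horizons,
                 ranges = rng), class = "igp_nomogram")
}

#' @export
print.igp_nomogram <- function(x, ...) {
  cat("igp_nomogram\n")
  print(data.frame(coef = x$betas, HR = exp(x$betas),
                   points_range = 100 * x$ranges / x$point_denom))
  print(x$baseline)
  invisible(x)
}

#' Nomogram total points
#'
#' Sum of per-covariate points (each in 0-100 over its observed range);
#' an affine function of the Cox linear predictor.
#'
#' @param model an `igp_nomogram`.
#' @param covariates data frame of covariates to score.
#' @return numeric vector of total points.
#' @export
total_points <- function(model, covariates) {
  enc <- encode_covariates(covariates, model$encodings)
  contrib <- sweep(enc$x, 2, model$betas, "*")
  pts <- sweep(contrib, 2, model$point_ref, "-") * 100 / model$point_denom
  rowSums(pts)
}

#' Predicted survival probability at a model horizon
#'
#' `S(h | x) = S0(h) ^ exp(lp(x) - lp_center)` with the Breslow baseline
#' centered at the training covariate means.
#'
#' @param model an `igp_nomogram`.
#' @param covariates data frame of covariates to score.
#' @param horizon one of the model's horizons (months).
#' @return numeric vector of survival probabilities in \[0, 1\] (`NA`
#'   when the horizon exceeded training follow-up).
#' @export
predict_survival <- function(model, covariates, horizon) {
  i <- match(horizon, model$baseline$horizon)
  if (is.na(i)) stop("predict_survival: horizon ", horizon,
                     " not tabulated; available: ",
                     paste(model$baseline$horizon, collapse = ", "))
  s0 <- model$baseline$s0[i]
  if (is.na(s0)) return(rep(NA_real_, nrow(covariates)))
  enc <- encode_covariates(covariates, model$encodings)
  lp <- drop(enc$x %*% model$betas)
  s0 ^ exp(lp - model$lp_center)
}

#' Paired bootstrap comparison of risk models by c-index
#'
#' Harrell's c for each named risk vector, bootstrapped over subjects
#' with shared resamples so models are compared on identical draws.
#'
#' @param risks named list of per-sample risk vectors (higher = worse),
#'   all aligned with `surv`.
#' @param surv a [survival_data] table.
#' @param B bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `c_index` (point estimates), `bootstrap_mean`,
#'   `bootstrap_sd`, `draws` (B x models matrix) and `pairwise`
#'   (fraction of draws in which the row model's c exceeds the column
#'   model's).
#' @export
compare_cindex <- function(risks, surv, B = 1000L, seed = 1L) {
  surv <- as_survival_data(surv)
  if (is.null(names(risks)) || any(names(risks) == ""))
    stop("compare_cindex: risks must be a named list")
  stopifnot(all(vapply(risks, length, 1L) == nrow(surv)))
  point <- vapply(risks, function(r) harrell_c(r, surv$time, surv$event),
                  numeric(1))
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = B, ncol = length(risks),
                  dimnames = list(NULL, names(risks)))
  for (b in seq_len(B)) {
    i <- sample.int(nrow(surv), replace = TRUE)
    draws[b, ] <- vapply(risks, function(r)
      harrell_c(r[i], surv$time[i], surv$event[i]), numeric(1))
  }
  m <- length(risks)
  pw <- matrix(NA_real_, m, m, dimnames = list(names(risks), names(risks)))
  for (a in seq_len(m)) for (bb in seq_len(m)) if (a != bb)
    pw[a, bb] <- mean(draws[, a] > draws[, bb], na.rm = TRUE)
  list(c_index = point, bootstrap_mean = colMeans(draws, na.rm = TRUE),
       bootstrap_sd = apply(draws, 2, stats::sd, na.rm = TRUE),
       draws = draws, pairwise = pw)
}

#' Nomogram calibration at the model horizons
#'
#' Predicted survival probabilities are binned into `n_groups`
#' equal-size groups and compared with the within-bin Kaplan-Meier
#' estimate at each horizon via [calibration_table()].
#'
#' @param model an `igp_nomogram`.
#' @param covariates data frame of covariates, aligned with `surv`.
#' @param surv a [survival_data] table.
#' @param horizons months (default: the model's horizons).
#' @param n_groups bins per horizon (default 4).
#' @return named list of calibration tables, one per horizon.
#' @export
calibrate_nomogram <- function(model, covariates, surv,
                               horizons = model$horizons, n_groups = 4L) {
  surv <- as_survival_data(surv)
  out <- list()
  for (h in horizons) {
    pred <- predict_survival(model, covariates, h)
    out[[as.character(h)]] <- if (all(is.na(pred))) NULL else
      calibration_table(pred, surv, horizon = h, n_groups = n_groups)
  }
  out
}
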