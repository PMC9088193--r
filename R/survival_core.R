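#' Kaplan-Meier estimate, optionally by group
#'
#' Product-limit estimator of the survival function, with the median
#' survival defined as the smallest observed event time at which the
#' estimated survival drops to 0.5 or below. When the curve never crosses
#' 0.5 (e.g. an all-censored group) the median is undefined and reported
#' as `NA` (serialized as `null`).
#'
#' @param surv a [survival_data] table.
#' @param group_labels optional vector (coerced to factor) of group
#'   membership, one per record; every group must be non-empty.
#' @return An object of class `km_result`: a list with one element per
#'   group, each containing `curve` (data frame `time`, `n_risk`,
#'   `n_event`, `surv` restricted to observed event times) and `median`.
#' @export
km_estimate <- function(surv, group_labels = NULL) {
  surv <- as_survival_data(surv)
  if (nrow(surv) == 0L) stop("km_estimate: empty input")
  if (is.null(group_labels)) {
    groups <- factor(rep("all", nrow(surv)))
  } else {
    if (length(group_labels) != nrow(surv))
      stop("km_estimate: group_labels length mismatch")
    groups <- droplevels(factor(group_labels))
    if (any(table(groups) == 0L)) stop("km_estimate: empty group")
  }
  out <- lapply(levels(groups), function(g) {
    idx <- groups == g
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = surv[idx, , drop = FALSE])
    keep <- fit$n.event > 0
    curve <- data.frame(time = fit$time[keep],
                        n_risk = fit$n.risk[keep],
                        n_event = fit$n.event[keep],
                        surv = fit$surv[keep])
    med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5]) else NA_real_
    list(curve = curve, median = med, n = sum(idx),
         n_events = sum(surv$event[idx]))
  })
  names(out) <- levels(groups)
  structure(out, class = "km_result")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation: survival is 1 before the first event time.
#'
#' @param km_group one element of a [km_estimate] result.
#' @param t numeric vector of times (months).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km_group, t) {
  curve <- km_group$curve
  vapply(t, function(ti) {
    below <- curve$time <= ti
    if (!any(below)) 1 else curve$surv[max(which(below))]
  }, numeric(1))
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square test with k - 1 degrees of freedom,
#' for k >= 2 groups.
#'
#' @param surv a [survival_data] table.
#' @param group_labels group membership, coerced to factor; at least two
#'   non-empty groups.
#' @return list with `statistic`, `df` and `p`. With zero observed events
#'   the statistic is 0 and p = 1.
#' @export
log_rank_test <- function(surv, group_labels) {
  surv <- as_survival_data(surv)
  groups <- droplevels(factor(group_labels))
  if (nlevels(groups) < 2L) stop("log_rank_test: need at least 2 groups")
  if (sum(surv$event) == 0)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = surv$time,
                                             event = surv$event, g = groups))
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times; Wald confidence intervals and p-values. Thin, contract-checked
#' wrapper around [survival::coxph()].
#'
#' Monotone partial likelihood (perfect separation) is detected via the
#' coefficient magnitude; affected coefficients are capped at +/- 15 on
#' the log-hazard scale and flagged with a warning.
#'
#' @param covariates numeric matrix or data frame (samples x covariates),
#'   complete cases only; rows aligned with `surv`.
#' @param surv a [survival_data] table.
#' @param conf_level confidence level for the Wald CI (default 0.95).
#' @param on_constant how to treat a zero-variance covariate: `"error"`
#'   (default) stops naming it; `"zero"` excludes it from the likelihood
#'   and reports the null effect (beta = 0, HR = 1, undefined se/p) with
#'   a warning.
#' @return An object of class `cox_fit` with elements `coefficients`,
#'   `hazard_ratios` (= exp(coefficients)), `se`, `ci_lower`, `ci_upper`
#'   (HR scale), `p_values`, `n_samples`, `n_events`, `separation`
#'   (logical per covariate) and the underlying `model`.
#' @export
cox_fit <- function(covariates, surv, conf_level = 0.95,
                    on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  surv <- as_survival_data(surv)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != nrow(surv)) stop("cox_fit: covariate rows must match survival records")
  if (anyNA(x)) stop("cox_fit: missing covariate values; supply complete cases only")
  if (sum(surv$event) < 2) stop("cox_fit: need at least 2 events")
  vars <- apply(x, 2, function(col) stats::var(col))
  constant <- vars == 0
  if (any(constant)) {
    if (on_constant == "error")
      stop("cox_fit: zero-variance covariate: ",
           paste(colnames(x)[constant], collapse = ", "))
    warning("cox_fit: zero-variance covariate reported as null effect: ",
            paste(colnames(x)[constant], collapse = ", "))
    if (all(constant)) {
      nm <- colnames(x)
      z0 <- stats::setNames(rep(0, ncol(x)), nm)
      return(structure(list(
        coefficients = z0, hazard_ratios = exp(z0),
        se = stats::setNames(rep(NA_real_, ncol(x)), nm),
        ci_lower = stats::setNames(rep(NA_real_, ncol(x)), nm),
        ci_upper = stats::setNames(rep(NA_real_, ncol(x)), nm),
        p_values = stats::setNames(rep(NA_real_, ncol(x)), nm),
        n_samples = nrow(surv), n_events = sum(surv$event),
        separation = stats::setNames(rep(FALSE, ncol(x)), nm),
        model = NULL), class = "cox_fit"))
    }
  }
  xf <- x[, !constant, drop = FALSE]
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ xf,
                         ties = "efron")
  beta_f <- unname(fit$coefficients)
  se_f <- unname(sqrt(diag(fit$var)))
  beta <- rep(0, ncol(x)); se <- rep(NA_real_, ncol(x))
  beta[!constant] <- beta_f
  se[!constant] <- se_f
  cap <- 15
  separation <- !is.finite(beta) | abs(beta) > cap
  if (any(separation)) {
    warning("cox_fit: monotone likelihood (separation) detected for ",
            paste(colnames(x)[separation], collapse = ", "),
            "; coefficients capped at +/-", cap)
    beta[separation] <- sign(beta[separation]) * cap
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  pv <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(
    coefficients = stats::setNames(beta, colnames(x)),
    hazard_ratios = stats::setNames(exp(beta), colnames(x)),
    se = stats::setNames(se, colnames(x)),
    ci_lower = stats::setNames(exp(beta - z * se), colnames(x)),
    ci_upper = stats::setNames(exp(beta + z * se), colnames(x)),
    p_values = stats::setNames(pv, colnames(x)),
    n_samples = nrow(surv), n_events = sum(surv$event),
    separation = stats::setNames(separation, colnames(x)),
    model = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: %d samples, %d events\n", x$n_samples, x$n_events))
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                   lower95 = x$ci_lower, upper95 = x$ci_upper,
                   p = x$p_values))
  invisible(x)
}

#' Harrell's concordance index with subject bootstrap
#'
#' Concordance over usable pairs: a pair is usable when the sample with
#' the earlier time had an observed event; ties in predicted risk count
#' 0.5. The bootstrap resamples subjects with replacement.
#'
#' @param risk numeric vector of per-sample risk scores (higher = worse).
#' @param surv a [survival_data] table aligned with `risk`.
#' @param bootstrap_B number of bootstrap resamples (0 = none).
#' @param seed integer seed for the bootstrap.
#' @return list with `c_index`, `n_pairs` (usable pairs), and when
#'   bootstrapped `bootstrap_mean`, `bootstrap_sd`, `bootstrap_values`.
#'   `c_index` is `NA` when no usable pair exists.
#' @export
concordance_index <- function(risk, surv, bootstrap_B = 0L, seed = NULL) {
  surv <- as_survival_data(surv)
  if (length(risk) != nrow(surv)) stop("concordance_index: risk length mismatch")
  if (anyNA(risk)) stop("concordance_index: risk must be defined for all samples")
  c0 <- harrell_c(risk, surv$time, surv$event)
  out <- list(c_index = c0, n = nrow(surv))
  if (bootstrap_B > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bs <- vapply(seq_len(bootstrap_B), function(b) {
      i <- sample.int(nrow(surv), replace = TRUE)
      harrell_c(risk[i], surv$time[i], surv$event[i])
    }, numeric(1))
    out$bootstrap_mean <- mean(bs, na.rm = TRUE)
    out$bootstrap_sd <- stats::sd(bs, na.rm = TRUE)
    out$bootstrap_values <- bs
  }
  out
}

# Harrell's c over usable pairs (internal): pairs are usable when the
# earlier time carries an observed event; risk ties count 0.5.
harrell_c <- function(r, tm, ev) {
  if (sum(ev) == 0) return(NA_real_)
  cc <- survival::concordance(survival::Surv(tm, ev) ~ r, reverse = TRUE)
  cnt <- cc$count
  usable <- cnt[["concordant"]] + cnt[["discordant"]] + cnt[["tied.x"]]
  if (usable == 0) return(NA_real_)
  (cnt[["concordant"]] + 0.5 * cnt[["tied.x"]]) / usable
}

#' Calibration table at a fixed horizon
#'
#' Samples are split into `n_groups` near-equal-size bins by predicted
#' survival probability; within each bin the observed survival is the
#' Kaplan-Meier estimate at the horizon. Bins whose follow-up ends before
#' the horizon report an undefined (`NA`) observed value.
#'
#' @param predicted per-sample predicted survival probability in \[0, 1\]
#'   at the horizon.
#' @param surv a [survival_data] table aligned with `predicted`.
#' @param horizon time (months) at which calibration is assessed.
#' @param n_groups number of bins (>= 1).
#' @return data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `km_observed`, `ci_lower`, `ci_upper`.
#' @export
calibration_table <- function(predicted, surv, horizon, n_groups = 4L) {
  surv <- as_survival_data(surv)
  if (length(predicted) != nrow(surv)) stop("calibration_table: length mismatch")
  if (anyNA(predicted) || any(predicted < 0 | predicted > 1))
    stop("calibration_table: predicted must be probabilities in [0, 1]")
  if (n_groups < 1L) stop("calibration_table: n_groups must be >= 1")
  # equal-size bins by rank of predicted value (ties broken by order)
  ord_rank <- rank(predicted, ties.method = "first")
  bin <- ceiling(ord_rank * n_groups / length(predicted))
  rows <- lapply(seq_len(n_groups), function(b) {
    idx <- bin == b
    si <- surv[idx, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = si)
    if (max(si$time) < horizon) {
      obs <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else {
      sm <- summary(fit, times = horizon, extend = TRUE)
      obs <- sm$surv; lo <- sm$lower; hi <- sm$upper
    }
    data.frame(bin = b, n = sum(idx), mean_predicted = mean(predicted[idx]),
               km_observed = obs, ci_lower = lo, ci_upper = hi)
  })
  do.call(rbind, rows)
}
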