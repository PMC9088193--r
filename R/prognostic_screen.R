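# Vectorized two-group survival statistics across many binary features.
#
# Screening tens of thousands of gene pairs per cohort (and simulation
# suites over many seeds) makes per-pair survdiff()/coxph() calls the
# bottleneck, so the score-0 vs score-1 log-rank test and the univariate
# Cox fit on a binary covariate are computed for all pairs at once from
# shared risk-set count matrices. Both reproduce survival::survdiff and
# survival::coxph(ties = "efron") to numerical precision (unit-tested).

# risk-set machinery shared by the log-rank and Cox screens.
# scores: P x n integer 0/1 matrix; time/event: length n.
risk_set_counts <- function(scores, time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; ev <- event[ord] == 1
  S <- scores[, ord, drop = FALSE]
  # at-risk count in group 1 from each index to the end (reverse cumsum)
  RS1 <- S[, n:1, drop = FALSE]
  RS1 <- t(apply(RS1, 1, cumsum))
  if (nrow(scores) == 1L) RS1 <- matrix(RS1, nrow = 1L)
  RS1 <- RS1[, n:1, drop = FALSE]
  ut <- unique(t_s[ev])
  fi <- match(ut, t_s)                       # first index at risk at each event time
  R <- n - fi + 1                            # total at risk
  R1 <- t(RS1[, fi, drop = FALSE])           # K x P at risk in group 1
  d <- as.vector(table(factor(t_s[ev], levels = ut)))
  M <- S[, ev, drop = FALSE]                 # P x (n events)
  grp <- match(t_s[ev], ut)
  D1 <- rowsum(t(M), group = grp)            # K x P events in group 1
  list(R = R, R1 = R1, d = d, D1 = D1, K = length(ut))
}

# two-group log-rank chi-square for every row of a binary score matrix
logrank_binary_many <- function(scores, time, event) {
  if (sum(event) == 0) return(list(statistic = rep(0, nrow(scores)),
                                   p = rep(1, nrow(scores))))
  rc <- risk_set_counts(scores, time, event)
  frac <- rc$R1 / rc$R                       # vector R recycles down columns
  E1 <- rc$d * frac
  vmult <- ifelse(rc$R > 1, rc$d * (rc$R - rc$d) / (rc$R - 1), 0)
  V <- vmult * frac * (1 - frac)
  num <- colSums(rc$D1) - colSums(E1)
  den <- colSums(V)
  chi <- ifelse(den > 0, num^2 / den, NA_real_)
  list(statistic = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

# univariate Cox (binary covariate, Efron ties) for every row of a binary
# score matrix; Newton-Raphson on the profile of each pair independently.
cox_binary_many <- function(scores, time, event, max_iter = 30L,
                            tol = 1e-10, cap = 15) {
  P <- nrow(scores)
  if (sum(event) < 2) return(list(beta = rep(NA_real_, P), se = rep(NA_real_, P),
                                  hr = rep(NA_real_, P), p = rep(NA_real_, P)))
  rc <- risk_set_counts(scores, time, event)
  # Efron expansion: event time k with d_k deaths contributes rows l = 0..d_k-1
  kidx <- rep.int(seq_len(rc$K), rc$d)
  frac <- (sequence(rc$d) - 1) / rc$d[kidx]
  Re <- rc$R[kidx]; de <- rc$d[kidx]
  R1e <- rc$R1[kidx, , drop = FALSE]
  D1e <- rc$D1[kidx, , drop = FALSE]
  A <- (Re - R1e) - frac * (de - D1e)        # group-0 effective risk mass
  B <- R1e - frac * D1e                      # group-1 effective risk mass
  s <- colSums(rc$D1)                        # events in group 1 per pair
  beta <- rep(0, P)
  active <- rep(TRUE, P)
  info <- rep(NA_real_, P)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    w <- exp(beta[active])
    Bw <- sweep(B[, active, drop = FALSE], 2, w, "*")
    denom <- A[, active, drop = FALSE] + Bw
    U <- s[active] - colSums(Bw / denom)
    I <- colSums(A[, active, drop = FALSE] * Bw / denom^2)
    bad <- !is.finite(I) | I <= 0
    step <- ifelse(bad, 0, U / pmax(I, .Machine$double.eps))
    step <- pmin(pmax(step, -2), 2)          # damped step for stability
    bnew <- beta[active] + step
    bnew <- pmin(pmax(bnew, -cap), cap)
    info[active] <- I
    conv <- bad | abs(step) < tol | abs(bnew) >= cap
    beta[active] <- bnew
    still <- active
    still[active] <- !conv
    if (it == max_iter) break
    active <- still
  }
  degenerate <- !is.finite(info) | info <= 0
  beta[degenerate] <- NA_real_
  se <- ifelse(degenerate, NA_real_, 1 / sqrt(info))
  list(beta = beta, se = se, hr = exp(beta),
       p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Screen gene pairs for prognostic value in one cohort
#'
#' For every pair: a two-group log-rank test (score 0 vs score 1) and a
#' univariate Cox hazard ratio for score 1 vs 0 (Efron ties). A pair is
#' flagged prognostic when its log-rank p-value falls below `alpha` and
#' both score groups are non-empty; pairs with a constant score are
#' non-prognostic by definition. Analysis is restricted to the samples
#' shared by the IGP matrix and the survival table (dropped counts are
#' reported via message).
#'
#' @param igp an `igp_matrix` for the cohort.
#' @param surv a [survival_data] table for the cohort.
#' @param alpha per-cohort significance threshold (default 0.05,
#'   unadjusted; the cross-cohort intersection is the false-positive
#'   control).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment of the log-rank p-values before thresholding.
#' @return data frame of class `igp_screen`: `gene_a`, `gene_b`, `n1`
#'   (score-1 samples), `beta`, `se`, `hr`, `logrank_p`, `p_adj` (when
#'   adjusted), `prognostic`.
#' @export
screen_cohort <- function(igp, surv, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  surv <- as_survival_data(surv)
  shared <- intersect(igp$sample_ids, surv$sample_id)
  if (length(shared) == 0L) stop("screen_cohort: no shared samples")
  dropped <- length(igp$sample_ids) - length(shared)
  if (dropped > 0)
    message("screen_cohort: ", dropped, " samples without survival dropped")
  igp <- igp_samples(igp, shared)
  surv <- subset_surv(surv, shared)
  if (sum(surv$event) == 0) stop("screen_cohort: zero events in cohort")
  sc <- igp$scores
  n1 <- rowSums(sc)
  lr <- logrank_binary_many(sc, surv$time, surv$event)
  cx <- cox_binary_many(sc, surv$time, surv$event)
  out <- data.frame(gene_a = igp$pairs$gene_a, gene_b = igp$pairs$gene_b,
                    n1 = n1, beta = cx$beta, se = cx$se, hr = cx$hr,
                    logrank_p = lr$p, stringsAsFactors = FALSE)
  p_use <- out$logrank_p
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$logrank_p, method = "BH")
    p_use <- out$p_adj
  }
  out$prognostic <- !is.na(p_use) & p_use < alpha &
    n1 > 0 & n1 < ncol(sc) & !is.na(out$hr)
  attr(out, "n_samples") <- length(shared)
  attr(out, "n_events") <- sum(surv$event)
  attr(out, "alpha") <- alpha
  class(out) <- c("igp_screen", "data.frame")
  out
}

#' Intersect prognostic pairs across cohorts
#'
#' @param fragments list (>= 2) of [screen_cohort()] results screened on
#'   the same candidate pair list.
#' @return pair data frame of pairs flagged prognostic in every cohort.
#' @export
intersect_prognostic <- function(fragments) {
  if (length(fragments) < 2L) stop("intersect_prognostic: need >= 2 cohorts")
  keys <- lapply(fragments, function(f) pair_keys(f)[f$prognostic])
  common <- Reduce(intersect, keys)
  f1 <- fragments[[1]]
  out <- f1[pair_keys(f1) %in% common, c("gene_a", "gene_b"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove direction-inconsistent (controversial) pairs
#'
#' An intersected prognostic pair whose per-cohort hazard ratios straddle
#' 1 (some above, some below) has no consensus direction and is removed.
#' Survivors carry `consensus_direction` "unfavorable" (all HR > 1) or
#' "favorable" (all HR < 1).
#'
#' @param pairs intersected pair data frame.
#' @param fragments the per-cohort [screen_cohort()] results.
#' @return list with `kept` (pairs + `consensus_direction`), `removed`
#'   (controversial pairs) and `hr` (pairs x cohorts HR matrix).
#' @export
remove_controversial <- function(pairs, fragments) {
  keys <- pair_keys(pairs)
  hr <- vapply(fragments, function(f) {
    f$hr[match(keys, pair_keys(f))]
  }, numeric(length(keys)))
  hr <- matrix(hr, nrow = length(keys),
               dimnames = list(keys, names(fragments)))
  if (anyNA(hr)) stop("remove_controversial: missing HR for an intersected pair")
  if (any(hr == 1)) stop("remove_controversial: HR exactly 1 for a prognostic pair")
  up <- rowSums(hr > 1)
  controversial <- up > 0 & up < ncol(hr)
  kept <- pairs[!controversial, , drop = FALSE]
  kept$consensus_direction <- ifelse(up[!controversial] == ncol(hr),
                                     "unfavorable", "favorable")
  rownames(kept) <- NULL
  removed <- pairs[controversial, , drop = FALSE]
  rownames(removed) <- NULL
  list(kept = kept, removed = removed, hr = hr)
}

#' Partition final pairs into UPPs and FPPs
#'
#' Unfavorable prognostic predictors (UPP, consensus HR > 1 for score 1)
#' versus favorable prognostic predictors (FPP, consensus HR < 1).
#'
#' @param pairs final pair data frame with `consensus_direction`.
#' @return list with `upp` and `fpp` pair data frames and `counts`.
#' @export
classify_pairs <- function(pairs) {
  upp <- pairs[pairs$consensus_direction == "unfavorable", , drop = FALSE]
  fpp <- pairs[pairs$consensus_direction == "favorable", , drop = FALSE]
  rownames(upp) <- NULL; rownames(fpp) <- NULL
  list(upp = upp, fpp = fpp,
       counts = c(upp = nrow(upp), fpp = nrow(fpp), total = nrow(pairs)))
}

#' Assign favorable/unfavorable/two-side gene roles
#'
#' Within a UPP (score 1 = `gene_a` higher is adverse) `gene_a` receives
#' an unfavorable vote and `gene_b` a favorable vote; within an FPP the
#' votes are reversed. A gene with only unfavorable votes is a UG, with
#' only favorable votes an FG, and with both a two-side gene (TSG).
#'
#' @param pairs final pair data frame with `consensus_direction`.
#' @return data frame `gene`, `role` (FG/UG/TSG), `degree` (number of
#'   final pairs containing the gene).
#' @export
assign_gene_roles <- function(pairs) {
  up <- pairs$consensus_direction == "unfavorable"
  unfav <- c(pairs$gene_a[up], pairs$gene_b[!up])
  fav <- c(pairs$gene_b[up], pairs$gene_a[!up])
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  has_u <- genes %in% unfav
  has_f <- genes %in% fav
  role <- ifelse(has_u & has_f, "TSG", ifelse(has_u, "UG", "FG"))
  deg <- table(factor(c(pairs$gene_a, pairs$gene_b), levels = genes))
  data.frame(gene = genes, role = role, degree = as.integer(deg),
             stringsAsFactors = FALSE)
}

#' Gene co-occurrence network of the final pairs
#'
#' Genes are nodes, pairs are edges; a gene's degree is the number of
#' final prognostic pairs containing it, so the degree sum equals twice
#' the number of pairs. High-degree genes are the network hubs.
#'
#' @param pairs final pair data frame.
#' @return list with `edges` (pair table) and `degrees` (data frame
#'   `gene`, `degree`, sorted by decreasing degree).
#' @export
build_pair_network <- function(pairs) {
  tab <- sort(table(c(pairs$gene_a, pairs$gene_b)), decreasing = TRUE)
  list(edges = pairs[, c("gene_a", "gene_b"), drop = FALSE],
       degrees = data.frame(gene = names(tab), degree = as.integer(tab),
                            stringsAsFactors = FALSE))
}
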