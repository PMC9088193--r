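# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

make_surv <- function(time, event, prefix = "s") {
  survival_data(paste0(prefix, seq_along(time)), time, event)
}

# two-group log-rank statistic by direct risk-set bookkeeping
oracle_logrank2 <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    R <- sum(at_risk); R1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * R1 / R
    if (R > 1) V <- V + d * (R1 / R) * (1 - R1 / R) * (R - d) / (R - 1)
  }
  (O1 - E1)^2 / V
}

# Efron partial log-likelihood for a single covariate (general x)
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    deaths <- event == 1 & time == t
    d <- sum(deaths)
    sum_risk <- sum(exp(beta * x[at_risk]))
    sum_death <- sum(exp(beta * x[deaths]))
    ll <- ll + beta * sum(x[deaths])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_risk - (l / d) * sum_death)
  }
  ll
}

# Harrell's c by exhaustive pair enumeration
oracle_cindex <- function(risk, time, event) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    early <- if (time[i] < time[j]) i else j
    late <- if (time[i] < time[j]) j else i
    if (event[early] != 1) next        # usable iff earlier time is an event
    den <- den + 1
    if (risk[early] > risk[late]) num <- num + 1
    else if (risk[early] == risk[late]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# per-sample focal-gene-higher count straight off the score matrix
oracle_hr_score <- function(gene, igp) {
  n <- length(igp$sample_ids)
  out <- integer(n)
  for (j in seq_len(n)) {
    cnt <- 0L
    for (k in seq_len(nrow(igp$pairs))) {
      a <- igp$pairs$gene_a[k]; b <- igp$pairs$gene_b[k]
      if (a != gene && b != gene) next
      s <- igp$scores[k, j]
      if ((a == gene && s == 1L) || (b == gene && s == 0L)) cnt <- cnt + 1L
    }
    out[j] <- cnt
  }
  out
}

# Weibull-PH survival times for a given linear predictor (inverse transform)
sim_weibull_surv <- function(lp, shape = 1.2, scale = 60,
                             cens = c(12, 120)) {
  n <- length(lp)
  t_ev <- scale * (-log(runif(n)) * exp(-lp))^(1 / shape)
  cn <- runif(n, cens[1], cens[2])
  make_surv(pmin(t_ev, cn), as.numeric(t_ev <= cn))
}

# engineered final-pair fixture with known FG/UG/TSG counts:
# 110 favorable-only genes (N...), 88 unfavorable-only (44 B... + 44 U...),
# 34 two-side genes (T...); 188 pairs in total.
role_fixture <- function() {
  Bg <- sprintf("B%03d", 1:44)
  Ng <- sprintf("N%03d", 1:110)
  Tg <- sprintf("T%03d", 1:34)
  Ug <- sprintf("U%03d", 1:44)
  upp <- data.frame(gene_a = rep_len(Bg, 110), gene_b = Ng,
                    consensus_direction = "unfavorable")
  fpp1 <- data.frame(gene_a = rep_len(Ng, 34), gene_b = Tg,
                     consensus_direction = "favorable")
  fpp2 <- data.frame(gene_a = rep_len(Tg, 44), gene_b = Ug,
                     consensus_direction = "favorable")
  rbind(upp, fpp1, fpp2)
}

# minimal screen-fragment stand-in for intersection/controversy tests
frag <- function(gene_a, gene_b, hr, prognostic = TRUE) {
  data.frame(gene_a = gene_a, gene_b = gene_b, hr = hr,
             prognostic = prognostic, stringsAsFactors = FALSE)
}
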