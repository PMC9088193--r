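#' Final pairs containing a focal gene
#'
#' @param gene focal gene symbol.
#' @param pairs final prognostic pair data frame.
#' @return subset of `pairs` containing the gene (as either member).
#' @export
related_pairs <- function(gene, pairs) {
  gene <- normalize_symbols(gene)
  hit <- pairs$gene_a == gene | pairs$gene_b == gene
  if (!any(hit)) stop("related_pairs: gene ", gene, " appears in no final pair")
  out <- pairs[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-centric HR score
#'
#' For a focal gene, the per-patient count of its related pairs in which
#' the focal gene is the higher-expressed member, regardless of the
#' pair's canonical orientation. The score is an integer in
#' 0..(number of related pairs): for an adverse hub like HOXA9 (all
#' related pairs unfavorable with the hub higher) a score of 28/28 is the
#' worst pattern, while for a protective hub like CRH a score of 27/27 is
#' the best. Because it is a sum of ordering indicators, the score is
#' invariant to per-sample monotone expression transforms.
#'
#' With the tie-scores-0 binarization rule, a tied pair counts toward the
#' partner when the focal gene is `gene_a` and toward the focal gene when
#' it is `gene_b`; on continuous expression scales ties do not occur and
#' the score equals the strict focal-gene-higher count.
#'
#' @param gene focal gene symbol.
#' @param igp an `igp_matrix` containing all related pairs.
#' @param related related pair table (default: all pairs of `igp`
#'   containing the gene).
#' @return integer vector of per-sample scores (named by sample), with
#'   attributes `gene` and `n_related`.
#' @export
hr_score <- function(gene, igp, related = NULL) {
  gene <- normalize_symbols(gene)
  if (is.null(related)) related <- related_pairs(gene, igp$pairs)
  sub <- igp_subset(igp, related[, c("gene_a", "gene_b"), drop = FALSE])
  focal_is_a <- sub$pairs$gene_a == gene
  if (!all(focal_is_a | sub$pairs$gene_b == gene))
    stop("hr_score: a related pair does not contain the focal gene")
  oriented <- sub$scores
  oriented[!focal_is_a, ] <- 1L - oriented[!focal_is_a, , drop = FALSE]
  sc <- colSums(oriented)
  structure(as.integer(sc), names = sub$sample_ids,
            gene = gene, n_related = nrow(related))
}

#' Stratify patients by HR score
#'
#' Three schemes over the attainable score range 0..`n_pairs`:
#' * `halves` — low = scores up to `floor(n_pairs / 2)`, high = above
#'   (for 28 related pairs: 0-14 vs 15-28);
#' * `extremes` — only patients at the attained minimum vs the attained
#'   maximum score (others labelled `NA`);
#' * `five_bins` — five contiguous equal-width integer bins of width
#'   `ceiling((n_pairs + 1) / 5)` spanning 0..`n_pairs`, the last bin
#'   truncated.
#'
#' @param scores integer HR scores (from [hr_score()]).
#' @param scheme `"halves"`, `"extremes"` or `"five_bins"`.
#' @param n_pairs number of related pairs (score ceiling); defaults to
#'   the `n_related` attribute of `scores`.
#' @return factor of group labels (same length as `scores`), with
#'   attribute `boundaries` describing the bins.
#' @export
stratify_scores <- function(scores, scheme = c("halves", "extremes", "five_bins"),
                            n_pairs = attr(scores, "n_related")) {
  scheme <- match.arg(scheme)
  if (is.null(n_pairs)) n_pairs <- max(scores)
  s <- as.integer(scores)
  if (scheme == "halves") {
    cut_at <- floor(n_pairs / 2)
    lab <- ifelse(s <= cut_at, sprintf("0-%d", cut_at),
                  sprintf("%d-%d", cut_at + 1L, n_pairs))
    out <- factor(lab, levels = c(sprintf("0-%d", cut_at),
                                  sprintf("%d-%d", cut_at + 1L, n_pairs)))
    attr(out, "boundaries") <- c(low_max = cut_at, high_max = n_pairs)
  } else if (scheme == "extremes") {
    lo <- min(s); hi <- max(s)
    if (lo == hi)
      stop("stratify_scores: extremes scheme needs >= 2 attained scores; attained: ",
           paste(sort(unique(s)), collapse = ", "))
    lab <- ifelse(s == lo, sprintf("score %d", lo),
                  ifelse(s == hi, sprintf("score %d", hi), NA))
    out <- factor(lab, levels = c(sprintf("score %d", lo), sprintf("score %d", hi)))
    attr(out, "boundaries") <- c(min = lo, max = hi)
  } else {
    width <- ceiling((n_pairs + 1L) / 5)
    lower <- pmin(width * 0:4, n_pairs)
    upper <- pmin(width * 1:5 - 1L, n_pairs)
    labs <- sprintf("%d-%d", lower, upper)
    bin <- pmin(s %/% width + 1L, 5L)
    out <- factor(labs[bin], levels = unique(labs))
    attr(out, "boundaries") <- data.frame(bin = seq_along(labs),
                                          lower = lower, upper = upper)
  }
  out
}

#' Survival stratification by a focal gene's HR score
#'
#' Bundles [hr_score()], [stratify_scores()], Kaplan-Meier curves and the
#' log-rank test, plus a trend summary: the sign of the Cox coefficient
#' for the integer score entered as a continuous covariate (positive =
#' survival decreases as the score rises).
#'
#' @param gene focal gene symbol.
#' @param igp an `igp_matrix` of the final pairs.
#' @param surv a [survival_data] table.
#' @param scheme stratification scheme, see [stratify_scores()].
#' @return list with `scores`, `groups`, `boundaries`, `km`, `logrank`,
#'   `trend_beta`, `trend` ("adverse"/"protective").
#' @export
evaluate_gene_score <- function(gene, igp, surv,
                                scheme = c("halves", "extremes", "five_bins")) {
  scheme <- match.arg(scheme)
  surv <- as_survival_data(surv)
  shared <- intersect(igp$sample_ids, surv$sample_id)
  igp <- igp_samples(igp, shared)
  surv <- subset_surv(surv, shared)
  sc <- hr_score(gene, igp)
  groups <- stratify_scores(sc, scheme)
  usable <- !is.na(groups)
  km <- km_estimate(surv[usable, , drop = FALSE], droplevels(groups[usable]))
  lr <- log_rank_test(surv[usable, , drop = FALSE], droplevels(groups[usable]))
  cf <- cox_fit(matrix(as.numeric(sc), ncol = 1,
                       dimnames = list(NULL, "hr_score")), surv)
  beta <- unname(cf$coefficients[1])
  list(gene = normalize_symbols(gene), scores = sc, groups = groups,
       boundaries = attr(groups, "boundaries"), km = km, logrank = lr,
       trend_beta = beta,
       trend = if (beta > 0) "adverse" else "protective")
}
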