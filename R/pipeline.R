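#' Run the full gene-pair prognostic workflow
#'
#' Chains every stage on a list of cohorts sharing a gene universe:
#' pair enumeration over the shared (optionally restricted) gene set,
#' per-cohort unevenness filtering with cross-cohort intersection of the
#' retained pairs, binarization, per-cohort prognostic screening with
#' cross-cohort intersection, controversial-pair removal, UPP/FPP
#' classification, gene roles and co-occurrence network, LASSO-Cox
#' signature fitting on the training cohort, signature evaluation on
#' every cohort with the training cutoff, and (when clinical tables carry
#' `grade` and `codel_1p19q`) a three-covariate nomogram with bootstrap
#' concordance and calibration.
#'
#' @param cohorts list of cohorts, each a list with `expression`
#'   (genes x samples matrix), `survival` (a [survival_data]) and
#'   optionally `clinical` (data frame with `sample_id`). The first
#'   cohort (or `train`) is the training cohort.
#' @param gene_list optional character vector restricting the gene
#'   universe (e.g. a curated immune list); default: all shared genes.
#' @param alpha per-cohort screening threshold.
#' @param max_fraction unevenness retention threshold.
#' @param train index or name of the training cohort.
#' @param cv_folds,cv_repeats,lambda_rule passed to [fit_signature()].
#' @param nomogram_B bootstrap resamples for the nomogram c-index.
#' @param seed master seed for signature CV folds and bootstraps.
#' @return object of class `igp_report`: list with `counts` (the
#'   workflow tally), `pairs` (final pair table with directions),
#'   `screen` (per-cohort fragments), `roles`, `network`, `signature`,
#'   `evaluation` (per cohort), `nomogram` (model, c-indices,
#'   calibration; NULL without clinical data) and `manifest`.
#' @export
run_igp_workflow <- function(cohorts, gene_list = NULL, alpha = 0.05,
                             max_fraction = 0.95, train = 1L,
                             cv_folds = 10L, cv_repeats = 100L,
                             lambda_rule = "1se", nomogram_B = 1000L,
                             seed = 1L) {
  stopifnot(length(cohorts) >= 2L)
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  exprs <- lapply(cohorts, function(co) validate_expression(co$expression))
  shared_genes <- Reduce(intersect, lapply(exprs, rownames))
  if (!is.null(gene_list))
    shared_genes <- intersect(shared_genes, normalize_symbols(gene_list))
  if (length(shared_genes) < 2L)
    stop("run_igp_workflow: fewer than 2 genes shared by all cohorts")
  all_pairs <- enumerate_pairs(shared_genes)
  counts <- list(genes = length(shared_genes), pairs_enumerated = nrow(all_pairs))

  # unevenness filter per cohort, then shared feature space
  retained <- lapply(exprs, function(e) {
    fr <- score_fractions(e[shared_genes, , drop = FALSE], all_pairs)
    filter_uneven(fr, max_fraction = max_fraction, pairs = all_pairs)$retained
  })
  counts$retained_per_cohort <- vapply(retained, nrow, 1L)
  overlap <- intersect_available(retained)
  counts$pairs_overlapping <- nrow(overlap)
  if (nrow(overlap) == 0L)
    stop("run_igp_workflow: no pair passes the unevenness filter in every ",
         "cohort; nothing to screen")

  igps <- lapply(exprs, function(e)
    binarize(e[shared_genes, , drop = FALSE], overlap))
  fragments <- lapply(seq_along(cohorts), function(i)
    screen_cohort(igps[[i]], cohorts[[i]]$survival, alpha = alpha))
  names(fragments) <- names(cohorts)
  counts$prognostic_per_cohort <- vapply(fragments, function(f)
    sum(f$prognostic), 1L)
  inter <- intersect_prognostic(fragments)
  counts$prognostic_intersection <- nrow(inter)
  rc <- remove_controversial(inter, fragments)
  counts$controversial_removed <- nrow(rc$removed)
  counts$final_pairs <- nrow(rc$kept)
  cls <- classify_pairs(rc$kept)
  counts$upp <- unname(cls$counts[["upp"]])
  counts$fpp <- unname(cls$counts[["fpp"]])
  roles <- if (nrow(rc$kept) > 0) assign_gene_roles(rc$kept) else NULL
  network <- if (nrow(rc$kept) > 0) build_pair_network(rc$kept) else NULL
  if (!is.null(roles)) {
    counts$fg <- sum(roles$role == "FG")
    counts$ug <- sum(roles$role == "UG")
    counts$tsg <- sum(roles$role == "TSG")
    counts$unique_genes <- nrow(roles)
  }

  # sparse signature on the training cohort, evaluated everywhere with
  # the training cutoff
  signature <- NULL; evaluation <- NULL; nomo <- NULL
  if (nrow(rc$kept) > 0) {
    tr <- if (is.character(train)) match(train, names(cohorts)) else train
    final_pairs <- rc$kept[, c("gene_a", "gene_b")]
    igp_final <- lapply(igps, igp_subset, pairs = final_pairs)
    fit_try <- function(rule) tryCatch(
      fit_signature(igp_final[[tr]], cohorts[[tr]]$survival,
                    cv_folds = cv_folds, cv_repeats = cv_repeats,
                    lambda_rule = rule, seed = seed),
      error = function(e) e)
    signature <- fit_try(lambda_rule)
    if (inherits(signature, "error") && lambda_rule == "1se" &&
        grepl("empty signature", conditionMessage(signature))) {
      message("run_igp_workflow: empty signature at lambda 1se; retrying ",
              "with lambda min")
      signature <- fit_try("min")
    }
    if (inherits(signature, "error")) {
      message("run_igp_workflow: signature not fitted: ",
              conditionMessage(signature))
      signature <- NULL
    }
    if (!is.null(signature)) {
      counts$signature_pairs <- nrow(signature$pairs)
      evaluation <- lapply(seq_along(cohorts), function(i)
        evaluate_signature(signature, igp_final[[i]], cohorts[[i]]$survival))
      names(evaluation) <- names(cohorts)
      clin <- cohorts[[tr]]$clinical
      if (!is.null(clin) && all(c("grade", "codel_1p19q") %in% names(clin))) {
        surv_tr <- cohorts[[tr]]$survival
        cl <- clin[match(surv_tr$sample_id, clin$sample_id), , drop = FALSE]
        covs <- data.frame(signature = as.character(evaluation[[tr]]$groups),
                           codel_1p19q = cl$codel_1p19q, grade = cl$grade,
                           stringsAsFactors = FALSE)
        cc <- stats::complete.cases(covs)
        model <- fit_nomogram(covs[cc, , drop = FALSE],
                              surv_tr[cc, , drop = FALSE])
        risk_nomo <- total_points(model, covs[cc, , drop = FALSE])
        cidx <- compare_cindex(
          list(nomogram = risk_nomo,
               signature = evaluation[[tr]]$risk[cc]),
          surv_tr[cc, , drop = FALSE], B = nomogram_B, seed = seed)
        calib <- calibrate_nomogram(model, covs[cc, , drop = FALSE],
                                    surv_tr[cc, , drop = FALSE])
        nomo <- list(model = model, c_index = cidx, calibration = calib)
        counts$nomogram_c_index <- unname(cidx$c_index[["nomogram"]])
      }
    }
  }

  manifest <- list(
    cohorts = lapply(seq_along(cohorts), function(i) list(
      name = names(cohorts)[i],
      n_genes = nrow(exprs[[i]]), n_samples = ncol(exprs[[i]]),
      n_events = sum(cohorts[[i]]$survival$event),
      expression_fingerprint = fingerprint(c(dim(exprs[[i]]),
                                             round(sum(exprs[[i]]), 6))))),
    parameters = list(alpha = alpha, max_fraction = max_fraction,
                      train = train, cv_folds = cv_folds,
                      cv_repeats = cv_repeats, lambda_rule = lambda_rule,
                      nomogram_B = nomogram_B, seed = seed),
    package_version = as.character(utils::packageVersion("igpsurv")),
    timestamp = format(Sys.time(), tz = "UTC"))

  structure(list(counts = counts, pairs = rc$kept, removed = rc$removed,
                 screen = fragments, roles = roles, network = network,
                 signature = signature, evaluation = evaluation,
                 nomogram = nomo, manifest = manifest),
            class = "igp_report")
}

#' @export
print.igp_report <- function(x, ...) {
  cat("igp_report\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-26s %s\n", nm, paste(x$counts[[nm]], collapse = " / ")))
  invisible(x)
}

#' Serialize a workflow report to JSON
#'
#' Canonical JSON of the counts, final pairs, gene roles, hub degrees,
#' signature and per-cohort headline statistics. With
#' `include_timestamp = FALSE` the output is byte-identical across runs
#' with the same inputs, configuration and seed.
#'
#' @param report an `igp_report`.
#' @param path optional output file.
#' @param include_timestamp keep the manifest timestamp (default TRUE).
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL, include_timestamp = TRUE) {
  manifest <- report$manifest
  if (!include_timestamp) manifest$timestamp <- NULL
  headline <- NULL
  if (!is.null(report$evaluation)) {
    headline <- lapply(report$evaluation, function(ev) list(
      logrank_p = ev$logrank$p,
      group_hr = unname(ev$group_fit$hazard_ratios[1]),
      group_hr_ci = c(unname(ev$group_fit$ci_lower[1]),
                      unname(ev$group_fit$ci_upper[1])),
      median_low = ev$km$low$median, median_high = ev$km$high$median))
  }
  obj <- list(counts = report$counts, final_pairs = report$pairs,
              removed_pairs = report$removed, roles = report$roles,
              top_degrees = if (!is.null(report$network))
                utils::head(report$network$degrees, 10) else NULL,
              signature = if (!is.null(report$signature)) list(
                pairs = report$signature$pairs,
                betas = report$signature$betas,
                lambda = report$signature$lambda,
                cutoff = report$signature$cutoff) else NULL,
              evaluation = headline, manifest = manifest)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
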