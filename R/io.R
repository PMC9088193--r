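# validate and normalize an expression matrix: unique uppercased gene
# symbols in rows, unique sample ids in columns, finite values; rows with
# any missing value are dropped with a message.
validate_expression <- function(expr) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  rownames(expr) <- normalize_symbols(rownames(expr))
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene symbols in expression matrix: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample ids in expression matrix: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  if (anyNA(expr)) {
    bad <- rowSums(is.na(expr)) > 0
    message("dropping ", sum(bad), " gene rows with missing values")
    expr <- expr[!bad, , drop = FALSE]
  }
  if (!all(is.finite(expr))) stop("expression matrix contains non-finite values")
  expr
}

#' Read an expression matrix
#'
#' Tab-separated, first column gene symbols, remaining columns samples
#' (`transpose = TRUE` for samples-in-rows layouts), or MatrixMarket
#' `.mtx` with sidecar row/column files. Symbols are normalized and rows
#' with missing values dropped with a message.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @param transpose set TRUE when samples are in rows (tsv only).
#' @param row_file,col_file sidecar files (one symbol / sample id per
#'   line) for `format = "mtx"`; default `<path>.rows` / `<path>.cols`.
#' @return numeric matrix genes x samples.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"), transpose = FALSE,
                            row_file = paste0(path, ".rows"),
                            col_file = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_expression: file not found: ", path)
  if (format == "mtx") {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("read_expression: the Matrix package is required for mtx input")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_file)
    colnames(m) <- readLines(col_file)
    return(validate_expression(m))
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("read_expression: malformed header in ", path)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1], is.numeric, TRUE))
    stop("read_expression: non-numeric values in column(s): ",
         paste(names(dt)[-1][bad], collapse = ", "))
  }
  rownames(m) <- genes
  if (transpose) m <- t(m)
  message("read_expression: ", nrow(m), " genes x ", ncol(m), " samples from ", path)
  validate_expression(m)
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix genes x samples.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  dt <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a clinical table with survival
#'
#' Tab-separated with required columns `sample_id`, `os_months`,
#' `os_event`; any further columns (grade, 1p/19q status, IDH status,
#' age, sex, ...) are returned as clinical covariates.
#'
#' @param path file path.
#' @return list with `survival` (a [survival_data]) and `clinical`
#'   (data frame of the remaining columns, keyed by `sample_id`).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("read_clinical: file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("sample_id", "os_months", "os_event")
  if (!all(req %in% names(dt)))
    stop("read_clinical: missing required column(s): ",
         paste(setdiff(req, names(dt)), collapse = ", "))
  bad <- which(!is.finite(dt$os_months) | dt$os_months <= 0)
  if (length(bad) > 0)
    stop("read_clinical: non-positive os_months at data row(s): ",
         paste(bad, collapse = ", "))
  surv <- survival_data(dt$sample_id, dt$os_months, dt$os_event)
  clin <- dt[, setdiff(names(dt), c("os_months", "os_event")), drop = FALSE]
  list(survival = surv, clinical = clin)
}

#' Write a survival table as TSV
#'
#' Columns `sample_id`, `os_months`, `os_event` plus any clinical columns.
#'
#' @param surv a [survival_data].
#' @param path output path.
#' @param clinical optional clinical data frame with `sample_id`.
#' @export
write_clinical <- function(surv, path, clinical = NULL) {
  out <- data.frame(sample_id = surv$sample_id, os_months = surv$time,
                    os_event = surv$event, stringsAsFactors = FALSE)
  if (!is.null(clinical))
    out <- merge(out, clinical, by = "sample_id", sort = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of normalized unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("read_gene_list: file not found: ", path)
  g <- normalize_symbols(readLines(path))
  g <- g[nzchar(g)]
  unique(g)
}

#' Write / read a pair table as two-column TSV
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param path file path.
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(pairs[, c("gene_a", "gene_b")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  canonical_pairs(dt)
}

#' Serialize / restore a signature model as JSON
#'
#' Full-precision JSON with pairs, coefficients, penalty, CV settings,
#' seed and cutoff, so a published signature can be re-applied verbatim.
#'
#' @param model an `igp_signature`.
#' @param path file path.
#' @export
write_signature <- function(model, path) {
  obj <- list(pairs = model$pairs, betas = model$betas,
              lambda = model$lambda, lambda_rule = model$lambda_rule,
              cv_folds = model$cv_folds, cv_repeats = model$cv_repeats,
              seed = model$seed, cutoff = model$cutoff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- new_signature(obj$pairs, obj$betas,
                         cutoff = obj$cutoff %||% NA_real_)
  for (f in c("lambda", "lambda_rule", "cv_folds", "cv_repeats", "seed"))
    model[[f]] <- obj[[f]]
  model
}

#' Serialize / restore a nomogram model as JSON
#'
#' @param model an `igp_nomogram`.
#' @param path file path.
#' @export
write_nomogram <- function(model, path) {
  obj <- list(betas = as.list(model$betas), encodings = model$encodings,
              baseline = model$baseline, lp_center = model$lp_center,
              point_ref = as.list(model$point_ref),
              point_denom = model$point_denom, horizons = model$horizons,
              ranges = as.list(model$ranges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_nomogram
#' @export
read_nomogram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fit = NULL, betas = unlist(obj$betas),
                 encodings = lapply(obj$encodings, function(e)
                   list(type = e$type, levels = e$levels)),
                 baseline = as.data.frame(obj$baseline),
                 lp_center = obj$lp_center, point_ref = unlist(obj$point_ref),
                 point_denom = obj$point_denom, horizons = obj$horizons,
                 ranges = unlist(obj$ranges)), class = "igp_nomogram")
}

# small stable content fingerprint (polynomial rolling hash over the
# serialized text) used in run manifests; not cryptographic.
fingerprint <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, vec.len = 1e6)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
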