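#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted; symbols must already be on a shared nomenclature.
#'
#' @param genes character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(genes) {
  toupper(trimws(as.character(genes)))
}

pair_keys <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "|")

#' Enumerate all unordered gene pairs
#'
#' All n(n-1)/2 unordered pairs of distinct symbols in canonical
#' lexicographic orientation (`gene_a < gene_b`), deterministically
#' ordered by `gene_a` then `gene_b`. For the curated immune list of
#' 2,214 symbols this yields 2,449,791 pairs.
#'
#' @param genes character vector of >= 2 unique gene symbols
#'   (normalized with [normalize_symbols()]).
#' @return data frame with columns `gene_a`, `gene_b`.
#' @examples
#' enumerate_pairs(c("B", "A", "C"))
#' @export
enumerate_pairs <- function(genes) {
  genes <- normalize_symbols(genes)
  if (anyDuplicated(genes))
    stop("enumerate_pairs: duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  n <- length(genes)
  if (n < 2L) stop("enumerate_pairs: need at least 2 genes")
  g <- sort(genes, method = "radix")
  reps <- (n - 1L):1L
  ia <- rep.int(seq_len(n - 1L), reps)
  ib <- ia + sequence(reps)
  data.frame(gene_a = g[ia], gene_b = g[ib], stringsAsFactors = FALSE)
}

#' Canonicalize a pair table
#'
#' Normalizes symbols, orients each pair lexicographically and sorts the
#' table into the canonical enumeration order.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @return canonical pair data frame.
#' @export
canonical_pairs <- function(pairs) {
  a <- normalize_symbols(pairs$gene_a)
  b <- normalize_symbols(pairs$gene_b)
  if (any(a == b)) stop("canonical_pairs: self-pair (gene_a == gene_b)")
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(pair_keys(out))) stop("canonical_pairs: duplicate pairs")
  out
}

#' Binarize expression into gene-pair ordering indicators
#'
#' The immune gene-pair (IGP) score of pair (a, b) in a sample is 1 when
#' the expression of `gene_a` strictly exceeds that of `gene_b` in that
#' sample, else 0 (ties score 0). The score depends only on the
#' within-sample ordering, so it is invariant under any strictly
#' increasing transform applied to a sample's expression column —
#' RNA-seq, microarray and qPCR-scale cohorts binarize identically.
#'
#' Processing is blocked over pairs so very large pair sets (millions of
#' pairs) never materialize intermediate matrices larger than
#' `block_size` x n_samples.
#'
#' @param expr numeric expression matrix, genes x samples, with rownames
#'   gene symbols and colnames sample ids; no missing values.
#' @param pairs data frame with `gene_a`, `gene_b` columns (canonical
#'   orientation).
#' @param on_missing `"error"` (default) stops naming genes absent from
#'   `expr`; `"drop"` silently removes pairs referencing absent genes.
#' @param block_size number of pairs scored per block.
#' @return An object of class `igp_matrix`: list with `pairs` (the scored
#'   pair table), `sample_ids` and `scores` (integer 0/1 matrix,
#'   pairs x samples). The attribute `tie_fraction` records the fraction
#'   of scored (pair, sample) cells that were expression ties.
#' @export
binarize <- function(expr, pairs, on_missing = c("error", "drop"),
                     block_size = 200000L) {
  on_missing <- match.arg(on_missing)
  expr <- validate_expression(expr)
  present <- pairs$gene_a %in% rownames(expr) & pairs$gene_b %in% rownames(expr)
  if (!all(present)) {
    if (on_missing == "error") {
      missing_genes <- setdiff(unique(c(pairs$gene_a[!present],
                                        pairs$gene_b[!present])),
                               rownames(expr))
      stop("binarize: genes absent from expression matrix: ",
           paste(utils::head(missing_genes, 10), collapse = ", "))
    }
    pairs <- pairs[present, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  np <- nrow(pairs); ns <- ncol(expr)
  if (np == 0L) stop("binarize: no scorable pairs")
  scores <- matrix(0L, nrow = np, ncol = ns,
                   dimnames = list(pair_keys(pairs), colnames(expr)))
  n_ties <- 0
  starts <- seq(1L, np, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, np)
    ea <- expr[pairs$gene_a[s:e], , drop = FALSE]
    eb <- expr[pairs$gene_b[s:e], , drop = FALSE]
    blk <- ea > eb
    storage.mode(blk) <- "integer"
    scores[s:e, ] <- blk
    n_ties <- n_ties + sum(ea == eb)
  }
  structure(list(pairs = pairs, sample_ids = colnames(expr), scores = scores),
            tie_fraction = n_ties / (as.double(np) * ns),
            class = "igp_matrix")
}

#' @export
print.igp_matrix <- function(x, ...) {
  cat(sprintf("igp_matrix: %d pairs x %d samples (tie fraction %.3g)\n",
              nrow(x$scores), ncol(x$scores),
              attr(x, "tie_fraction") %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset an igp_matrix to a pair table (by key), preserving class/attrs
igp_subset <- function(igp, pairs) {
  idx <- match(pair_keys(pairs), pair_keys(igp$pairs))
  if (anyNA(idx)) stop("igp_subset: pairs not present in igp_matrix")
  structure(list(pairs = pairs, sample_ids = igp$sample_ids,
                 scores = igp$scores[idx, , drop = FALSE]),
            tie_fraction = attr(igp, "tie_fraction"), class = "igp_matrix")
}

# subset an igp_matrix to a set of samples
igp_samples <- function(igp, ids) {
  idx <- match(ids, igp$sample_ids)
  if (anyNA(idx)) stop("igp_samples: unknown sample ids")
  structure(list(pairs = igp$pairs, sample_ids = ids,
                 scores = igp$scores[, idx, drop = FALSE]),
            tie_fraction = attr(igp, "tie_fraction"), class = "igp_matrix")
}

#' Per-pair score-1 fractions, streamed in blocks
#'
#' Computes, for every pair, the fraction of samples scoring 1, without
#' retaining the full binary matrix — the memory-bounded path for
#' filtering millions of candidate pairs.
#'
#' @inheritParams binarize
#' @return numeric vector of score-1 fractions, one per pair.
#' @export
score_fractions <- function(expr, pairs, block_size = 200000L) {
  expr <- validate_expression(expr)
  np <- nrow(pairs)
  out <- numeric(np)
  starts <- seq(1L, np, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, np)
    out[s:e] <- rowMeans(expr[pairs$gene_a[s:e], , drop = FALSE] >
                         expr[pairs$gene_b[s:e], , drop = FALSE])
  }
  out
}

#' Remove unevenly distributed pairs
#'
#' A pair is retained only when neither score value dominates: the
#' fraction of 1s and the fraction of 0s must both be at most
#' `max_fraction`. "Over 95%" is strict — a pair at exactly the
#' threshold is retained.
#'
#' @param igp an `igp_matrix`, or a numeric vector of score-1 fractions
#'   (as returned by [score_fractions()]) together with `pairs`.
#' @param max_fraction retention threshold (default 0.95).
#' @param pairs pair table, required when `igp` is a fraction vector.
#' @return list with `retained` (pair data frame), `removed` (pair data
#'   frame), and `fractions` (score-1 fraction per input pair).
#' @export
filter_uneven <- function(igp, max_fraction = 0.95, pairs = NULL) {
  if (inherits(igp, "igp_matrix")) {
    fr <- rowMeans(igp$scores)
    pairs <- igp$pairs
  } else {
    fr <- igp
    if (is.null(pairs) || length(fr) != nrow(pairs))
      stop("filter_uneven: fraction vector requires a matching pair table")
  }
  keep <- fr <= max_fraction & (1 - fr) <= max_fraction
  res <- list(retained = pairs[keep, , drop = FALSE],
              removed = pairs[!keep, , drop = FALSE],
              fractions = fr)
  rownames(res$retained) <- NULL
  rownames(res$removed) <- NULL
  if (nrow(res$retained) == 0L)
    message("filter_uneven: no pairs retained")
  res
}

#' Intersect retained pair sets across cohorts
#'
#' Exact set intersection of per-cohort pair tables, preserving the
#' canonical ordering of the first cohort.
#'
#' @param pair_sets list (>= 2) of pair data frames.
#' @return pair data frame present in every cohort (possibly empty; an
#'   empty intersection is reported with a message and halts the
#'   end-to-end workflow).
#' @export
intersect_available <- function(pair_sets) {
  if (length(pair_sets) < 2L) stop("intersect_available: need >= 2 cohorts")
  keys <- lapply(pair_sets, pair_keys)
  common <- Reduce(intersect, keys)
  out <- pair_sets[[1]][keys[[1]] %in% common, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    message("intersect_available: no pair is retained in every cohort")
  out
}
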