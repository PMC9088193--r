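#' Construct a validated survival table
#'
#' A `survival_data` object is a data frame with columns `sample_id`,
#' `time` (overall survival in months, strictly positive) and `event`
#' (1 = death observed, 0 = censored). All downstream survival machinery
#' in the package consumes this type.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param time positive numeric vector, overall survival in months.
#' @param event integer/numeric vector in \{0, 1\}; 1 = death observed.
#' @return A data frame of class `survival_data`.
#' @examples
#' survival_data(paste0("s", 1:4), c(12, 30, 7, 48), c(1, 0, 1, 1))
#' @export
survival_data <- function(sample_id, time, event) {
  if (length(sample_id) == 0L) stop("survival_data: no records supplied")
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop("survival_data: sample_id, time and event must have equal length")
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("survival_data: duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyNA(time) || any(time <= 0))
    stop("survival_data: survival time must be positive and non-missing")
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop("survival_data: event indicator must be 0 (censored) or 1 (death)")
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_data", "data.frame")
  out
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("survival_data: %d samples, %d events, median follow-up %.1f months\n",
              nrow(x), sum(x$event), stats::median(x$time)))
  NextMethod()
}

as_survival_data <- function(x) {
  if (inherits(x, "survival_data")) return(x)
  survival_data(x$sample_id, x$time, x$event)
}

# subset rows of a survival_data by sample id, preserving class
subset_surv <- function(surv, ids) {
  keep <- match(ids, surv$sample_id)
  if (anyNA(keep)) stop("subset_surv: unknown sample ids")
  out <- surv[keep, , drop = FALSE]
  class(out) <- c("survival_data", "data.frame")
  out
}
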