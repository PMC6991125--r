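#' A single replicate's count time series
#'
#' The unit of curve fitting: timed cell counts for one culture replicate,
#' with its treatment metadata (host, bacterial inoculum, vitamin level,
#' replicate id).
#'
#' @param times hours since inoculation; strictly increasing, `>= 0`.
#' @param counts cell counts (cells per microlitre); strictly positive, so
#'   the natural-log transform is always defined.
#' @param host,inoculum,vitamin treatment labels (character scalars).
#' @param replicate replicate identifier.
#' @return A list of class `"count_series"`.
#' @examples
#' s <- count_series(c(0, 24, 96), c(5, 12, 80), host = "KBDT20",
#'                   inoculum = "control", vitamin = "replete", replicate = 1)
#' @export
count_series <- function(times, counts, host = "host", inoculum = "control",
                         vitamin = "replete", replicate = 1L) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts) || length(times) < 1L) {
    stop_churchill("invalid_series",
                   "times and counts must have equal length >= 1")
  }
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0)) {
    stop_churchill("invalid_series",
                   "times must be finite, >= 0, strictly increasing")
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop_churchill("invalid_count",
                   "counts must be finite and strictly positive")
  }
  structure(list(times = times, counts = counts,
                 host = as.character(host), inoculum = as.character(inoculum),
                 vitamin = as.character(vitamin),
                 replicate = as.character(replicate)),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("Count series: %s / %s / %s / rep %s\n",
              x$host, x$inoculum, x$vitamin, x$replicate))
  cat(sprintf("  %d timepoints over %g-%g h; counts %g-%g cells/uL\n",
              length(x$times), min(x$times), max(x$times),
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
as.data.frame.count_series <- function(x, ...) {
  data.frame(host = x$host, inoculum = x$inoculum, vitamin = x$vitamin,
             replicate = x$replicate, time_h = x$times,
             count_per_uL = x$counts, stringsAsFactors = FALSE)
}

series_label <- function(x) {
  paste(x$host, x$inoculum, x$vitamin, x$replicate, sep = " / ")
}
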