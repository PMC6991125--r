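#' Maximum abundance of a replicate
#'
#' The peak statistic used as the "carrying capacity" response: the best
#' mean over all windows of three consecutive timepoints.  By default the
#' mean is taken on the natural-log scale (`type = "mean_ln"`, consistent
#' with all analyses being run on ln-transformed counts); `type =
#' "ln_mean"` instead takes the ln of the mean of the raw counts in the
#' window.  Ties go to the earliest window.
#'
#' @param x a [count_series()] or a numeric vector of counts.
#' @param type `"mean_ln"` (default) or `"ln_mean"`; see Details.
#' @param ... unused.
#' @return Maximum abundance in ln(cells per microlitre).
#' @examples
#' max_abundance(c(1, 5, 9, 10, 8, 2))  # mean(log(c(9, 10, 8)))
#' @export
max_abundance <- function(x, ...) UseMethod("max_abundance")

#' @rdname max_abundance
#' @export
max_abundance.count_series <- function(x, type = c("mean_ln", "ln_mean"), ...) {
  max_abundance(x$counts, type = type)
}

#' @rdname max_abundance
#' @export
max_abundance.default <- function(x, type = c("mean_ln", "ln_mean"), ...) {
  type <- match.arg(type)
  counts <- as.numeric(x)
  if (length(counts) < 3L) {
    stop_churchill("insufficient_data",
                   "at least 3 timepoints required, got %d", length(counts))
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop_churchill("invalid_count", "counts must be positive and finite")
  }
  n <- length(counts)
  wins <- vapply(seq_len(n - 2L), function(i) {
    w <- counts[i:(i + 2L)]
    if (type == "mean_ln") mean(log(w)) else log(mean(w))
  }, 0)
  max(wins)
}

#' Per-replicate derived responses
#'
#' Assembles the three responses used in downstream inference for one
#' replicate: the growth exponent and decline exponent from the
#' Churchill-Usagi fit, and the maximum abundance computed directly from
#' the data (not a fit output).
#'
#' @param series the [count_series()] the fit was produced from.
#' @param fit the matching [churchill_fit()].
#' @param type passed to [max_abundance()].
#' @return A one-row data frame with columns `host`, `inoculum`,
#'   `vitamin`, `replicate`, `growth`, `max_abundance`, `decline`,
#'   `fit_converged`.
#' @export
summarize_replicate <- function(series, fit, type = c("mean_ln", "ln_mean")) {
  if (!inherits(fit, "churchill_fit")) {
    stop_churchill("consistency", "fit must be a churchill_fit")
  }
  fs <- fit$series
  same <- identical(fs$host, series$host) &&
    identical(fs$inoculum, series$inoculum) &&
    identical(fs$vitamin, series$vitamin) &&
    identical(fs$replicate, series$replicate)
  if (!same) {
    stop_churchill("consistency",
                   "series and fit metadata disagree (%s vs %s)",
                   series_label(series), series_label(fs))
  }
  p <- coef(fit)
  data.frame(host = series$host, inoculum = series$inoculum,
             vitamin = series$vitamin, replicate = series$replicate,
             growth = unname(p["lambda1"]),
             max_abundance = max_abundance(series, type = type),
             decline = unname(p["lambda2"]),
             fit_converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Fit every replicate in a count table
#'
#' Convenience wrapper over the whole pipeline front end: fits each
#' replicate's series and collects the per-replicate parameter table that
#' feeds [build_impact_tables()].
#'
#' @param series_list a list of [count_series()], e.g. from
#'   [read_count_table()] or [simulate_experiment()].
#' @param control a [fit_control()].
#' @param type passed to [max_abundance()].
#' @param warn_nonconverged warn (with the replicate label) when a fit
#'   does not converge; such replicates are retained in the table but
#'   flagged, and inference excludes them.
#' @return A data frame of per-replicate parameters, one row per series.
#' @export
fit_replicates <- function(series_list, control = fit_control(),
                           type = c("mean_ln", "ln_mean"),
                           warn_nonconverged = TRUE) {
  if (!length(series_list)) {
    stop_churchill("insufficient_data", "no series supplied")
  }
  rows <- lapply(series_list, function(s) {
    fit <- churchill_fit(s, control = control)
    if (warn_nonconverged && !fit$converged) {
      warning(sprintf("fit did not converge for %s; flagged for exclusion",
                      series_label(s)), call. = FALSE)
    }
    summarize_replicate(s, fit, type = type)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
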