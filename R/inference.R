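#' Saturated cell-means model for per-replicate responses
#'
#' Fits the linear model used for treatment inference: one mean per
#' design cell (the saturated factorial model) with a pooled residual
#' variance.  For one host and one response this is the model behind the
#' estimated-marginal-means contrasts; with a single factor it is the
#' classical one-way ANOVA layout used for the bacterial broth-growth
#' comparisons.
#'
#' @param table a per-replicate parameter data frame (see
#'   [fit_replicates()]); rows with `fit_converged == FALSE` are excluded
#'   listwise.
#' @param response name of the response column, typically one of
#'   `"growth"`, `"max_abundance"`, `"decline"`.
#' @param host restrict the table to this host label; required when the
#'   table contains several hosts.
#' @param factors names of the design factor columns; default the
#'   inoculum-by-vitamin layout.
#' @param min_reps minimum replicates per cell (default 2, so a within-cell
#'   variance exists).
#' @return An object of class `"cell_means"`: `cells` (factor levels,
#'   `mean`, `n` per cell), `sigma2` (pooled residual variance), `df`
#'   (residual degrees of freedom), `response`, `host`, `factors`.
#' @examples
#' d <- data.frame(inoculum = rep(c("A", "B"), each = 3),
#'                 vitamin = "replete",
#'                 growth = c(1, 2, 3, 2, 3, 4))
#' m <- cell_means(d, "growth", factors = c("inoculum", "vitamin"))
#' m$sigma2   # pooled variance 1
#' @export
cell_means <- function(table, response, host = NULL,
                       factors = c("inoculum", "vitamin"), min_reps = 2L) {
  if (!response %in% names(table)) {
    stop_churchill("specification", "response column '%s' not found", response)
  }
  if (!all(factors %in% names(table))) {
    stop_churchill("specification", "missing factor column(s): %s",
                   paste(setdiff(factors, names(table)), collapse = ", "))
  }
  if (!is.null(host)) table <- table[table$host == host, , drop = FALSE]
  if ("host" %in% names(table) && length(unique(table$host)) > 1L) {
    stop_churchill("specification",
                   "table spans several hosts; supply `host`")
  }
  if ("fit_converged" %in% names(table)) {
    table <- table[table$fit_converged, , drop = FALSE]
  }
  if (!nrow(table)) {
    stop_churchill("insufficient_replication", "no usable replicates")
  }
  y <- table[[response]]
  key <- interaction(table[factors], drop = TRUE, lex.order = TRUE)
  cells <- unique(table[factors])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rownames(cells) <- NULL
  ckey <- interaction(cells[factors], drop = TRUE, lex.order = TRUE)
  idx <- match(key, ckey)
  cells$n <- as.integer(tabulate(idx, nbins = nrow(cells)))
  if (any(cells$n < min_reps)) {
    bad <- cells[cells$n < min_reps, factors, drop = FALSE]
    stop_churchill("insufficient_replication",
                   "cell(s) with fewer than %d replicates: %s", min_reps,
                   paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "))
  }
  cells$mean <- as.numeric(tapply(y, idx, mean))
  within_ss <- sum(tapply(y, idx, function(v) sum((v - mean(v))^2)))
  df <- length(y) - nrow(cells)
  structure(list(cells = cells, sigma2 = within_ss / df, df = df,
                 n_obs = length(y), response = response,
                 host = if (is.null(host)) unique(table$host)[1] else host,
                 factors = factors),
            class = "cell_means")
}

#' @export
print.cell_means <- function(x, digits = 4, ...) {
  cat(sprintf("Cell-means model: response '%s'%s\n", x$response,
              if (!is.null(x$host) && !is.na(x$host))
                paste0(", host ", x$host) else ""))
  print(format(x$cells, digits = digits), row.names = FALSE)
  cat(sprintf("Pooled residual variance %.4g on %d df\n", x$sigma2, x$df))
  invisible(x)
}

#' @export
summary.cell_means <- function(object, ...) {
  # omnibus F of the cell-means model against the grand mean
  cells <- object$cells
  gm <- sum(cells$mean * cells$n) / sum(cells$n)
  ss_between <- sum(cells$n * (cells$mean - gm)^2)
  df_between <- nrow(cells) - 1L
  f <- (ss_between / df_between) / object$sigma2
  p <- stats::pf(f, df_between, object$df, lower.tail = FALSE)
  out <- object
  out$F <- f; out$df_between <- df_between; out$p_value <- p
  class(out) <- "summary.cell_means"
  out
}

#' @export
print.summary.cell_means <- function(x, digits = 4, ...) {
  print.cell_means(x, digits = digits)
  cat(sprintf("Omnibus F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df, x$F, x$p_value))
  invisible(x)
}

match_cells <- function(model, at) {
  keep <- rep(TRUE, nrow(model$cells))
  for (f in names(at)) {
    if (!f %in% model$factors) {
      stop_churchill("specification", "unknown factor '%s'", f)
    }
    keep <- keep & model$cells[[f]] == at[[f]]
  }
  which(keep)
}

#' Estimated marginal means from a cell-means model
#'
#' For a balanced saturated model the marginal mean of a cell is its cell
#' mean with standard error `sqrt(sigma2 / n)`; a margin (a partial
#' specification) is the unweighted average of the matching cell means
#' with the propagated standard error.
#'
#' @param model a [cell_means()] fit.
#' @param at named list or character vector selecting factor levels, e.g.
#'   `c(inoculum = "control")`; factors left out are averaged over.
#'   Empty (default) averages over everything.
#' @return A one-row data frame with `mean`, `se` and `n_cells`.
#' @export
marginal_means <- function(model, at = list()) {
  idx <- match_cells(model, as.list(at))
  if (!length(idx)) {
    stop_churchill("specification", "no design cells match the request")
  }
  cells <- model$cells[idx, , drop = FALSE]
  k <- nrow(cells)
  data.frame(mean = mean(cells$mean),
             se = sqrt(model$sigma2 * sum(1 / cells$n)) / k,
             n_cells = k)
}

# two-sided p for a marginal-means contrast, optionally Tukey-adjusted
contrast_p <- function(tstat, df, k_levels, adjust) {
  p <- 2 * stats::pt(-abs(tstat), df)
  padj <- switch(adjust,
                 none = p,
                 tukey = stats::ptukey(sqrt(2) * abs(tstat), k_levels, df,
                                       lower.tail = FALSE))
  pmin(pmax(padj, p), 1)
}

#' All pairwise marginal-means contrasts of one factor
#'
#' Differences of cell means for every pair of levels of `factor`,
#' conditioned on fixed level(s) of the other factor(s), with pooled-SE t
#' statistics and familywise adjustment.  The family is the set of all
#' pairs among the factor's levels within the conditioning level;
#' `adjust = "tukey"` applies the studentized-range correction (families
#' of size 1 are never adjusted).
#'
#' @param model a [cell_means()] fit.
#' @param factor the factor whose levels are compared.
#' @param within named vector fixing the remaining factor(s), e.g.
#'   `c(vitamin = "deficient")`; may be omitted for one-factor models.
#' @param adjust `"tukey"` (default) or `"none"`.
#' @return A data frame with one row per pair: `a`, `b`, the conditioning
#'   level(s), `mean_a`, `mean_b`, `estimate` (mean_a - mean_b), `se`,
#'   `t`, `df`, `p_value`, `adj_p`, `adjust`, `family_size`.
#' @export
pairwise_contrasts <- function(model, factor, within = NULL,
                               adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  if (!factor %in% model$factors) {
    stop_churchill("specification", "unknown factor '%s'", factor)
  }
  idx <- match_cells(model, as.list(within))
  cells <- model$cells[idx, , drop = FALSE]
  if (anyDuplicated(cells[[factor]])) {
    stop_churchill("specification",
                   "conditioning level does not isolate one cell per level of '%s'",
                   factor)
  }
  lev <- cells[[factor]]
  k <- length(lev)
  if (k < 2L) {
    stop_churchill("specification",
                   "factor '%s' needs >= 2 levels within the conditioning level",
                   factor)
  }
  pairs <- utils::combn(seq_len(k), 2L)
  m <- ncol(pairs)
  est <- cells$mean[pairs[1, ]] - cells$mean[pairs[2, ]]
  se <- sqrt(model$sigma2 * (1 / cells$n[pairs[1, ]] + 1 / cells$n[pairs[2, ]]))
  tstat <- est / se
  eff_adjust <- if (m > 1L) adjust else "none"
  out <- data.frame(a = lev[pairs[1, ]], b = lev[pairs[2, ]],
                    mean_a = cells$mean[pairs[1, ]],
                    mean_b = cells$mean[pairs[2, ]],
                    estimate = est, se = se, t = tstat, df = model$df,
                    p_value = 2 * stats::pt(-abs(tstat), model$df),
                    adj_p = contrast_p(tstat, model$df, k, eff_adjust),
                    adjust = eff_adjust, family_size = m,
                    stringsAsFactors = FALSE)
  if (length(within)) {
    for (f in names(within)) out[[f]] <- within[[f]]
  }
  out
}

#' Vitamin-effect contrast within one inoculation state
#'
#' The replete-minus-deficient difference of cell means for a fixed
#' inoculum; a family of size 1, so no multiplicity adjustment.
#'
#' @param model a [cell_means()] fit over `inoculum` and `vitamin`.
#' @param inoculum the inoculation state to condition on.
#' @param replete,deficient the vitamin-level labels.
#' @return A one-row data frame shaped like [pairwise_contrasts()] output.
#' @export
vitamin_contrast <- function(model, inoculum, replete = "replete",
                             deficient = "deficient") {
  idx <- match_cells(model, list(inoculum = inoculum))
  cells <- model$cells[idx, , drop = FALSE]
  ia <- which(cells$vitamin == replete)
  ib <- which(cells$vitamin == deficient)
  if (length(ia) != 1L || length(ib) != 1L) {
    stop_churchill("specification",
                   "both vitamin levels must be present for inoculum '%s'",
                   inoculum)
  }
  est <- cells$mean[ia] - cells$mean[ib]
  se <- sqrt(model$sigma2 * (1 / cells$n[ia] + 1 / cells$n[ib]))
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), model$df)
  data.frame(a = replete, b = deficient, inoculum = inoculum,
             mean_a = cells$mean[ia], mean_b = cells$mean[ib],
             estimate = est, se = se, t = tstat, df = model$df,
             p_value = p, adj_p = p, adjust = "none", family_size = 1L,
             stringsAsFactors = FALSE)
}

#' Percent impact of an effector condition
#'
#' The effect metric reported in the treatment tables: the difference
#' between the effector-condition mean and the default-condition mean,
#' as a percentage of the average of the two,
#' \deqn{100\,\frac{\bar x_{\mathrm{eff}} - \bar x_{\mathrm{def}}}
#'   {(\bar x_{\mathrm{eff}} + \bar x_{\mathrm{def}})/2}.}
#' Bounded by (-200, 200) when both means are positive; antisymmetric in
#' its arguments; invariant to rescaling both means.
#'
#' @param effector_mean,default_mean condition means (vectorised).
#' @return Percent impact.
#' @examples
#' impact_percent(3, 1)   # 100
#' @export
impact_percent <- function(effector_mean, default_mean) {
  avg <- (effector_mean + default_mean) / 2
  if (any(avg == 0)) {
    stop_churchill("undefined_impact",
                   "impact undefined when the two means average to zero")
  }
  100 * (effector_mean - default_mean) / avg
}

#' Classify an impact as beneficial or detrimental
#'
#' Increased growth or maximum abundance is beneficial and decreased is
#' detrimental; for the decline exponent the directions flip (a faster
#' decline harms the host).  A zero estimate is `"none"`.
#'
#' @param response one of `"growth"`, `"max_abundance"`, `"decline"`.
#' @param estimate the signed effect (estimate or percent impact);
#'   vectorised.
#' @return `"beneficial"`, `"detrimental"` or `"none"` per element.
#' @export
classify_direction <- function(response, estimate) {
  if (!all(response %in% c("growth", "max_abundance", "decline"))) {
    stop_churchill("specification", "unknown response '%s'",
                   paste(setdiff(response, c("growth", "max_abundance",
                                             "decline")), collapse = ", "))
  }
  s <- sign(estimate)
  flip <- response == "decline"
  s[flip] <- -s[flip]
  out <- rep("none", length(s))
  out[s > 0] <- "beneficial"
  out[s < 0] <- "detrimental"
  out
}

#' Treatment impact report tables
#'
#' Runs the full factorial inference over every host and response and
#' assembles the three report tables: inoculation-versus-control
#' contrasts within each vitamin level, inoculation-versus-inoculation
#' contrasts within each vitamin level, and vitamin contrasts within each
#' inoculation state.  Each row carries the percent impact computed from
#' the two condition means, the multiplicity-adjusted p-value, and a
#' beneficial/detrimental classification.
#'
#' @param table a per-replicate parameter data frame
#'   ([fit_replicates()] output or equivalent) covering one or more
#'   hosts; non-converged fits are excluded.
#' @param alpha significance level for the filtered tables (default
#'   0.05).
#' @param adjust multiplicity adjustment for the inoculation families
#'   (`"tukey"` default, `"none"`).
#' @param control_label,replete_label,deficient_label design vocabulary.
#' @param responses response columns to analyse.
#' @return An object of class `"impact_tables"`: `full` and
#'   `significant` (each a list of data frames `inoculation`, `pairwise`,
#'   `vitamin`), and `alpha`.  Rows are ordered by host, response and
#'   comparison.
#' @export
build_impact_tables <- function(table, alpha = 0.05,
                                adjust = c("tukey", "none"),
                                control_label = "control",
                                replete_label = "replete",
                                deficient_label = "deficient",
                                responses = c("growth", "max_abundance",
                                              "decline")) {
  adjust <- match.arg(adjust)
  if (!(alpha > 0 && alpha <= 1)) {
    stop_churchill("configuration", "alpha must be in (0, 1]")
  }
  hosts <- unique(table$host)
  inoc_rows <- list(); pair_rows <- list(); vit_rows <- list()
  for (h in hosts) {
    for (resp in responses) {
      model <- cell_means(table, resp, host = h)
      vits <- unique(model$cells$vitamin)
      for (v in vits) {
        pc <- pairwise_contrasts(model, "inoculum",
                                 within = c(vitamin = v), adjust = adjust)
        # orient control comparisons as inoculum (effector) vs control
        is_ctrl <- pc$a == control_label | pc$b == control_label
        ctrl <- pc[is_ctrl, , drop = FALSE]
        if (nrow(ctrl)) {
          swap <- ctrl$a == control_label
          tmp_a <- ctrl$a[swap]; tmp_ma <- ctrl$mean_a[swap]
          ctrl$a[swap] <- ctrl$b[swap]; ctrl$mean_a[swap] <- ctrl$mean_b[swap]
          ctrl$b[swap] <- tmp_a; ctrl$mean_b[swap] <- tmp_ma
          ctrl$estimate[swap] <- -ctrl$estimate[swap]
          ctrl$t[swap] <- -ctrl$t[swap]
          inoc_rows[[length(inoc_rows) + 1L]] <-
            finish_rows(ctrl, h, resp)
        }
        rest <- pc[!is_ctrl, , drop = FALSE]
        if (nrow(rest)) {
          pair_rows[[length(pair_rows) + 1L]] <- finish_rows(rest, h, resp)
        }
      }
      inocs <- unique(model$cells$inoculum)
      for (ino in inocs) {
        vc <- tryCatch(vitamin_contrast(model, ino, replete = replete_label,
                                        deficient = deficient_label),
                       churchill_specification = function(e) NULL)
        if (!is.null(vc)) {
          vit_rows[[length(vit_rows) + 1L]] <- finish_rows(vc, h, resp)
        }
      }
    }
  }
  full <- list(inoculation = bind_ordered(inoc_rows),
               pairwise = bind_ordered(pair_rows),
               vitamin = bind_ordered(vit_rows))
  full <- lapply(full, function(d) {
    d$significant <- if (nrow(d)) d$adj_p < alpha else logical(0)
    d
  })
  sig <- lapply(full, function(d) d[d$significant, , drop = FALSE])
  structure(list(full = full, significant = sig, alpha = alpha),
            class = "impact_tables")
}

finish_rows <- function(d, host, resp) {
  d$host <- host
  d$response <- resp
  d$impact_percent <- impact_percent(d$mean_a, d$mean_b)
  d$direction <- classify_direction(d$response, d$estimate)
  d
}

bind_ordered <- function(rows) {
  cols <- c("host", "response", "a", "b", "vitamin", "inoculum",
            "mean_a", "mean_b", "estimate", "se", "t", "df", "p_value",
            "adj_p", "adjust", "family_size", "impact_percent", "direction")
  if (!length(rows)) {
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols)))
  }
  d <- do.call(rbind, rows)
  d <- d[, intersect(cols, names(d)), drop = FALSE]
  d <- d[order(d$host, d$response, d$a, d$b), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @export
print.impact_tables <- function(x, digits = 3, ...) {
  cat(sprintf("Impact tables (alpha = %g)\n", x$alpha))
  show <- c(inoculation = "Inoculation vs control (within vitamin level)",
            pairwise = "Inoculation vs inoculation (within vitamin level)",
            vitamin = "Vitamin effect (within inoculation state)")
  for (nm in names(show)) {
    d <- x$significant[[nm]]
    cat("\n", show[[nm]], ": ", nrow(d), " significant of ",
        nrow(x$full[[nm]]), " comparisons\n", sep = "")
    if (nrow(d)) {
      keep <- intersect(c("host", "response", "a", "b", "vitamin", "inoculum",
                          "impact_percent", "adj_p", "direction"), names(d))
      dd <- d[keep]
      dd$impact_percent <- round(dd$impact_percent)
      dd$adj_p <- signif(dd$adj_p, 2)
      print(format(dd, digits = digits), row.names = FALSE)
    }
  }
  invisible(x)
}
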