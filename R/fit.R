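#' Control settings for Churchill-Usagi fitting
#'
#' @param reltol relative convergence tolerance on the residual sum of
#'   squares.
#' @param gradtol gradient-based convergence tolerance.
#' @param maxit maximum solver iterations per start.
#' @param restarts number of starts: one deterministic start from
#'   [initial_guess()] plus `restarts - 1` multiplicatively jittered
#'   starts (factors uniform in \[0.5, 2\], seeded).
#' @param restart_seed seed for the jittered restarts; fitting is
#'   deterministic given these options.
#' @param min_obs minimum observations required to attempt a fit; at least
#'   4 (one per parameter).
#' @param rate_floor smallest identifiable exponent (per hour); fitted
#'   rates at or below it are flagged as boundary estimates.
#' @return A list of class `"churchill_control"`.
#' @export
fit_control <- function(reltol = 1e-10, gradtol = 1e-8, maxit = 500,
                        restarts = 5, restart_seed = 20317, min_obs = 5,
                        rate_floor = 1e-4) {
  if (reltol <= 0 || gradtol <= 0) {
    stop_churchill("configuration", "tolerances must be > 0")
  }
  if (restarts < 1) stop_churchill("configuration", "restarts must be >= 1")
  if (min_obs < 4) stop_churchill("configuration", "min_obs must be >= 4")
  structure(list(reltol = reltol, gradtol = gradtol, maxit = maxit,
                 restarts = as.integer(restarts),
                 restart_seed = as.integer(restart_seed),
                 min_obs = as.integer(min_obs), rate_floor = rate_floor),
            class = "churchill_control")
}

# run code with the global RNG state untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Data-driven starting values for the Churchill-Usagi fit
#'
#' Heuristic initialisation from a count series.  On the ln-count scale
#' the curve approaches `K1*exp(lambda1*t)` early and `K2*exp(-lambda2*t)`
#' late, so: `lambda1` comes from the secant of `log(ln count)` over the
#' first pre-peak timepoints; `K2` and `lambda2` come from a straight-line
#' fit of `log(ln count)` against time over the points from the best
#' 3-point window onward (intercept and negated slope); when no decline
#' is observed the rate falls back to the `rate_floor` and `K2` to the
#' best window mean; and `K1` solves the t=0 identity
#' `1/y0 = 1/K1 + 1/K2` from the first ln count (falling back to `K2/10`
#' when that is not solvable).  All outputs are clipped to be strictly
#' positive (rates are floored at `rate_floor`).
#'
#' @param series a [count_series()].
#' @param control a [fit_control()]; supplies `min_obs` and `rate_floor`.
#' @return A [churchill_params()] starting point.
#' @export
initial_guess <- function(series, control = fit_control()) {
  n <- length(series$times)
  if (n < control$min_obs) {
    stop_churchill("insufficient_data",
                   "series has %d observations; %d required", n, control$min_obs)
  }
  y <- log(series$counts)
  t <- series$times
  win <- vapply(seq_len(n - 2L), function(i) mean(y[i:(i + 2L)]), 0)
  peak_i <- which.max(win) + 1L   # middle of the best window
  maxwin <- max(max(win), 1e-2)

  logy_line <- function(idx) {
    idx <- idx[y[idx] > 0]       # log(ln count) needs ln count > 0
    if (length(idx) < 2L) return(c(NA_real_, NA_real_))
    tt <- t[idx]; zz <- log(y[idx])
    b <- sum((tt - mean(tt)) * (zz - mean(zz))) / sum((tt - mean(tt))^2)
    c(intercept = mean(zz) - b * mean(tt), slope = b)
  }

  # decline regime: intercept gives the envelope scale, slope the rate
  tail_fit <- logy_line(peak_i:n)
  if (!is.na(tail_fit[2]) && -tail_fit[2] > control$rate_floor) {
    lambda2 <- -tail_fit[2]
    K2 <- max(exp(tail_fit[1]), maxwin)
  } else {
    lambda2 <- control$rate_floor
    K2 <- maxwin
  }

  # growth regime: earliest usable secant, least contaminated by decline
  pre <- which(seq_len(n) <= peak_i & y > 0)
  lambda1 <- if (length(pre) >= 2L) {
    max((log(y[pre[2]]) - log(y[pre[1]])) / (t[pre[2]] - t[pre[1]]),
        control$rate_floor)
  } else control$rate_floor

  y0 <- y[1L]
  K1 <- if (y0 > 0 && y0 < K2) 1 / (1 / y0 - 1 / K2) else K2 / 10
  K1 <- max(K1, 1e-2)
  churchill_params(K1, K2, lambda1, lambda2)
}

#' Fit the Churchill-Usagi growth-and-decline curve
#'
#' Nonlinear least squares of a replicate's ln-transformed counts against
#' the Churchill-Usagi curve, minimising
#' \deqn{\sum_i \big(\ln N_i - \ln N(t_i)\big)^2}
#' over strictly positive parameters.  Positivity is enforced by
#' optimising the log-parameters; the solver is Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) with the analytic Jacobian, multi-started from
#' [initial_guess()] plus seeded jittered restarts.  Deterministic given
#' `control`.
#'
#' @param x a [count_series()], a formula such as `count ~ time` (with
#'   `data`), or a numeric vector of times (with `counts`).
#' @param ... passed to methods.
#' @return An object of class `"churchill_fit"` with components `params`
#'   ([churchill_params()]), `se` (per-parameter standard errors from the
#'   Jacobian at the solution), `rss` (residual sum of squares on the ln
#'   scale), `converged`, `boundary` (any rate at the identifiability
#'   floor), `n_obs`, `fitted`, `residuals`, and the input `series`.
#'   Supports `print`, `summary`, `coef`, `vcov`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' truth <- churchill_params(1.8, 12, 0.02, 0.003)
#' tt <- c(0, 24, seq(84, 624, by = 60))
#' s <- count_series(tt, exp(ln_abundance(truth, tt)))
#' fit <- churchill_fit(s)
#' coef(fit)
#' @export
churchill_fit <- function(x, ...) UseMethod("churchill_fit")

#' @rdname churchill_fit
#' @param control a [fit_control()].
#' @export
churchill_fit.count_series <- function(x, control = fit_control(), ...) {
  n <- length(x$times)
  if (n < control$min_obs) {
    stop_churchill("insufficient_data",
                   "series %s has %d observations; %d required",
                   series_label(x), n, control$min_obs)
  }
  fit_core(x, control)
}

#' @rdname churchill_fit
#' @param data a data frame holding the formula's variables; treatment
#'   metadata is taken from columns `host`, `inoculum`, `vitamin`,
#'   `replicate` when present (they must be constant).
#' @export
churchill_fit.formula <- function(x, data, control = fit_control(), ...) {
  mf <- stats::model.frame(x, data)
  counts <- mf[[1L]]
  times <- mf[[2L]]
  meta <- lapply(c(host = "host", inoculum = "inoculum", vitamin = "vitamin",
                   replicate = "replicate"), function(col) {
    if (col %in% names(data)) {
      v <- unique(data[[col]])
      if (length(v) != 1L) {
        stop_churchill("consistency", "column '%s' is not constant", col)
      }
      as.character(v)
    } else NULL
  })
  ord <- order(times)
  s <- count_series(times[ord], counts[ord],
                    host = meta$host %||% "host",
                    inoculum = meta$inoculum %||% "control",
                    vitamin = meta$vitamin %||% "replete",
                    replicate = meta$replicate %||% 1L)
  churchill_fit(s, control = control)
}

#' @rdname churchill_fit
#' @param counts cell counts matching `x` when `x` is a vector of times.
#' @export
churchill_fit.default <- function(x, counts, control = fit_control(), ...) {
  churchill_fit(count_series(x, counts), control = control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_core <- function(series, control) {
  t <- series$times
  y <- log(series$counts)

  resid_fn <- function(theta) y - ln_abundance(exp(theta), t)
  jac_fn <- function(theta) {
    p <- exp(theta)
    -ln_abundance_grad(p, t) * rep(p, each = length(t))
  }
  lm_ctrl <- minpack.lm::nls.lm.control(ftol = control$reltol, ptol = 1e-12,
                                        gtol = control$gradtol,
                                        maxiter = min(control$maxit, 1024L))
  run_start <- function(theta0) {
    tryCatch(minpack.lm::nls.lm(par = theta0, fn = resid_fn, jac = jac_fn,
                                control = lm_ctrl),
             error = function(e) NULL)
  }

  theta0 <- log(unclass(initial_guess(series, control)))
  starts <- list(theta0)
  if (control$restarts > 1L) {
    jit <- with_local_seed(control$restart_seed, {
      matrix(stats::runif(4L * (control$restarts - 1L), 0.5, 2),
             ncol = 4L)
    })
    for (i in seq_len(control$restarts - 1L)) {
      starts[[i + 1L]] <- theta0 + log(jit[i, ])
    }
  }

  best <- NULL
  for (th in starts) {
    res <- run_start(th)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop_churchill("fit_failure", "all solver starts failed for series %s",
                   series_label(series))
  }

  p <- exp(coef(best))
  names(p) <- c("K1", "K2", "lambda1", "lambda2")
  params <- churchill_params(p[1], p[2], p[3], p[4])
  fitted_y <- ln_abundance(params, t)
  rss <- sum((y - fitted_y)^2)
  n <- length(t)
  boundary <- any(p[c("lambda1", "lambda2")] <= control$rate_floor)
  converged <- (best$info %in% 1:4) && !boundary

  # standard errors from the Jacobian in the original parameter scale
  J <- ln_abundance_grad(params, t)
  se <- rep(NA_real_, 4L)
  if (n > 4L) {
    sigma2 <- rss / (n - 4L)
    cv <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) se <- sqrt(diag(cv))
  }
  names(se) <- names(p)

  structure(list(params = params, se = se, rss = rss,
                 converged = converged, boundary = boundary,
                 n_obs = n, fitted = fitted_y, residuals = y - fitted_y,
                 series = series, control = control,
                 info = best$info, message = best$message,
                 niter = best$niter),
            class = "churchill_fit")
}

#' Pooled fit across several replicates
#'
#' Fits one Churchill-Usagi curve to the concatenated points of several
#' replicates (the illustrative all-points fit of a treatment group).
#' Per-replicate fits remain the canonical input to inference; the pooled
#' fit is descriptive only.
#'
#' @param series_list a list of [count_series()] objects.
#' @param control a [fit_control()].
#' @return A `"churchill_fit"` whose `series` holds the pooled points
#'   (sorted by time; replicate id `"pooled"`).
#' @export
churchill_fit_pooled <- function(series_list, control = fit_control()) {
  if (!length(series_list)) {
    stop_churchill("insufficient_data", "no series supplied")
  }
  tt <- unlist(lapply(series_list, `[[`, "times"))
  cc <- unlist(lapply(series_list, `[[`, "counts"))
  ord <- order(tt)
  tt <- tt[ord]; cc <- cc[ord]
  # collapse duplicate timepoints by geometric mean so the series stays valid
  key <- match(tt, unique(tt))
  cc <- tapply(log(cc), key, mean)
  s <- count_series(unique(tt), exp(cc),
                    host = series_list[[1L]]$host,
                    inoculum = series_list[[1L]]$inoculum,
                    vitamin = series_list[[1L]]$vitamin,
                    replicate = "pooled")
  churchill_fit(s, control = control)
}

#' @export
print.churchill_fit <- function(x, digits = 4, ...) {
  cat("Churchill-Usagi fit:", series_label(x$series), "\n")
  print(round(unclass(x$params), digits))
  cat(sprintf("RSS (ln scale): %.4g on %d points; converged: %s%s\n",
              x$rss, x$n_obs, x$converged,
              if (x$boundary) " (rate at identifiability floor)" else ""))
  invisible(x)
}

#' @export
coef.churchill_fit <- function(object, ...) unclass(object$params)

#' @export
vcov.churchill_fit <- function(object, ...) {
  J <- ln_abundance_grad(object$params, object$series$times)
  sigma2 <- object$rss / max(object$n_obs - 4L, 1L)
  solve(crossprod(J)) * sigma2
}

#' @export
fitted.churchill_fit <- function(object, ...) object$fitted

#' @export
residuals.churchill_fit <- function(object, ...) object$residuals

#' @export
summary.churchill_fit <- function(object, ...) {
  tab <- cbind(Estimate = unclass(object$params), `Std. Error` = object$se)
  df <- max(object$n_obs - 4L, 0L)
  structure(list(coefficients = tab, rss = object$rss, df = df,
                 sigma = if (df > 0) sqrt(object$rss / df) else NA_real_,
                 converged = object$converged, boundary = object$boundary,
                 peak = peak_time(object$params),
                 y0 = ln_abundance(object$params, 0),
                 label = series_label(object$series)),
            class = "summary.churchill_fit")
}

#' @export
print.summary.churchill_fit <- function(x, digits = 4, ...) {
  cat("Churchill-Usagi growth-and-decline fit\n")
  cat("Series:", x$label, "\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nResidual SS %.4g (ln scale), residual SD %.4g on %d df\n",
              x$rss, x$sigma, x$df))
  cat(sprintf("Peak ln abundance at %.1f h; ln abundance at t=0: %.3f\n",
              x$peak, x$y0))
  if (!x$converged) cat("Warning: fit did not converge cleanly",
                        if (x$boundary) "(rate at identifiability floor)", "\n")
  invisible(x)
}

#' @export
predict.churchill_fit <- function(object, t = object$series$times,
                                  type = c("ln_count", "count"), ...) {
  type <- match.arg(type)
  y <- ln_abundance(object$params, t)
  if (type == "count") exp(y) else y
}

#' @export
plot.churchill_fit <- function(x, n_grid = 200, ...) {
  s <- x$series
  tg <- seq(min(s$times), max(s$times), length.out = n_grid)
  graphics::plot(s$times, log(s$counts), xlab = "time (h)",
                 ylab = "ln count (cells/uL)",
                 main = series_label(s), ...)
  graphics::lines(tg, ln_abundance(x$params, tg), col = "steelblue", lwd = 2)
  tp <- peak_time(x$params)
  if (tp > min(s$times) && tp < max(s$times)) {
    graphics::abline(v = tp, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' @export
simulate.churchill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    return(with_local_seed(seed, simulate(object, nsim = nsim, seed = NULL)))
  }
  sdlog <- if (object$n_obs > 4L) sqrt(object$rss / (object$n_obs - 4L)) else 0
  mu <- object$fitted
  lapply(seq_len(nsim), function(i) {
    s <- object$series
    count_series(s$times, exp(mu + stats::rnorm(length(mu), 0, sdlog)),
                 host = s$host, inoculum = s$inoculum, vitamin = s$vitamin,
                 replicate = paste0(s$replicate, ".sim", i))
  })
}
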