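#' Churchill-Usagi parameter set
#'
#' Bundle and validate the four parameters of the Churchill-Usagi
#' growth-and-decline curve.  On the natural-log count scale the curve is
#' the harmonic blend of two asymptotic exponentials,
#' \deqn{\ln N(t) = \left(\frac{1}{K_1}e^{-\lambda_1 t} +
#'   \frac{1}{K_2}e^{\lambda_2 t}\right)^{-1},}
#' which rises at rate \eqn{\lambda_1} towards the envelope
#' \eqn{K_1 e^{\lambda_1 t}}, peaks, and then declines at rate
#' \eqn{\lambda_2} along the envelope \eqn{K_2 e^{-\lambda_2 t}}.
#'
#' @param K1 ln-abundance scale constant of the growth regime, in units of
#'   ln(cells per microlitre); together with `K2` it sets the initial
#'   density, since the curve at `t = 0` equals `K1 * K2 / (K1 + K2)`.
#' @param K2 ln-abundance scale constant of the decline regime (same
#'   units); controls the peak density.
#' @param lambda1 growth exponent, per hour.
#' @param lambda2 decline exponent, per hour.
#'
#' @return A named numeric vector of class `"churchill_params"` with
#'   elements `K1`, `K2`, `lambda1`, `lambda2`.
#' @examples
#' p <- churchill_params(K1 = 2, K2 = 10, lambda1 = 0.1, lambda2 = 0.02)
#' ln_abundance(p, 0)   # K1*K2/(K1+K2)
#' peak_time(p)
#' @export
churchill_params <- function(K1, K2, lambda1, lambda2) {
  p <- c(K1 = as.numeric(K1), K2 = as.numeric(K2),
         lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2))
  validate_params(p)
  structure(p, class = "churchill_params")
}

#' @export
print.churchill_params <- function(x, digits = 4, ...) {
  cat("Churchill-Usagi parameters:\n")
  print(round(unclass(x), digits))
  cat(sprintf("peak time: %.4g h, value at t=0: %.4g\n",
              peak_time(x), ln_abundance(x, 0)))
  invisible(x)
}

# coerce list / named vector to the canonical parameter vector
as_params <- function(p) {
  if (inherits(p, "churchill_params")) return(unclass(p))
  p <- unlist(p)
  need <- c("K1", "K2", "lambda1", "lambda2")
  if (!all(need %in% names(p))) {
    stop_churchill("invalid_parameter",
                   "parameters must be named K1, K2, lambda1, lambda2")
  }
  p <- p[need]
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (length(p) != 4L || !is.numeric(p) || any(!is.finite(p)) || any(p <= 0)) {
    stop_churchill("invalid_parameter",
                   "all four parameters must be strictly positive and finite")
  }
  invisible(p)
}

# classed conditions so callers can distinguish failure modes
stop_churchill <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("churchill_", class), "churchill_error")))
}

#' Evaluate the Churchill-Usagi curve on the ln-count scale
#'
#' @param params a [churchill_params()] object (or named vector/list with
#'   `K1`, `K2`, `lambda1`, `lambda2`).
#' @param t time in hours since inoculation; vectorised, must be `>= 0`.
#' @return ln abundance (ln cells per microlitre) at each `t`; strictly
#'   positive and bounded above by `min(K1*exp(lambda1*t), K2*exp(-lambda2*t))`.
#' @seealso [peak_time()], [ln_abundance_grad()]
#' @export
ln_abundance <- function(params, t) {
  p <- as_params(params)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_churchill("invalid_parameter", "t must be finite and >= 0")
  }
  1 / (exp(-p[["lambda1"]] * t) / p[["K1"]] + exp(p[["lambda2"]] * t) / p[["K2"]])
}

#' Gradient of the Churchill-Usagi curve in its parameters
#'
#' Analytic partial derivatives of [ln_abundance()] with respect to
#' `(K1, K2, lambda1, lambda2)`, used as the Jacobian of the least-squares
#' fit.
#'
#' @inheritParams ln_abundance
#' @return A `length(t) x 4` matrix with columns `K1`, `K2`, `lambda1`,
#'   `lambda2`.
#' @export
ln_abundance_grad <- function(params, t) {
  p <- as_params(params)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_churchill("invalid_parameter", "t must be finite and >= 0")
  }
  eg <- exp(-p[["lambda1"]] * t)   # growth-regime exponential
  ed <- exp(p[["lambda2"]] * t)    # decline-regime exponential
  y <- 1 / (eg / p[["K1"]] + ed / p[["K2"]])
  cbind(K1 = y^2 * eg / p[["K1"]]^2,
        K2 = y^2 * ed / p[["K2"]]^2,
        lambda1 = y^2 * t * eg / p[["K1"]],
        lambda2 = -(y^2) * t * ed / p[["K2"]])
}

#' Time of peak ln abundance
#'
#' Closed form for the maximiser of the Churchill-Usagi curve: setting the
#' derivative of the blended denominator to zero gives
#' \deqn{t^{*} = \frac{\ln(\lambda_1 K_2 / (\lambda_2 K_1))}
#'   {\lambda_1 + \lambda_2}.}
#' The value is returned unclamped: it is negative when
#' `lambda1*K2 < lambda2*K1`, in which case the curve is monotone
#' declining for all `t >= 0`.
#'
#' @inheritParams ln_abundance
#' @return Peak time in hours.
#' @export
peak_time <- function(params) {
  p <- as_params(params)
  log(p[["lambda1"]] * p[["K2"]] / (p[["lambda2"]] * p[["K1"]])) /
    (p[["lambda1"]] + p[["lambda2"]])
}
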