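#' Fit a Boltzmann curve to voltage-response data
#'
#' Least-squares fit of \eqn{y = A / (1 + \exp((V_{1/2} - V)/k))} (activation)
#' or the voltage-decreasing form (inactivation/availability) using bounded
#' Levenberg-Marquardt. Starting values are data-driven: `vhalf` from the
#' half-range crossing, `k` from the 10--90% span divided by `2 ln 9`
#' (\eqn{\approx 4.39}), `A` from the response range; up to `restarts`
#' jittered restarts are attempted on non-convergence.
#'
#' @param v Command/membrane voltages, mV.
#' @param y Responses (normalized conductance or availability; any uniform
#'   scaling of `y` leaves `vhalf` and `k` unchanged).
#' @param orientation `"activation"` (y increases with V) or `"inactivation"`
#'   (y decreases with V). The slope factor is reported positive either way.
#' @param restarts Maximum number of jittered restarts.
#' @return A `boltzmann_fit` object with components `coefficients`
#'   (`vhalf`, `k`, `A`), `se`, `rss`, `n`, `orientation`, `data`.
#' @examples
#' v <- seq(-60, 20, 5)
#' f <- fit_boltzmann(v, boltzmann(v, -31, 6))
#' coef(f)
#' @export
fit_boltzmann <- function(v, y, orientation = c("activation", "inactivation"),
                          restarts = 5) {
  orientation <- match.arg(orientation)
  ok <- is.finite(v) & is.finite(y)
  v <- v[ok]; y <- y[ok]
  n <- length(v)
  if (n < 5L) stop_cc("Boltzmann fit needs at least 5 points, got %d", n)
  if (max(y) - min(y) <= 0) stop_cc("response has no span; cannot fit a transition")

  o <- order(v); v <- v[o]; y <- y[o]
  # data-driven initialization on the monotone envelope
  yr <- (y - min(y)) / (max(y) - min(y))
  if (orientation == "inactivation") yr <- 1 - yr
  v50 <- cross_time(v, yr, 0.5, direction = "up")
  v10 <- cross_time(v, yr, 0.1, direction = "up")
  v90 <- cross_time(v, yr, 0.9, direction = "up")
  vhalf0 <- if (is.finite(v50)) v50 else stats::median(v)
  k0 <- if (is.finite(v10) && is.finite(v90) && v90 > v10) {
    (v90 - v10) / (2 * log(9))
  } else diff(range(v)) / 8
  k0 <- max(k0, 0.5)
  A0 <- max(abs(y))

  dat <- data.frame(v = v, y = y)
  form <- if (orientation == "activation") {
    y ~ A / (1 + exp((vhalf - v) / k))
  } else {
    y ~ A / (1 + exp((v - vhalf) / k))
  }
  lower <- c(vhalf = min(v) - 50, k = 1e-3, A = 1e-12)
  upper <- c(vhalf = max(v) + 50, k = 200, A = 10 * A0 + 1e-9)

  fit <- NULL
  start <- list(vhalf = vhalf0, k = k0, A = A0)
  for (i in seq_len(restarts + 1L)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
    start <- list(vhalf = vhalf0 + stats::rnorm(1, 0, abs(k0) + 2),
                  k = abs(k0 * exp(stats::rnorm(1, 0, 0.5))),
                  A = A0 * exp(stats::rnorm(1, 0, 0.2)))
  }
  if (is.null(fit)) {
    stop_cc("Boltzmann fit failed to converge after %d restarts (init vhalf=%.1f, k=%.2f)",
            restarts, vhalf0, k0)
  }
  sm <- summary(fit)
  cf <- coef(fit)
  structure(list(
    coefficients = c(vhalf = unname(cf["vhalf"]), k = unname(cf["k"]),
                     A = unname(cf["A"])),
    se = setNames(sm$coefficients[c("vhalf", "k", "A"), "Std. Error"],
                  c("vhalf", "k", "A")),
    rss = sum(stats::resid(fit)^2),
    n = n,
    orientation = orientation,
    data = dat,
    nls = fit
  ), class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit (n = %d)\n", x$orientation, x$n))
  cat(sprintf("  V1/2 = %.2f +/- %.2f mV\n", x$coefficients["vhalf"], x$se["vhalf"]))
  cat(sprintf("  k    = %.2f +/- %.2f mV\n", x$coefficients["k"], x$se["k"]))
  cat(sprintf("  A    = %.4g (RSS %.3g)\n", x$coefficients["A"], x$rss))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients, se = object$se)
  attr(out, "orientation") <- object$orientation
  attr(out, "n") <- object$n
  out
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v else {
    if (is.data.frame(newdata)) newdata$v else newdata
  }
  cf <- object$coefficients
  boltzmann(v, cf["vhalf"], cf["k"], cf["A"], orientation = object$orientation)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  plot(x$data$v, x$data$y, xlab = "Voltage (mV)", ylab = "Response",
       main = sprintf("Boltzmann %s fit", x$orientation), ...)
  vv <- seq(min(x$data$v), max(x$data$v), length.out = 200)
  lines(vv, predict(x, vv), col = "firebrick")
  abline(v = x$coefficients["vhalf"], lty = 3)
  invisible(x)
}
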