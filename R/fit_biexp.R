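#' Fit a biexponential kinetic curve
#'
#' Fits one of three biexponential forms used in voltage-clamp kinetics, with
#' bounded Levenberg-Marquardt, log-linear-segment initialization and jittered
#' restarts:
#' \describe{
#'   \item{`"decay"`}{\eqn{y = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}} --
#'     current decay after the peak (inactivation onset).}
#'   \item{`"recovery"`}{\eqn{y = 1 - A_f e^{-t/\tau_f} - A_s e^{-t/\tau_s}} --
#'     double-pulse recovery from inactivation (P2/P1 vs recovery interval).}
#'   \item{`"entry"`}{\eqn{y = C + A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}} --
#'     entry into slow inactivation (P2/P1 vs conditioning duration).}
#' }
#' Components are relabeled so that `tau_fast < tau_slow`. When the two time
#' constants collapse (ratio below `mono_ratio`) or one amplitude vanishes,
#' the fit falls back to a monoexponential and sets the `mono` flag.
#'
#' @param t Time (ms).
#' @param y Response.
#' @param form Model form, see Details.
#' @param restarts Maximum jittered restarts on non-convergence.
#' @param mono_ratio Minimum `tau_slow/tau_fast` ratio below which the
#'   monoexponential fallback is used.
#' @return A `biexp_fit` object; `coef()` returns `tau_fast`, `tau_slow`,
#'   `A_fast`, `A_slow` (and `offset` for the entry form). For a
#'   monoexponential fallback `tau_slow`/`A_slow` are `NA` and `mono` is TRUE.
#' @examples
#' t <- seq(0, 60, 0.25)
#' f <- fit_biexp(t, 0.8 * exp(-t / 2) + 0.2 * exp(-t / 20))
#' coef(f)
#' @export
fit_biexp <- function(t, y, form = c("decay", "recovery", "entry"),
                      restarts = 5, mono_ratio = 1.5) {
  form <- match.arg(form)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  o <- order(t); t <- t[o]; y <- y[o]
  if (length(t) < 5L) stop_cc("biexponential fit needs at least 5 points")

  # express every form as a decaying quantity d(t) = a_f e^-t/tf + a_s e^-t/ts (+0)
  d <- switch(form, decay = y, recovery = 1 - y, entry = y - min(y))
  init <- biexp_init(t, d)

  dat <- data.frame(t = t, y = y)
  lower <- c(tf = 1e-6, ts = 1e-6, af = 0, as = 0)
  upper <- c(tf = Inf, ts = Inf, af = Inf, as = Inf)
  model <- switch(form,
    decay    = y ~ af * exp(-t / tf) + as * exp(-t / ts),
    recovery = y ~ 1 - af * exp(-t / tf) - as * exp(-t / ts),
    entry    = y ~ C + af * exp(-t / tf) + as * exp(-t / ts))
  start <- as.list(init)
  if (form == "entry") {
    start$C <- max(min(y), 1e-6)
    lower <- c(lower, C = 0); upper <- c(upper, C = Inf)
  }

  fit <- NULL
  for (i in seq_len(restarts + 1L)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = dat, start = start,
                        lower = lower[names(start)], upper = upper[names(start)],
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) break
    jit <- function(x, s = 0.5) x * exp(stats::rnorm(1, 0, s))
    start$tf <- jit(init[["tf"]]); start$ts <- jit(init[["ts"]])
    start$af <- jit(init[["af"]], 0.3); start$as <- jit(init[["as"]], 0.3)
  }
  res <- list(form = form, n = length(t), data = dat, mono = FALSE)
  if (is.null(fit)) {
    # a two-component fit that cannot even be constructed usually means one
    # component is absent (a zero amplitude makes its tau column singular):
    # try the monoexponential before giving up
    mono <- fit_monoexp(dat, form, a0 = max(init[["af"]] + init[["as"]], 1e-6),
                        tau0 = init[["ts"]])
    if (!is.null(mono)) return(structure(utils::modifyList(res, mono),
                                         class = "biexp_fit"))
    stop_cc("biexponential %s fit failed after %d restarts (init tf=%.3g, ts=%.3g)",
            form, restarts, init[["tf"]], init[["ts"]])
  }
  cf <- coef(fit)
  # relabel so tau_fast < tau_slow
  if (cf["tf"] > cf["ts"]) {
    cf[c("tf", "ts", "af", "as")] <- cf[c("ts", "tf", "as", "af")]
  }
  atot <- cf["af"] + cf["as"]
  collapse <- (cf["ts"] / max(cf["tf"], 1e-12) < mono_ratio) ||
    (atot > 0 && min(cf["af"], cf["as"]) / atot < 0.01)

  if (collapse) {
    mono <- fit_monoexp(dat, form, a0 = max(atot, 1e-6),
                        tau0 = max(cf[["tf"]], 1e-3))
    if (!is.null(mono)) {
      return(structure(utils::modifyList(res, mono), class = "biexp_fit"))
    }
  }
  res$coefficients <- c(tau_fast = unname(cf["tf"]), tau_slow = unname(cf["ts"]),
                        A_fast = unname(cf["af"]), A_slow = unname(cf["as"]))
  if (form == "entry") res$coefficients <- c(res$coefficients, offset = unname(cf["C"]))
  res$rss <- sum(stats::resid(fit)^2)
  res$nls <- fit
  structure(res, class = "biexp_fit")
}

# monoexponential fallback fit; returns the result fields or NULL
fit_monoexp <- function(dat, form, a0, tau0) {
  mono_model <- switch(form,
    decay    = y ~ a * exp(-t / tau),
    recovery = y ~ 1 - a * exp(-t / tau),
    entry    = y ~ C + a * exp(-t / tau))
  mstart <- list(a = a0, tau = max(tau0, 1e-3))
  mlower <- c(a = 0, tau = 1e-6)
  if (form == "entry") {
    mstart$C <- max(min(dat$y), 0)
    mlower <- c(mlower, C = 0)
  }
  mfit <- tryCatch(
    minpack.lm::nlsLM(mono_model, data = dat, start = mstart,
                      lower = mlower[names(mstart)],
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(mfit)) return(NULL)
  mcf <- coef(mfit)
  cfs <- c(tau_fast = unname(mcf["tau"]), tau_slow = NA_real_,
           A_fast = unname(mcf["a"]), A_slow = NA_real_)
  if (form == "entry") cfs <- c(cfs, offset = unname(mcf["C"]))
  list(mono = TRUE, coefficients = cfs, rss = sum(stats::resid(mfit)^2),
       nls = mfit)
}

# log-linear segment initialization for a decaying biexponential
biexp_init <- function(t, d) {
  tr <- diff(range(t))
  eps <- max(d, 0) * 1e-9 + 1e-12
  tail_idx <- which(t >= stats::quantile(t, 0.6) & d > eps)
  ts0 <- tr / 2; as0 <- max(d) / 4
  if (length(tail_idx) >= 3L) {
    fit <- lm(log(d[tail_idx]) ~ t[tail_idx])
    sl <- unname(coef(fit)[2])
    if (is.finite(sl) && sl < 0) {
      ts0 <- -1 / sl
      as0 <- unname(exp(coef(fit)[1]))
    }
  }
  resid_early <- d - as0 * exp(-t / ts0)
  early_idx <- which(t <= stats::quantile(t, 0.4) & resid_early > eps)
  tf0 <- ts0 / 10; af0 <- max(d) / 2
  if (length(early_idx) >= 3L) {
    fit <- lm(log(resid_early[early_idx]) ~ t[early_idx])
    sl <- unname(coef(fit)[2])
    if (is.finite(sl) && sl < 0) {
      tf0 <- -1 / sl
      af0 <- unname(exp(coef(fit)[1]))
    }
  }
  if (!is.finite(tf0) || tf0 <= 0) tf0 <- tr / 20
  if (!is.finite(ts0) || ts0 <= 0) ts0 <- tr / 2
  if (tf0 >= ts0) tf0 <- ts0 / 10
  c(tf = tf0, ts = ts0, af = max(af0, 1e-9), as = max(as0, 1e-9))
}

#' @export
coef.biexp_fit <- function(object, ...) object$coefficients

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("Biexponential %s fit (n = %d)%s\n", x$form, x$n,
              if (x$mono) " [monoexponential fallback]" else ""))
  cf <- x$coefficients
  if (x$mono) {
    cat(sprintf("  tau = %.3g ms (A = %.3g)\n", cf["tau_fast"], cf["A_fast"]))
  } else {
    cat(sprintf("  tau_fast = %.4g ms (A = %.3g)\n", cf["tau_fast"], cf["A_fast"]))
    cat(sprintf("  tau_slow = %.4g ms (A = %.3g)\n", cf["tau_slow"], cf["A_slow"]))
  }
  if ("offset" %in% names(cf)) cat(sprintf("  steady offset = %.3g\n", cf["offset"]))
  cat(sprintf("  RSS = %.3g\n", x$rss))
  invisible(x)
}

#' @export
predict.biexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else {
    if (is.data.frame(newdata)) newdata$t else newdata
  }
  cf <- object$coefficients
  comp <- if (object$mono) {
    cf["A_fast"] * exp(-t / cf["tau_fast"])
  } else {
    cf["A_fast"] * exp(-t / cf["tau_fast"]) + cf["A_slow"] * exp(-t / cf["tau_slow"])
  }
  switch(object$form,
    decay = unname(comp),
    recovery = unname(1 - comp),
    entry = unname(cf["offset"] + comp))
}

#' @export
residuals.biexp_fit <- function(object, ...) object$data$y - predict(object)

#' @export
plot.biexp_fit <- function(x, log_time = FALSE, ...) {
  plot(x$data$t, x$data$y, log = if (log_time) "x" else "",
       xlab = "Time (ms)", ylab = "Response",
       main = sprintf("Biexponential %s fit", x$form), ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 300)
  lines(tt, predict(x, tt), col = "firebrick")
  invisible(x)
}
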