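# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cc <- function(fmt, ..., class = "cardioclamp_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)) ||
      x < lower || x > upper) {
    stop_cc("'%s' must be a single number in [%g, %g]", name, lower, upper)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_cc("'%s' must be TRUE or FALSE", name)
  }
  invisible(x)
}

# local RNG scope: runs expr with the given seed without disturbing the
# caller's RNG stream; seed = NULL leaves the stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_number(seed, "seed")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# trapezoidal integral; x strictly increasing
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# linear interpolation of the first crossing of `level` by y between samples,
# searching indices idx (ordered); direction "down" = first i with y[i] <= level
cross_time <- function(t, y, level, idx = seq_along(y), direction = c("down", "up")) {
  direction <- match.arg(direction)
  yy <- y[idx]; tt <- t[idx]
  hit <- if (direction == "down") which(yy <= level) else which(yy >= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(tt[1L])
  y0 <- yy[i - 1L]; y1 <- yy[i]
  if (y1 == y0) return(tt[i])
  tt[i - 1L] + (level - y0) / (y1 - y0) * (tt[i] - tt[i - 1L])
}

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# significance bands used throughout cohort reports
signif_band <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}
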