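#' Fixed-period cosinor fit
#'
#' Least-squares fit of `y = M + A*cos(2*pi*(t - phi)/tau)` at a known
#' period `tau`, via the linear basis `{1, cos(2*pi*t/tau),
#' sin(2*pi*t/tau)}`. The amplitude is `sqrt(bc^2 + bs^2)` and the
#' acrophase `atan2(bs, bc) * tau / (2*pi)` mapped into `[0, tau)`, i.e.
#' reported as a peak time in hours. The zero-amplitude test compares the
#' fit to the mesor-only model with an F(2, n-3) statistic.
#'
#' @param series data.frame with `time_hours` and `value` columns (see
#'   [read_time_series()]), or a list with `times`/`values`.
#' @param period period in hours (> 0).
#' @return An object of class `cosinor_fit`: list with `mesor`,
#'   `amplitude`, `acrophase`, `period`, `rss`, `rss0` (mesor-only),
#'   `f_stat`, `df`, `p`, `n`, `coef` (basis coefficients), and
#'   `degenerate` flag.
#' @export
fit_cosinor_fixed <- function(series, period) {
  ts <- as_times_values(series)
  t <- ts$times; y <- ts$values
  n <- length(y)
  if (n < 4L) stop("insufficient data: cosinor needs >= 4 points",
                   call. = FALSE)
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  if (length(unique(t)) == 1L)
    stop("times must not all be identical", call. = FALSE)
  w <- 2 * pi * t / period
  X <- cbind(1, cos(w), sin(w))
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("rank-deficient cosine basis at this period (aliased sampling)",
         call. = FALSE)
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  rss0 <- sum((y - mean(y))^2)
  A <- sqrt(beta[2L]^2 + beta[3L]^2)
  phi <- (atan2(beta[3L], beta[2L]) * period / (2 * pi)) %% period
  degenerate <- rss0 <= 1e-12
  f <- if (degenerate) 0 else ((rss0 - rss) / 2) / (rss / (n - 3L))
  # guard exact fits: rss == 0 gives infinite F, p = 0
  p <- if (degenerate) 1 else stats::pf(f, 2L, n - 3L, lower.tail = FALSE)
  structure(list(mesor = unname(beta[1L]), amplitude = unname(A),
                 acrophase = unname(phi), period = period, rss = rss,
                 rss0 = rss0, f_stat = f, df = c(2L, n - 3L), p = p,
                 n = n, coef = unname(beta), degenerate = degenerate),
            class = "cosinor_fit")
}

#' Free-period cosinor fit
#'
#' Profiles the fixed-period residual sum of squares over a 0.01-hour
#' grid on `[period_lo, period_hi]`, then refines the minimizing period
#' by golden-section search to 1e-4 hours, returning the full cosinor
#' fit at the optimum.
#'
#' @param series as in [fit_cosinor_fixed()].
#' @param period_lo,period_hi search bounds in hours.
#' @return A `cosinor_fit` with the estimated `period`; attribute
#'   `"profile"` holds the coarse grid (period, rss) for inspection.
#' @export
fit_cosinor_free <- function(series, period_lo = 20, period_hi = 28) {
  stopifnot(period_lo < period_hi, period_lo > 0)
  ts <- as_times_values(series)
  if (length(ts$values) < 5L)
    stop("free-period fit needs >= 5 points", call. = FALSE)
  if (stats::sd(ts$values) == 0) {
    fit <- fit_cosinor_fixed(series, (period_lo + period_hi) / 2)
    fit$degenerate <- TRUE
    warning("constant series: period unidentifiable")
    return(fit)
  }
  rss_at <- function(tau) {
    f <- try(fit_cosinor_fixed(series, tau), silent = TRUE)
    if (inherits(f, "try-error")) Inf else f$rss
  }
  grid <- seq(period_lo, period_hi, by = 0.01)
  rss <- vapply(grid, rss_at, numeric(1L))
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- rss_at(x1); f2 <- rss_at(x2)
  while (b - a > 1e-4) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- rss_at(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- rss_at(x2)
    }
  }
  fit <- fit_cosinor_fixed(series, (a + b) / 2)
  attr(fit, "profile") <- data.frame(period = grid, rss = rss)
  fit
}

as_times_values <- function(series) {
  if (is.data.frame(series)) {
    validate_time_series(series)
    list(times = series$time_hours, values = series$value)
  } else if (is.list(series) && all(c("times", "values") %in%
                                      names(series))) {
    stopifnot(length(series$times) == length(series$values))
    list(times = series$times, values = series$values)
  } else stop("series must be a data.frame or times/values list",
              call. = FALSE)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit: mesor %.4g, amplitude %.4g, acrophase %.4g h, period %.4g h\n",
    x$mesor, x$amplitude, x$acrophase, x$period))
  cat(sprintf("  zero-amplitude F(%d,%d) = %.4g, p = %.3g\n",
              x$df[1L], x$df[2L], x$f_stat, x$p))
  invisible(x)
}
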