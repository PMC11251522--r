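#' Apparent-rate series across a titration
#'
#' Holds apparent initial association rates versus total protein
#' concentration, with a per-point inclusion mask marking the initial linear
#' regime used for the zero-intercept regression.
#'
#' @param E_total total protein concentrations (M).
#' @param rates apparent initial rates (s^-1), non-negative.
#' @param included optional logical mask (default all `TRUE`).
#' @return object of class `rate_series`.
#' @export
rate_series <- function(E_total, rates, included = NULL) {
  stopifnot(length(E_total) == length(rates), all(rates >= 0))
  included <- included %||% rep(TRUE, length(rates))
  stopifnot(length(included) == length(rates), is.logical(included))
  o <- order(E_total)
  structure(list(E_total = E_total[o], rates = rates[o], included = included[o]),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d points (%d included)\n",
              length(x$rates), sum(x$included)))
  invisible(x)
}

#' Apparent initial rate of an FP association trace
#'
#' Fits a cubic smoothing spline (smoothness chosen by generalized
#' cross-validation) and returns the spline slope at the first time point
#' divided by the spline dynamic range (plateau minus starting value). The
#' result is invariant under affine transformations of the signal, so it can
#' be computed on raw anisotropy.
#'
#' @param trace a [bk_trace()] with at least 20 points covering the initial
#'   rise.
#' @return apparent rate (s^-1).
#' @export
initial_rate_fp <- function(trace) {
  stopifnot(inherits(trace, "bk_trace"))
  t <- trace$time; y <- trace$signal
  if (length(t) < 20)
    stop("at least 20 points covering the initial rise are required", call. = FALSE)
  sp <- stats::smooth.spline(t, y)
  s0 <- predict(sp, min(t), deriv = 1)$y
  f <- predict(sp, t)$y
  rng <- max(f) - f[which.min(t)]
  if (rng <= 0)
    stop("unreliable rate: spline has no dynamic range", call. = FALSE)
  early <- f[t <= quantile(t, 0.25)]
  if (length(early) >= 5) {
    drops <- diff(early) < -3 * sd(diff(early)) - .Machine$double.eps
    if (mean(drops) > 0.2)
      warning("unreliable rate: early segment is non-monotone beyond noise",
              call. = FALSE)
  }
  s0 / rng
}

#' Apparent initial rate of an SPR association segment
#'
#' Computes the signal change over the first `slope_window` seconds of the
#' association segment, divides by the window length, and normalizes by the
#' segment's dynamic range. Segments with negligible dynamic range are
#' rejected (excluded-point signal) because their normalized slope is
#' meaningless.
#'
#' @param trace a `delta_RU` association [bk_trace()].
#' @param slope_window slope window (s), default 3.
#' @param min_range minimum dynamic range (signal units) below which the
#'   point is excluded.
#' @return apparent rate (s^-1).
#' @export
initial_rate_spr <- function(trace, slope_window = 3, min_range = 1e-9) {
  stopifnot(inherits(trace, "bk_trace"))
  t <- trace$time; y <- trace$signal
  t0 <- min(t)
  if (sum(t <= t0 + slope_window) < 2)
    stop("at least 2 points are required inside the slope window", call. = FALSE)
  rng <- max(y) - min(y)
  if (rng <= min_range)
    stop("excluded point: negligible signal dynamic range", call. = FALSE)
  y_end <- stats::approx(t, y, t0 + slope_window)$y
  (y_end - y[which.min(t)]) / slope_window / rng
}

#' Apparent association rate constant by zero-intercept regression
#'
#' Zero-intercept least squares of apparent initial rate on total protein
#' concentration, restricted to the initial linear regime. With
#' `pruning = "auto"` points are included (sorted by concentration) while the
#' local secant slope stays at or above half the slope through the two lowest
#' concentrations; the first violation and everything above it is excluded
#' (the plateau caused by incomplete association curves at high protein).
#' A logical mask may be supplied instead.
#'
#' @param series a [rate_series()].
#' @param pruning `"auto"`, `"manual"` (use the mask in `series`), or a
#'   logical vector.
#' @return list with `kon` (M^-1 s^-1), `se`, and the inclusion `mask` used.
#' @export
fit_kon <- function(series, pruning = "auto") {
  stopifnot(inherits(series, "rate_series"))
  E <- series$E_total; r <- series$rates
  n <- length(E)
  mask <- if (is.logical(pruning)) {
    stopifnot(length(pruning) == n)
    pruning
  } else if (identical(pruning, "manual")) {
    series$included
  } else if (identical(pruning, "auto")) {
    if (n == 1) TRUE
    else {
      m <- rep(FALSE, n)
      m[1:2] <- TRUE
      s0 <- (r[2] - r[1]) / (E[2] - E[1])
      if (n > 2) for (i in 3:n) {
        si <- (r[i] - r[i - 1]) / (E[i] - E[i - 1])
        if (si >= 0.5 * s0) m[i] <- TRUE else break
      }
      m
    }
  } else stop("pruning must be 'auto', 'manual', or a logical mask", call. = FALSE)
  if (sum(mask) < 1) stop("empty regime: all points pruned", call. = FALSE)
  if (sum(mask) == 1) {
    kon <- r[mask] / E[mask]
    return(list(kon = kon, se = NA_real_, mask = mask))
  }
  fit <- lm(r ~ 0 + E, subset = mask, data = data.frame(E = E, r = r))
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  list(kon = coef(fit)[[1]], se = se, mask = mask)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_d = koff / kon` for a one-step binding mechanism; for multiphasic
#' dissociation the fast and slow off-rates each yield a candidate `K_d`
#' attributable to the corresponding complex state. Use [format_kd()] to
#' display at 2 significant figures in nM/uM.
#'
#' @param koff dissociation rate constant (s^-1), >= 0.
#' @param kon association rate constant (M^-1 s^-1), > 0.
#' @return K_d in molar.
#' @export
kd_from_rates <- function(koff, kon) {
  if (any(kon <= 0)) stop("division error: kon must be > 0", call. = FALSE)
  if (any(koff < 0)) stop("koff must be >= 0", call. = FALSE)
  koff / kon
}
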