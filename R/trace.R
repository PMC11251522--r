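#' Time-series binding traces and equilibrium isotherms
#'
#' `bk_trace` holds one signal of one kind over a strictly increasing time
#' grid; `bk_isotherm` holds equilibrium signal versus total protein
#' concentration at fixed ligand concentration.
#'
#' @param time numeric vector of times (seconds), strictly increasing.
#' @param signal numeric vector of the same length.
#' @param kind signal kind, one of `"anisotropy"`, `"fraction_bound"`,
#'   `"delta_RU"`, `"relative_anisotropy"`.
#' @param meta named list of experiment metadata (e.g. `E_total`, `L_total`
#'   in molar, temperature label, experiment kind).
#' @return an object of class `bk_trace`.
#' @export
bk_trace <- function(time, signal,
                     kind = c("anisotropy", "fraction_bound", "delta_RU",
                              "relative_anisotropy"),
                     meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), is.numeric(signal), length(time) == length(signal))
  if (any(!is.finite(time)) || is.unsorted(time, strictly = TRUE))
    stop("time must be finite and strictly increasing", call. = FALSE)
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 kind = kind, meta = meta),
            class = "bk_trace")
}

#' @export
print.bk_trace <- function(x, ...) {
  cat(sprintf("<bk_trace> %s, %d points, t = [%.4g, %.4g] s\n",
              x$kind, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.bk_trace <- function(x, ...) {
  data.frame(time_s = x$time, signal = x$signal, signal_kind = x$kind)
}

#' @param E_total numeric vector of total protein concentrations (molar,
#'   non-negative, strictly increasing after sorting).
#' @param L_total total ligand concentration (molar).
#' @rdname bk_trace
#' @export
bk_isotherm <- function(E_total, signal, L_total,
                        kind = c("anisotropy", "fraction_bound", "delta_RU",
                                 "relative_anisotropy")) {
  kind <- match.arg(kind)
  stopifnot(length(E_total) == length(signal), all(E_total >= 0))
  o <- order(E_total)
  E_total <- E_total[o]; signal <- signal[o]
  if (anyDuplicated(E_total)) stop("duplicated E_total values", call. = FALSE)
  structure(list(E_total = as.numeric(E_total), signal = as.numeric(signal),
                 L_total = as.numeric(L_total), kind = kind),
            class = "bk_isotherm")
}

#' @export
print.bk_isotherm <- function(x, ...) {
  cat(sprintf("<bk_isotherm> %s, %d points, E_T = [%.3g, %.3g] M, L_T = %.3g M\n",
              x$kind, length(x$E_total), min(x$E_total), max(x$E_total), x$L_total))
  invisible(x)
}

#' Normalize a raw anisotropy trace to fraction bound
#'
#' Rescales a raw trace against two internal controls: a free-ligand control
#' (baseline, fraction bound 0) and a saturated control (max, fraction
#' bound 1). Control levels are scalars by default -- the mean of each
#' control's final plateau window -- because the controls are flat by design;
#' `time_matched = TRUE` interpolates the control curves point by point for
#' drifting controls. Values are not clamped to `[0, 1]`.
#'
#' @param raw a [bk_trace()] of raw signal.
#' @param baseline_ctrl,max_ctrl control traces covering the raw trace's time
#'   span.
#' @param time_matched interpolate controls at each raw time point instead of
#'   using scalar plateau levels.
#' @param window final-window length (s) used for the scalar control levels.
#' @param min_range_frac minimum dynamic range `M - B` relative to `|M|`
#'   below which the controls are rejected as degenerate.
#' @return a `fraction_bound` [bk_trace()].
#' @export
to_fraction_bound <- function(raw, baseline_ctrl, max_ctrl,
                              time_matched = FALSE, window = 600,
                              min_range_frac = 1e-6) {
  stopifnot(inherits(raw, "bk_trace"), inherits(baseline_ctrl, "bk_trace"),
            inherits(max_ctrl, "bk_trace"))
  for (ctrl in list(baseline_ctrl, max_ctrl))
    if (min(ctrl$time) > min(raw$time) || max(ctrl$time) < max(raw$time))
      stop("controls must overlap the raw trace's time span", call. = FALSE)
  level <- function(tr) {
    keep <- tr$time >= max(tr$time) - window
    mean(tr$signal[keep])
  }
  if (time_matched) {
    B <- stats::approx(baseline_ctrl$time, baseline_ctrl$signal, raw$time)$y
    M <- stats::approx(max_ctrl$time, max_ctrl$signal, raw$time)$y
  } else {
    B <- level(baseline_ctrl)
    M <- level(max_ctrl)
  }
  if (any(abs(M - B) <= min_range_frac * pmax(abs(M), .Machine$double.eps)))
    stop("degenerate dynamic range: max and baseline controls coincide", call. = FALSE)
  bk_trace(raw$time, (raw$signal - B) / (M - B), kind = "fraction_bound",
           meta = raw$meta)
}

#' Reference- and baseline-corrected SPR signal
#'
#' Subtracts the reference flow-cell trace from the sample trace (linear
#' interpolation onto the sample grid when the grids differ), then subtracts
#' the mean signal over the pre-injection baseline window, giving a
#' `delta_RU` trace re-zeroed at its start.
#'
#' @param sample,reference [bk_trace()] objects; their time spans must
#'   overlap the sample grid.
#' @param baseline_window length (s) of the initial window whose mean is
#'   subtracted.
#' @return a `delta_RU` [bk_trace()].
#' @export
spr_delta_ru <- function(sample, reference, baseline_window = 10) {
  stopifnot(inherits(sample, "bk_trace"), inherits(reference, "bk_trace"))
  if (min(reference$time) > min(sample$time) ||
      max(reference$time) < max(sample$time))
    stop("alignment error: reference grid does not cover the sample grid",
         call. = FALSE)
  ref <- if (length(reference$time) == length(sample$time) &&
             all(reference$time == sample$time)) reference$signal
         else stats::approx(reference$time, reference$signal, sample$time)$y
  adj <- sample$signal - ref
  base <- mean(adj[sample$time <= min(sample$time) + baseline_window])
  bk_trace(sample$time - min(sample$time), adj - base, kind = "delta_RU",
           meta = sample$meta)
}

#' Equilibrium signal from the final window of a trace
#'
#' Averages all points within the final `window` seconds. Warns when the
#' linear trend across the window exceeds twice the residual noise estimate,
#' i.e. when the trace has not equilibrated.
#'
#' @param trace a [bk_trace()] longer than `window`.
#' @param window window length in seconds (default 600, i.e. the last 10
#'   minutes).
#' @return scalar mean signal.
#' @export
equilibrium_signal <- function(trace, window = 600) {
  stopifnot(inherits(trace, "bk_trace"))
  if (diff(range(trace$time)) <= window)
    stop("trace duration must exceed the averaging window", call. = FALSE)
  keep <- trace$time >= max(trace$time) - window
  t <- trace$time[keep]; y <- trace$signal[keep]
  if (length(y) >= 3) {
    fit <- stats::lm(y ~ t)
    drift <- abs(stats::coef(fit)[[2]]) * window
    noise <- stats::sd(stats::resid(fit))
    # absolute floor keeps noiseless plateaus from warning on residual decay
    if (is.finite(noise) && drift > 2 * noise + 1e-6 * max(abs(y), 1))
      warning("not equilibrated: trend within the window exceeds 2x noise",
              call. = FALSE)
  }
  mean(y)
}
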