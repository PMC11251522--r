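#' @importFrom stats coef lm resid setNames quantile vcov predict sd
NULL

new_bk_fit <- function(model, estimate, se, rss, converged, constraints = list(),
                       n = NA_integer_, flags = character(), derived = list()) {
  structure(list(model = model, estimate = estimate, se = se, rss = rss,
                 converged = converged, constraints = constraints, n = n,
                 flags = flags, derived = derived),
            class = "bk_fit")
}

#' @export
print.bk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<bk_fit> model '%s' (%s), n = %d, RSS = %.4g\n", x$model,
              if (x$converged) "converged" else "NOT converged", x$n, x$rss))
  tab <- data.frame(estimate = signif(x$estimate, digits),
                    se = signif(x$se[names(x$estimate)], digits))
  print(tab)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.bk_fit <- function(object, ...) object$estimate

# Small-sample corrected information criterion for least-squares fits.
aicc <- function(rss, n, k) {
  k <- k + 1  # variance counts as a parameter
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# Levenberg-Marquardt driver with multiple deterministic starts; returns the
# converged fit with the lowest RSS (ties broken by `prefer`).
run_nls <- function(formula, data, starts, lower, upper, prefer = NULL) {
  best <- NULL
  for (st in starts) {
    # keep deterministic starts inside any user-supplied box
    st <- lapply(stats::setNames(names(st), names(st)), function(nm)
      min(max(st[[nm]], lower[[nm]]), upper[[nm]]))
    # tight tolerances first; on an exact (zero-residual) fit nlsLM can fail
    # to rebuild its model object, in which case default tolerances suffice
    fit <- NULL
    for (ctrl in list(minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-12,
                                                 ptol = 1e-12),
                      minpack.lm::nls.lm.control(maxiter = 1024))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(formula, data = data, start = st,
                          lower = lower[names(st)], upper = upper[names(st)],
                          control = ctrl),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    better <- is.null(best) || rss < best$rss * (1 - 1e-10) ||
      (!is.null(prefer) && abs(rss - best$rss) <= best$rss * 1e-10 + 1e-300 &&
         prefer(coef(fit), best$coef))
    if (better) best <- list(fit = fit, rss = rss, coef = coef(fit))
  }
  best
}

fit_se <- function(fit, nm) {
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (!is.null(se)) out[names(se)] <- se
  out
}

#' Fit the Hill binding equation to an isotherm
#'
#' Unweighted nonlinear least squares on linear axes for
#' `A = A_min + (A_max - A_min) * E^n / (E^n + Kd^n)`. Initial values are
#' data-driven (signal extremes; Kd from the half-signal crossing) with a
#' small deterministic grid of Hill-coefficient starts. Non-convergence or a
#' fitted `Kd` more than 100x outside the data range is flagged, not raised.
#'
#' @param iso a [bk_isotherm()] with at least 5 points spanning the
#'   transition.
#' @param bounds optional list with `lower`/`upper` named vectors overriding
#'   the default box constraints.
#' @return a `bk_fit` with estimates `A_min`, `A_max`, `Kd` (M), `n`.
#' @export
fit_hill <- function(iso, bounds = NULL) {
  stopifnot(inherits(iso, "bk_isotherm"), length(iso$E_total) >= 5)
  E <- iso$E_total; y <- iso$signal
  A0 <- min(y); A1 <- max(y)
  half <- (A0 + A1) / 2
  kd0 <- tryCatch(stats::approx(y, E, xout = half, ties = "ordered")$y,
                  error = function(e) NA)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(E[E > 0])
  # Kd is fitted on a log scale: it lives orders of magnitude below the
  # signal, and a linear parameterization makes the start singular.
  starts <- lapply(c(0.5, 1, 2, 4), function(n0)
    list(A_min = A0, A_max = A1, lKd = log(kd0), n = n0))
  lower <- c(A_min = -Inf, A_max = -Inf, lKd = -Inf, n = 1e-3)
  upper <- c(A_min = Inf, A_max = Inf, lKd = Inf, n = 100)
  if (!is.null(bounds)) {
    to_log <- function(b) {
      if ("Kd" %in% names(b)) b <- c(b[names(b) != "Kd"], lKd = log(b[["Kd"]]))
      b
    }
    bl <- to_log(bounds$lower); bu <- to_log(bounds$upper)
    lower[names(bl)] <- bl
    upper[names(bu)] <- bu
  }
  # algebraically identical logistic form in log concentration; E = 0 maps
  # cleanly to the A_min plateau via logE = -Inf
  best <- run_nls(y ~ A_min + (A_max - A_min) / (1 + exp(n * (lKd - logE))),
                  data = list(y = y, logE = log(E)), starts, lower, upper)
  flags <- character()
  if (is.null(best)) {
    est <- c(A_min = A0, A_max = A1, Kd = kd0, n = 1)
    return(new_bk_fit("hill", est, setNames(rep(NA_real_, 4), names(est)),
                      NA_real_, FALSE, n = length(E),
                      flags = "non-convergence"))
  }
  co <- coef(best$fit)
  est <- c(A_min = co[["A_min"]], A_max = co[["A_max"]], Kd = exp(co[["lKd"]]),
           n = co[["n"]])
  pos <- E[E > 0]
  if (est[["Kd"]] > 100 * max(pos) || est[["Kd"]] < min(pos) / 100)
    flags <- c(flags, "Kd outside data range by > 100x")
  sefit <- fit_se(best$fit, names(co))
  se <- c(sefit[c("A_min", "A_max")], Kd = est[["Kd"]] * sefit[["lKd"]],
          n = sefit[["n"]])
  new_bk_fit("hill", est, se, best$rss, TRUE, n = length(E), flags = flags)
}

#' Fit the two-transition tight-binding isotherm
#'
#' Fits `A_min`, `A_max`, `Kd1`, `Kd2` and `alpha` (fraction of the dynamic
#' range on the first, ligand-depletion-limited transition), with the
#' ordering `Kd1 <= Kd2` enforced by parameterizing `Kd2 = Kd1 + dK`,
#' `dK >= 0`, and `alpha` box-bounded to `[0, 1]`. An `alpha` pinned at 0 or
#' 1 triggers a degenerate-transition warning (the model has collapsed to a
#' single transition). RSS ties between starts are broken toward larger
#' `alpha`.
#'
#' @param iso a [bk_isotherm()] with known `L_total`.
#' @return a `bk_fit` with estimates `A_min`, `A_max`, `Kd1`, `Kd2` (M),
#'   `alpha`.
#' @export
fit_two_transition <- function(iso) {
  stopifnot(inherits(iso, "bk_isotherm"), length(iso$E_total) >= 6)
  E <- iso$E_total; y <- iso$signal; LT <- iso$L_total
  if (!is.finite(LT) || LT <= 0)
    stop("L_total must be known and > 0 for the two-transition fit", call. = FALSE)
  A0 <- min(y); A1 <- max(y)
  half <- (A0 + A1) / 2
  kdh <- tryCatch(stats::approx(y, E, xout = half, ties = "ordered")$y,
                  error = function(e) NA)
  if (!is.finite(kdh) || kdh <= 0) kdh <- stats::median(E[E > 0])
  # both dissociation constants are fitted on log scales (ordering Kd1 <= Kd2
  # enforced by Kd2 = Kd1 + exp(ldK)); alpha is box-bounded to [0, 1]
  starts <- list()
  for (a0 in c(0.3, 0.5, 0.7))
    for (k10 in unique(c(LT / 4, kdh / 10, kdh)))
      starts <- c(starts, list(list(A_min = A0, A_max = A1, lKd1 = log(k10),
                                    ldK = log(max(kdh * 5 - k10, LT)),
                                    alpha = a0)))
  lower <- c(A_min = -Inf, A_max = -Inf, lKd1 = -Inf, ldK = -Inf, alpha = 0)
  upper <- c(A_min = Inf, A_max = Inf, lKd1 = Inf, ldK = Inf, alpha = 1)
  form <- y ~ A_min + (A_max - A_min) *
    (alpha * (E + LT + exp(lKd1) -
                sqrt(pmax((E + LT + exp(lKd1))^2 - 4 * E * LT, 0))) / (2 * LT) +
       (1 - alpha) * E / (E + exp(lKd1) + exp(ldK)))
  best <- run_nls(form, data = list(y = y, E = E, LT = LT), starts, lower, upper,
                  prefer = function(a, b) a[["alpha"]] > b[["alpha"]])
  if (is.null(best)) {
    est <- c(A_min = A0, A_max = A1, Kd1 = LT / 2, Kd2 = kdh, alpha = 0.5)
    return(new_bk_fit("two_transition", est,
                      setNames(rep(NA_real_, 5), names(est)), NA_real_, FALSE,
                      n = length(E), flags = "non-convergence"))
  }
  co <- coef(best$fit)
  kd1 <- exp(co[["lKd1"]]); dk <- exp(co[["ldK"]])
  est <- c(A_min = co[["A_min"]], A_max = co[["A_max"]], Kd1 = kd1,
           Kd2 = kd1 + dk, alpha = co[["alpha"]])
  if (est[["alpha"]] <= 1e-6 || est[["alpha"]] >= 1 - 1e-6)
    warning("degenerate transition: alpha pinned at ", round(est[["alpha"]]),
            "; the model reduces to one transition", call. = FALSE)
  sefit <- fit_se(best$fit, names(co))
  se <- c(sefit[c("A_min", "A_max")], Kd1 = kd1 * sefit[["lKd1"]],
          Kd2 = sqrt((kd1 * sefit[["lKd1"]])^2 + (dk * sefit[["ldK"]])^2),
          alpha = sefit[["alpha"]])
  new_bk_fit("two_transition", est, se, best$rss, TRUE, n = length(E),
             constraints = list(L_total = LT))
}

# Deterministic rate initialization from trace shape: slow rate from a
# log-linear fit of the final 20 %, fast rate from the first 10 %.
init_decay_rates <- function(t, z) {
  # z: positive, decaying component (signal above its floor)
  rng <- max(z) - min(z)
  floor_z <- pmax(z - min(z), rng * 1e-4 + 1e-300)
  n <- length(t)
  tail_i <- t >= quantile(t, 0.8)
  head_i <- t <= quantile(t, 0.1)
  slope <- function(idx) {
    if (sum(idx) < 3) return(NA_real_)
    -coef(lm(log(floor_z[idx]) ~ t[idx]))[[2]]
  }
  ks <- slope(tail_i); kf <- slope(head_i)
  if (!is.finite(ks) || ks <= 0) ks <- 1 / max(t)
  if (!is.finite(kf) || kf <= ks) kf <- max(10 * ks, 5 / max(t[head_i], t[2]))
  # amplitude split: extrapolate the slow phase back to t = 0
  sl <- lm(log(floor_z[tail_i]) ~ t[tail_i])
  As <- exp(coef(sl)[[1]])
  beta <- 1 - min(max(As / max(rng, 1e-300), 0.05), 0.95)
  list(k_slow = ks, k_fast = kf, beta = beta)
}

order_phases <- function(est) {
  if (est[["k_fast"]] < est[["k_slow"]]) {
    tmp <- est[["k_fast"]]
    est[["k_fast"]] <- est[["k_slow"]]; est[["k_slow"]] <- tmp
    est[["beta_fast"]] <- 1 - est[["beta_fast"]]
  }
  est
}

#' Fit mono- or biphasic association kinetics
#'
#' Fits the monophasic rise (one observed rate) or the biphasic rise (fast
#' and slow rates plus the fraction `beta_fast` of the dynamic range on the
#' fast phase) to an association trace, optionally restricted to an initial
#' time window first. Phase labels are ordered so that `k_fast >= k_slow`;
#' a fitted rate ratio below 3 triggers a phase-indistinguishable warning.
#' With `n_phases = NULL` the model is chosen by a small-sample corrected
#' information criterion.
#'
#' @param trace a [bk_trace()] with at least 8 points.
#' @param n_phases 1, 2, or `NULL` for information-criterion selection.
#' @param window optional window length (s) from the trace start to which the
#'   fit is restricted.
#' @return a `bk_fit` with model `assoc_mono` (`A_min`, `A_max`, `k_on`) or
#'   `assoc_biexp` (`A_min`, `A_max`, `k_fast`, `k_slow`, `beta_fast`).
#' @export
fit_association <- function(trace, n_phases = NULL, window = NULL) {
  stopifnot(inherits(trace, "bk_trace"))
  t <- trace$time; y <- trace$signal
  if (!is.null(window)) {
    keep <- t <= min(t) + window
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 8) stop("at least 8 points are required for a fit", call. = FALSE)
  t <- t - min(t)
  A0 <- min(y); A1 <- max(y)
  ini <- init_decay_rates(t, pmax(A1 - y, 0))
  fit1 <- run_nls(y ~ A_min + (A_max - A_min) * (1 - exp(-k_on * tt)),
                  data = list(y = y, tt = t),
                  starts = list(list(A_min = A0, A_max = A1, k_on = ini$k_slow),
                                list(A_min = A0, A_max = A1, k_on = ini$k_fast)),
                  lower = c(A_min = -Inf, A_max = -Inf, k_on = 1e-12),
                  upper = c(A_min = Inf, A_max = Inf, k_on = Inf))
  starts2 <- lapply(c(1, 5, 0.2), function(f)
    list(A_min = A0, A_max = A1, k_fast = ini$k_fast * f, k_slow = ini$k_slow,
         beta_fast = ini$beta))
  fit2 <- run_nls(
    y ~ A_min + (A_max - A_min) *
      (1 - beta_fast * exp(-k_fast * tt) - (1 - beta_fast) * exp(-k_slow * tt)),
    data = list(y = y, tt = t), starts = starts2,
    lower = c(A_min = -Inf, A_max = -Inf, k_fast = 1e-12, k_slow = 1e-12,
              beta_fast = 0),
    upper = c(A_min = Inf, A_max = Inf, k_fast = Inf, k_slow = Inf,
              beta_fast = 1))
  use <- n_phases
  if (is.null(use)) {
    if (is.null(fit2)) use <- 1
    else if (is.null(fit1)) use <- 2
    else use <- if (aicc(fit2$rss, length(t), 5) < aicc(fit1$rss, length(t), 3))
      2 else 1
  }
  if (use == 1) {
    if (is.null(fit1))
      return(new_bk_fit("assoc_mono",
                        c(A_min = A0, A_max = A1, k_on = ini$k_slow),
                        setNames(rep(NA_real_, 3), c("A_min", "A_max", "k_on")),
                        NA_real_, FALSE, n = length(t),
                        flags = "non-convergence"))
    est <- coef(fit1$fit)[c("A_min", "A_max", "k_on")]
    return(new_bk_fit("assoc_mono", est, fit_se(fit1$fit, names(est)),
                      fit1$rss, TRUE, n = length(t)))
  }
  if (is.null(fit2))
    return(new_bk_fit("assoc_biexp",
                      c(A_min = A0, A_max = A1, k_fast = ini$k_fast,
                        k_slow = ini$k_slow, beta_fast = ini$beta),
                      setNames(rep(NA_real_, 5),
                               c("A_min", "A_max", "k_fast", "k_slow", "beta_fast")),
                      NA_real_, FALSE, n = length(t), flags = "non-convergence"))
  est <- order_phases(coef(fit2$fit)[c("A_min", "A_max", "k_fast", "k_slow",
                                       "beta_fast")])
  flags <- character()
  if (est[["k_fast"]] < 3 * est[["k_slow"]]) {
    warning("phases indistinguishable: k_fast/k_slow < 3", call. = FALSE)
    flags <- "phase-indistinguishable"
  }
  new_bk_fit("assoc_biexp", est, fit_se(fit2$fit, names(est)), fit2$rss, TRUE,
             n = length(t), flags = flags)
}

#' Fit constrained biexponential dissociation kinetics
#'
#' Fits the biexponential decay to a dissociation trace. The initial signal
#' `A_max` may be constrained to a known value (e.g. the internal-control
#' fraction bound at the moment dissociation was induced); a constrained
#' `A_max` is reported exactly as supplied. With `monophasic = TRUE` the fit
#' is additionally constrained to `k_fast = 0`, `beta_fast = 0` (a single
#' slow exponential). The fast-phase percentage `100 * beta_fast` is reported
#' in `$derived$pct_fast`.
#'
#' @param trace a decaying [bk_trace()] with at least 8 points.
#' @param A_max optional fixed value of the initial signal.
#' @param monophasic constrain to a single slow phase.
#' @return a `bk_fit` with estimates `A_min`, `A_max`, `k_fast`, `k_slow`,
#'   `beta_fast` and the applied constraints recorded.
#' @export
fit_dissociation <- function(trace, A_max = NULL, monophasic = FALSE) {
  stopifnot(inherits(trace, "bk_trace"))
  t <- trace$time - min(trace$time); y <- trace$signal
  if (length(t) < 8) stop("at least 8 points are required for a fit", call. = FALSE)
  n <- length(y)
  head_m <- mean(y[seq_len(max(3, n %/% 10))])
  tail_m <- mean(y[seq(n - max(3, n %/% 10) + 1, n)])
  if (tail_m >= head_m)
    stop("not a decay: trace does not decrease", call. = FALSE)
  A0 <- min(y)
  A1 <- A_max %||% max(y)
  fixed_amax <- !is.null(A_max)
  constraints <- list(A_max_fixed = fixed_amax, monophasic = monophasic)
  ini <- init_decay_rates(t, pmax(y - A0, 0))
  if (monophasic) {
    form <- if (fixed_amax)
      y ~ A_min + (AMAX - A_min) * exp(-k_slow * tt)
    else y ~ A_min + (A_max - A_min) * exp(-k_slow * tt)
    st <- list(A_min = A0, k_slow = ini$k_slow)
    if (!fixed_amax) st$A_max <- A1
    best <- run_nls(form, data = list(y = y, tt = t, AMAX = A1), starts = list(st),
                    lower = c(A_min = -Inf, A_max = -Inf, k_slow = 0),
                    upper = c(A_min = Inf, A_max = Inf, k_slow = Inf))
    if (is.null(best))
      return(new_bk_fit("dissoc_biexp",
                        c(A_min = A0, A_max = A1, k_fast = 0,
                          k_slow = ini$k_slow, beta_fast = 0),
                        setNames(rep(NA_real_, 5),
                                 c("A_min", "A_max", "k_fast", "k_slow", "beta_fast")),
                        NA_real_, FALSE, constraints, length(t),
                        flags = "non-convergence"))
    co <- coef(best$fit)
    est <- c(A_min = co[["A_min"]],
             A_max = if (fixed_amax) A_max else co[["A_max"]],
             k_fast = 0, k_slow = co[["k_slow"]], beta_fast = 0)
    se <- setNames(rep(NA_real_, 5), names(est))
    sefit <- fit_se(best$fit, names(co))
    se[c("A_min", "k_slow")] <- sefit[c("A_min", "k_slow")]
    if (!fixed_amax) se["A_max"] <- sefit["A_max"]
    return(new_bk_fit("dissoc_biexp", est, se, best$rss, TRUE, constraints,
                      length(t), derived = list(pct_fast = 0)))
  }
  starts <- lapply(c(1, 5, 0.2), function(f) {
    st <- list(A_min = A0, beta_fast = ini$beta, k_fast = ini$k_fast * f,
               k_slow = ini$k_slow)
    if (!fixed_amax) st$A_max <- A1
    st
  })
  form <- if (fixed_amax)
    y ~ A_min + (AMAX - A_min) *
      (beta_fast * exp(-k_fast * tt) + (1 - beta_fast) * exp(-k_slow * tt))
  else
    y ~ A_min + (A_max - A_min) *
      (beta_fast * exp(-k_fast * tt) + (1 - beta_fast) * exp(-k_slow * tt))
  best <- run_nls(form, data = list(y = y, tt = t, AMAX = A1), starts = starts,
                  lower = c(A_min = -Inf, A_max = -Inf, beta_fast = 0,
                            k_fast = 0, k_slow = 0),
                  upper = c(A_min = Inf, A_max = Inf, beta_fast = 1,
                            k_fast = Inf, k_slow = Inf))
  if (is.null(best))
    return(new_bk_fit("dissoc_biexp",
                      c(A_min = A0, A_max = A1, k_fast = ini$k_fast,
                        k_slow = ini$k_slow, beta_fast = ini$beta),
                      setNames(rep(NA_real_, 5),
                               c("A_min", "A_max", "k_fast", "k_slow", "beta_fast")),
                      NA_real_, FALSE, constraints, length(t),
                      flags = "non-convergence"))
  co <- coef(best$fit)
  est <- c(A_min = co[["A_min"]],
           A_max = if (fixed_amax) A_max else co[["A_max"]],
           k_fast = co[["k_fast"]], k_slow = co[["k_slow"]],
           beta_fast = co[["beta_fast"]])
  est <- order_phases(est)
  se <- setNames(rep(NA_real_, 5), names(est))
  sefit <- fit_se(best$fit, names(co))
  se[intersect(names(sefit), names(se))] <- sefit[intersect(names(sefit), names(se))]
  new_bk_fit("dissoc_biexp", est, se, best$rss, TRUE, constraints, length(t),
             derived = list(pct_fast = 100 * est[["beta_fast"]]))
}
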