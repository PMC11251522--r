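#' Simulation protocol for two-phase binding experiments
#'
#' Describes the in-silico mixing/dilution experiment: phase 1 (association)
#' starts from free protein and ligand and runs for `t_on`; phase 2
#' (dissociation) starts from the phase-1 endpoint divided by
#' `dilution_factor` and runs for `t_off`. Defaults mirror a fluorescence
#' polarization titration: 5 nM ligand, total protein on a two-fold dilution
#' grid from 2^-12 to 1 uM, 1.5 h association, 1 h dissociation, and a 10^6
#' dilution emulating competitor addition. The output grid `dt_out` is a
#' sampling grid only; integration is error-controlled and adaptive
#' (default reporting at 1 s; 25 ms grids are supported but cost memory, not
#' accuracy).
#'
#' @param dt_out output grid spacing (s), > 0.
#' @param t_on association duration (s).
#' @param t_off dissociation duration (s).
#' @param dilution_factor dimensionless factor >= 1 applied between phases.
#' @param E_total_grid total protein concentrations (M) for titrations.
#' @param L_total total ligand concentration (M).
#' @param rel_tol,abs_tol integrator tolerances (abs_tol in molar).
#' @return a list of class `sim_protocol`.
#' @export
sim_protocol <- function(dt_out = 1, t_on = 5400, t_off = 3600,
                         dilution_factor = 1e6,
                         E_total_grid = 2^seq(-12, 0) * 1e-6,
                         L_total = 5e-9, rel_tol = 1e-10, abs_tol = 1e-14) {
  stopifnot(dt_out > 0, t_on >= 0, t_off >= 0, dilution_factor >= 1,
            rel_tol > 0, abs_tol > 0, all(E_total_grid >= 0), L_total >= 0)
  structure(list(dt_out = dt_out, t_on = t_on, t_off = t_off,
                 dilution_factor = dilution_factor,
                 E_total_grid = E_total_grid, L_total = L_total,
                 rel_tol = rel_tol, abs_tol = abs_tol),
            class = "sim_protocol")
}

new_trajectory <- function(time, conc, label) {
  structure(list(time = time, conc = conc, scheme = label),
            class = "bk_trajectory")
}

#' @export
print.bk_trajectory <- function(x, ...) {
  cat(sprintf("<bk_trajectory> scheme '%s', %d species x %d time points\n",
              x$scheme, ncol(x$conc), length(x$time)))
  invisible(x)
}

# Shared deSolve driver with negative-concentration hygiene.
run_ode <- function(func, y0, duration, dt_out, rel_tol, abs_tol, label,
                    parms = NULL) {
  times <- seq(0, duration, by = dt_out)
  if (times[length(times)] < duration) times <- c(times, duration)
  # hmax/hini are fixed by the duration, not the reporting grid, so dt_out is
  # purely a sampling grid: refining it cannot change the step sequence
  out <- deSolve::ode(y = y0, times = times, func = func, parms = parms,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol,
                      hmax = duration, hini = min(1e-2, duration / 100),
                      maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) {
    msg <- paste(utils::capture.output(deSolve::diagnostics(out)), collapse = "\n")
    stop("integration error:\n", msg, call. = FALSE)
  }
  conc <- unclass(out)[, -1, drop = FALSE]
  # species slaved to a fast equilibrium sit near zero with solver noise well
  # above abs_tol; clamp negatives inside that hygiene band, fail beyond it
  neg_tol <- max(1e3 * abs_tol, 1e-5 * max(abs(conc)))
  neg <- conc < 0
  if (any(conc[neg] < -neg_tol))
    stop("integration error: negative concentration beyond tolerance",
         call. = FALSE)
  conc[neg] <- 0
  new_trajectory(unclass(out)[, 1], conc, label)
}

#' Integrate a reaction scheme
#'
#' Error-controlled adaptive integration (stiff-capable lsoda) of the
#' mass-action rate equations, sampled on the `dt_out` output grid. Rate
#' constants spanning many orders of magnitude are handled by the stiff
#' solver; conserved totals are preserved to within the integration
#' tolerances.
#'
#' @param scheme a [reaction_scheme()].
#' @param initial named numeric vector of initial concentrations (molar)
#'   covering every species.
#' @param duration integration time (s), > 0.
#' @param dt_out output grid spacing (s).
#' @param rel_tol,abs_tol integrator tolerances.
#' @return a `bk_trajectory`: time grid plus a species-by-time concentration
#'   matrix.
#' @export
integrate_scheme <- function(scheme, initial, duration, dt_out = 1,
                             rel_tol = 1e-10, abs_tol = 1e-14) {
  stopifnot(inherits(scheme, "reaction_scheme"), duration > 0)
  if (is.null(names(initial)) || !setequal(names(initial), scheme$species))
    stop("initial state must name every scheme species", call. = FALSE)
  stopifnot_nonneg(initial, "initial concentrations")
  y0 <- initial[scheme$species]
  S <- stoich_matrix(scheme)
  ks <- vapply(scheme$reactions, `[[`, numeric(1), "rate")
  rct_idx <- lapply(scheme$reactions, function(rx)
    match(names(rx$reactants), scheme$species))
  rct_ord <- lapply(scheme$reactions, function(rx) as.numeric(rx$reactants))
  func <- function(t, y, p) {
    y <- pmax(y, 0)
    v <- ks
    for (j in seq_along(v))
      v[j] <- v[j] * prod(y[rct_idx[[j]]]^rct_ord[[j]])
    list(drop(S$net %*% v))
  }
  run_ode(func, y0, duration, dt_out, rel_tol, abs_tol, scheme$label)
}

#' Integrate the feedback-isomerization equations directly
#'
#' Integrates [feedback_rhs()] (conserving by default, or the published
#' non-conserving free-protein equation with `verbatim = TRUE`).
#'
#' @param rates a [rate_constants()] vector.
#' @param initial named vector with `E`, `L`, `EL`, `ELstar`, `E2L` (molar).
#' @param duration integration time (s).
#' @param dt_out output grid spacing (s).
#' @param verbatim use the published free-protein equation (leaks protein at
#'   rate `k3b * E * EL`).
#' @param rel_tol,abs_tol integrator tolerances.
#' @return a `bk_trajectory`.
#' @export
integrate_feedback <- function(rates, initial, duration, dt_out = 1,
                               verbatim = FALSE, rel_tol = 1e-10,
                               abs_tol = 1e-14) {
  func <- function(t, y, p) list(feedback_rhs(y, rates, verbatim = verbatim,
                                              tol = 1e3 * abs_tol))
  need <- c("E", "L", "EL", "ELstar", "E2L")
  stopifnot(all(need %in% names(initial)))
  run_ode(func, initial[need], duration, dt_out, rel_tol, abs_tol,
          if (verbatim) "feedback_verbatim" else "feedback")
}

scheme_weights <- function(scheme, weights = NULL) {
  w <- weights %||% scheme$weights
  if (is.null(w))
    stop("scheme has no anisotropy weights; supply `weights`", call. = FALSE)
  w
}

#' Two-phase association/dissociation experiment
#'
#' Runs the in-silico protocol: phase 1 starts with all protein and ligand
#' free and integrates for `t_on`; phase 2 starts from the phase-1 endpoint
#' divided by the dilution factor and integrates for `t_off`. The relative
#' anisotropy observable is computed at every output point; because it is a
#' ratio, it is unchanged by the dilution, so the phase-2 trace starts exactly
#' where the phase-1 trace ends.
#'
#' @param scheme a [reaction_scheme()] whose species include `E` and `L`.
#' @param protocol a [sim_protocol()].
#' @param E_total total protein concentration (M) for this run.
#' @param weights optional anisotropy weights overriding the scheme's.
#' @param t_on optional association duration overriding the protocol's.
#' @return list with `association` and `dissociation`
#'   (`relative_anisotropy` [bk_trace()]s, dissociation time restarting at 0)
#'   and the two `bk_trajectory` objects `phase1`, `phase2`.
#' @export
run_two_phase <- function(scheme, protocol, E_total, weights = NULL,
                          t_on = NULL) {
  stopifnot(inherits(protocol, "sim_protocol"))
  w <- scheme_weights(scheme, weights)
  t_on <- t_on %||% protocol$t_on
  y0 <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  y0["E"] <- E_total
  y0["L"] <- protocol$L_total
  ph1 <- integrate_scheme(scheme, y0, t_on, protocol$dt_out,
                          protocol$rel_tol, protocol$abs_tol)
  y1 <- ph1$conc[nrow(ph1$conc), ] / protocol$dilution_factor
  # keep the absolute tolerance meaningful relative to the diluted state
  ph2 <- integrate_scheme(scheme, y1, protocol$t_off, protocol$dt_out,
                          protocol$rel_tol,
                          protocol$abs_tol / protocol$dilution_factor)
  meta <- list(E_total = E_total, L_total = protocol$L_total,
               dilution_factor = protocol$dilution_factor, scheme = scheme$label)
  a1 <- relative_anisotropy(ph1$conc, w)
  a2 <- relative_anisotropy(ph2$conc, w)
  # the observable is a ratio, so the uniform dilution leaves it unchanged;
  # reuse the phase-1 endpoint to keep that identity exact in floating point
  a2[1] <- a1[length(a1)]
  list(
    association = bk_trace(ph1$time, a1, kind = "relative_anisotropy",
                           meta = c(meta, phase = "association")),
    dissociation = bk_trace(ph2$time, a2, kind = "relative_anisotropy",
                            meta = c(meta, phase = "dissociation")),
    phase1 = ph1, phase2 = ph2)
}

#' Titration series with equilibrium isotherm
#'
#' Runs one two-phase experiment per concentration on the protocol's
#' `E_total_grid` and assembles the equilibrium isotherm from the phase-1
#' endpoints.
#'
#' @inheritParams run_two_phase
#' @return list with `experiments` (list of [run_two_phase()] results, one
#'   per grid point) and `isotherm` (a [bk_isotherm()]).
#' @export
run_titration <- function(scheme, protocol, weights = NULL) {
  stopifnot(length(protocol$E_total_grid) >= 1)
  w <- scheme_weights(scheme, weights)
  runs <- lapply(protocol$E_total_grid, function(ET) {
    if (ET == 0) {
      # no protein: flat zero observable without integration
      t1 <- seq(0, protocol$t_on, by = protocol$dt_out)
      t2 <- seq(0, protocol$t_off, by = protocol$dt_out)
      meta <- list(E_total = 0, L_total = protocol$L_total)
      return(list(association = bk_trace(t1, rep(0, length(t1)),
                                         "relative_anisotropy", meta),
                  dissociation = bk_trace(t2, rep(0, length(t2)),
                                          "relative_anisotropy", meta),
                  phase1 = NULL, phase2 = NULL))
    }
    run_two_phase(scheme, protocol, ET, weights = w)
  })
  eq <- vapply(runs, function(r) {
    s <- r$association$signal
    s[length(s)]
  }, numeric(1))
  list(experiments = runs,
       isotherm = bk_isotherm(protocol$E_total_grid, eq, protocol$L_total,
                              kind = "relative_anisotropy"))
}

#' Variable-incubation dissociation experiments
#'
#' For each incubation time `T`, phase 1 is run for `T` instead of the
#' protocol's `t_on`, then phase 2 as usual. Reproduces the dependence of
#' dissociation multiphasicity on how long the binding reaction was allowed
#' to proceed before dissociation was induced.
#'
#' @inheritParams run_two_phase
#' @param incubation_times vector of phase-1 durations (s), > 0.
#' @return list of [run_two_phase()] results, one per incubation time.
#' @export
run_variable_incubation <- function(scheme, protocol, E_total,
                                    incubation_times, weights = NULL) {
  stopifnot(all(incubation_times > 0))
  lapply(incubation_times, function(T)
    run_two_phase(scheme, protocol, E_total, weights = weights, t_on = T))
}
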