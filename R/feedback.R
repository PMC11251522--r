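#' Rate constants for the feedback-isomerization scheme
#'
#' Container for the nine rate constants of the isomer-limited sequential
#' binding scheme with feedback-catalyzed isomerization:
#' bimolecular association `k1` (M^-1 s^-1) and dissociation `k_m1` (s^-1) of
#' the initial complex, intrinsic isomerization `k2` and reverse isomerization
#' `k_m2` (both s^-1), association to the isomerized complex `k3`
#' (M^-1 s^-1) and dissociation of the higher-order complex `k_m3` (s^-1),
#' direct association to the non-isomerized complex `k3b` (M^-1 s^-1,
#' irreversible), and the feedback catalysis constants `k_alpha` (by the
#' isomerized complex) and `k_beta` (by the two-protein complex), both
#' M^-1 s^-1.
#'
#' @param k1,k_m1,k2,k_m2,k3,k_m3,k3b,k_alpha,k_beta non-negative finite rate
#'   constants; defaults are 0.
#' @return a named numeric vector of class `rate_constants`.
#' @export
rate_constants <- function(k1 = 0, k_m1 = 0, k2 = 0, k_m2 = 0, k3 = 0,
                           k_m3 = 0, k3b = 0, k_alpha = 0, k_beta = 0) {
  k <- c(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2, k3 = k3, k_m3 = k_m3,
         k3b = k3b, k_alpha = k_alpha, k_beta = k_beta)
  stopifnot_nonneg(k, "rate constants")
  structure(k, class = c("rate_constants", "numeric"))
}

#' Reference parameter set for feedback-scheme simulations
#'
#' The rate-constant set used for the simulated dilution experiments that
#' reproduce lagged triphasic association of a dimeric transcription factor on
#' its target site: `k1 = 1e6 M^-1 s^-1`, `k_m1 = 1.6e-3 s^-1`,
#' `k2 = 1e-5 s^-1`, `k_m2 = 3.2e-3 s^-1`, `k3 = 1e9 M^-1 s^-1`,
#' `k_m3 = 2e-2 s^-1`, `k3b = 1e4 M^-1 s^-1`, `k_alpha = 2e7 M^-1 s^-1`,
#' `k_beta = 2e6 M^-1 s^-1`. Raising the reverse isomerization rate `k_m2` to
#' 10 s^-1 (the `"fast"` variant) abolishes the lag and mimics the
#' RNA-binding behaviour.
#'
#' Note `k2` multiplies a complex concentration alone, so it is treated as a
#' first-order constant (s^-1) for dimensional consistency.
#'
#' @param reverse_isomerization `"slow"` (`k_m2 = 3.2e-3`) or `"fast"`
#'   (`k_m2 = 10`).
#' @return a [rate_constants()] vector.
#' @export
feedback_demo_rates <- function(reverse_isomerization = c("slow", "fast")) {
  reverse_isomerization <- match.arg(reverse_isomerization)
  rate_constants(
    k1 = 1e6, k_m1 = 1.6e-3, k2 = 1e-5,
    k_m2 = if (reverse_isomerization == "slow") 3.2e-3 else 10,
    k3 = 1e9, k_m3 = 2e-2, k3b = 1e4, k_alpha = 2e7, k_beta = 2e6)
}

#' Time derivatives of the feedback-isomerization scheme
#'
#' Evaluates the coupled rate equations for the five species `E` (free
#' protein), `L` (free ligand), `EL` (initial complex), `ELstar` (isomerized
#' complex) and `E2L` (two-protein complex).
#'
#' The published form of the free-protein equation omits consumption of `E`
#' by the direct `E + EL -> E2L` pathway, so summing the five equations with
#' protein weights (1, 0, 1, 1, 2) leaves a spurious source term
#' `+k3b * E * EL`. By default (`verbatim = FALSE`) the term
#' `-k3b * E * EL` is included in the `E` derivative so that total protein is
#' conserved; `verbatim = TRUE` reproduces the published equations exactly,
#' which is useful to audit the leak.
#'
#' @param state named numeric vector with components `E`, `L`, `EL`,
#'   `ELstar`, `E2L` (molar). Small negative values within `tol` are clamped
#'   to zero; larger ones are an error.
#' @param rates a [rate_constants()] vector.
#' @param verbatim logical; use the published (non-conserving) free-protein
#'   equation.
#' @param tol tolerance for negative concentrations (molar).
#' @return named numeric vector of derivatives (molar per second).
#' @export
feedback_rhs <- function(state, rates, verbatim = FALSE, tol = 1e-12) {
  need <- c("E", "L", "EL", "ELstar", "E2L")
  if (is.null(names(state)) || !all(need %in% names(state)))
    stop("state must be named with components E, L, EL, ELstar, E2L", call. = FALSE)
  s <- state[need]
  if (any(s < -tol))
    stop("invalid state: negative concentration beyond tolerance", call. = FALSE)
  s <- pmax(s, 0)
  k <- as.numeric(rates[c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3", "k3b",
                          "k_alpha", "k_beta")])
  names(k) <- c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3", "k3b", "k_alpha", "k_beta")
  E <- s[["E"]]; L <- s[["L"]]; EL <- s[["EL"]]; ELs <- s[["ELstar"]]; E2L <- s[["E2L"]]
  dE <- k[["k_m1"]] * EL + k[["k_m3"]] * E2L - E * (k[["k1"]] * L + k[["k3"]] * ELs)
  if (!verbatim) dE <- dE - k[["k3b"]] * E * EL
  dL <- k[["k_m1"]] * EL - k[["k1"]] * E * L
  dEL <- k[["k1"]] * E * L + k[["k_m2"]] * ELs -
    EL * (k[["k_m1"]] + k[["k2"]] + k[["k_alpha"]] * ELs + k[["k_beta"]] * E2L +
            k[["k3b"]] * E)
  dELs <- (k[["k2"]] + k[["k_alpha"]] * ELs + k[["k_beta"]] * E2L) * EL +
    k[["k_m3"]] * E2L - ELs * (k[["k_m2"]] + k[["k3"]] * E)
  dE2L <- k[["k3"]] * E * ELs + k[["k3b"]] * E * EL - k[["k_m3"]] * E2L
  c(E = dE, L = dL, EL = dEL, ELstar = dELs, E2L = dE2L)
}

#' Relative predicted anisotropy of a species state
#'
#' Computes the stoichiometry-weighted bound fraction used as the predicted
#' anisotropy observable: with default weights,
#' `A_rel = (E2L + (EL + ELstar) / 2) / (E2L + ELstar + EL + L)`. In general
#' `A_rel = sum(w_i x_i) / sum(x_i)` over the ligand-containing species, with
#' free ligand weighted 0, single-protein complexes 0.5 and two-protein
#' complexes 1. The ratio is invariant under uniform dilution of all species.
#'
#' @param state named numeric vector or a matrix with named columns (one row
#'   per time point) of species concentrations. Species not named in
#'   `weights` (e.g. free protein) are ignored.
#' @param weights named numeric vector of weights in `[0, 1]` for every
#'   ligand-containing species; default is the feedback-scheme convention.
#' @return numeric scalar (or vector for matrix input) in `[0, 1]`.
#' @export
relative_anisotropy <- function(state,
                                weights = c(L = 0, EL = 0.5, ELstar = 0.5, E2L = 1)) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0 | weights > 1))
    stop("anisotropy weights must lie in [0, 1]", call. = FALSE)
  if (is.matrix(state)) {
    miss <- setdiff(names(weights), colnames(state))
    if (length(miss)) stop("state lacks species: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    x <- state[, names(weights), drop = FALSE]
    tot <- rowSums(x)
    if (any(tot <= 0))
      stop("undefined observable: all ligand-containing species are zero", call. = FALSE)
    return(as.numeric(x %*% weights / tot))
  }
  miss <- setdiff(names(weights), names(state))
  if (length(miss)) stop("state lacks species: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- state[names(weights)]
  tot <- sum(x)
  if (tot <= 0)
    stop("undefined observable: all ligand-containing species are zero", call. = FALSE)
  sum(weights * x) / tot
}
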