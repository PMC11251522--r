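#' Forward evaluation of the binding and kinetic models
#'
#' Evaluates one of the five regression models used throughout the analysis:
#'
#' * `"hill"`: equilibrium Hill binding,
#'   `A = A_min + (A_max - A_min) * E^n / (E^n + Kd^n)`;
#'   params `A_min`, `A_max`, `Kd` (M), `n`.
#' * `"two_transition"`: two-transition tight-binding isotherm; the first
#'   transition is the quadratic ligand-depletion form in `E_T`, `L_T`,
#'   `Kd1`, the second a hyperbola in `Kd2`, mixed by `alpha` (fraction of
#'   the dynamic range on the first transition); params `A_min`, `A_max`,
#'   `Kd1`, `Kd2`, `alpha`, `L_total`.
#' * `"assoc_mono"`: monophasic association,
#'   `A_t = A_min + (A_max - A_min) * (1 - exp(-k_on * t))`; params `A_min`,
#'   `A_max`, `k_on`.
#' * `"assoc_biexp"`: biphasic association with fraction `beta_fast` of the
#'   dynamic range on the fast phase; params `A_min`, `A_max`, `k_fast`,
#'   `k_slow`, `beta_fast`.
#' * `"dissoc_biexp"`: biexponential decay
#'   `A_t = A_min + (A_max - A_min) * (beta_fast * exp(-k_fast * t) +
#'   (1 - beta_fast) * exp(-k_slow * t))`; params as above.
#'
#' @param model model id.
#' @param params named list/vector of parameters (see above). Invariants are
#'   checked: `Kd`, `n`, rates > 0; `A_max > A_min`; `alpha`, `beta_fast` in
#'   `[0, 1]`; `Kd1 <= Kd2`; `k_fast >= k_slow`.
#' @param x total protein concentrations (M) for the equilibrium models,
#'   times (s) for the kinetic models.
#' @return numeric vector of predicted signal.
#' @export
eval_model <- function(model = c("hill", "two_transition", "assoc_mono",
                                 "assoc_biexp", "dissoc_biexp"),
                       params, x) {
  model <- match.arg(model)
  p <- as.list(params)
  g <- function(nm) {
    v <- p[[nm]]
    if (is.null(v) || !is.finite(v))
      stop(sprintf("parameter error: '%s' missing or non-finite", nm), call. = FALSE)
    v
  }
  chk <- function(ok, msg) if (!ok) stop("parameter error: ", msg, call. = FALSE)
  chk(g("A_max") > g("A_min"), "A_max must exceed A_min")
  rng <- g("A_max") - g("A_min")
  switch(model,
    hill = {
      chk(g("Kd") > 0 && g("n") > 0, "Kd and n must be > 0")
      g("A_min") + rng * x^g("n") / (x^g("n") + g("Kd")^g("n"))
    },
    two_transition = {
      chk(g("Kd1") > 0 && g("Kd2") > 0, "Kd1 and Kd2 must be > 0")
      chk(g("Kd1") <= g("Kd2"), "Kd1 must not exceed Kd2")
      chk(g("alpha") >= 0 && g("alpha") <= 1, "alpha must lie in [0, 1]")
      LT <- g("L_total"); chk(LT > 0, "L_total must be > 0")
      b <- x + LT + g("Kd1")
      q1 <- (b - sqrt(pmax(b^2 - 4 * x * LT, 0))) / (2 * LT)
      g("A_min") + rng * (g("alpha") * q1 + (1 - g("alpha")) * x / (x + g("Kd2")))
    },
    assoc_mono = {
      chk(g("k_on") > 0, "k_on must be > 0")
      g("A_min") + rng * (1 - exp(-g("k_on") * x))
    },
    assoc_biexp = {
      chk(g("k_fast") > 0 && g("k_slow") > 0, "rates must be > 0")
      chk(g("k_fast") >= g("k_slow"), "k_fast must be >= k_slow")
      chk(g("beta_fast") >= 0 && g("beta_fast") <= 1, "beta_fast must lie in [0, 1]")
      g("A_min") + rng * (1 - g("beta_fast") * exp(-g("k_fast") * x) -
                            (1 - g("beta_fast")) * exp(-g("k_slow") * x))
    },
    dissoc_biexp = {
      chk(g("k_fast") >= 0 && g("k_slow") >= 0, "rates must be >= 0")
      # the monophasic constrained form carries k_fast = 0 with beta_fast = 0
      chk(g("beta_fast") == 0 || g("k_fast") >= g("k_slow"),
          "k_fast must be >= k_slow")
      chk(g("beta_fast") >= 0 && g("beta_fast") <= 1, "beta_fast must lie in [0, 1]")
      g("A_min") + rng * (g("beta_fast") * exp(-g("k_fast") * x) +
                            (1 - g("beta_fast")) * exp(-g("k_slow") * x))
    })
}
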