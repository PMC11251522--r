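#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert concentrations to molar
#'
#' @param x numeric vector of concentrations.
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return numeric vector in molar.
#' @export
conc_to_molar <- function(x, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  x * switch(unit, M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
}

#' Convert times to seconds
#'
#' @param x numeric vector of times.
#' @param unit one of `"s"`, `"min"`, `"h"`.
#' @return numeric vector in seconds.
#' @export
time_to_seconds <- function(x, unit = c("s", "min", "h")) {
  unit <- match.arg(unit)
  x * switch(unit, s = 1, min = 60, h = 3600)
}

#' Format a dissociation constant for display
#'
#' Scales a molar K_d into pM/nM/uM/mM and rounds to two significant figures,
#' the convention used when comparing koff/kon ratios with equilibrium
#' titration results.
#'
#' @param kd_M dissociation constant(s) in molar.
#' @param digits significant figures (default 2).
#' @return character vector such as `"13 nM"`.
#' @export
format_kd <- function(kd_M, digits = 2) {
  vapply(kd_M, function(x) {
    if (!is.finite(x)) return(NA_character_)
    if (x == 0) return("0 M")
    if (x >= 1e-3) sprintf("%s mM", signif(x * 1e3, digits))
    else if (x >= 1e-6) sprintf("%s uM", signif(x * 1e6, digits))
    else if (x >= 1e-9) sprintf("%s nM", signif(x * 1e9, digits))
    else sprintf("%s pM", signif(x * 1e12, digits))
  }, character(1))
}

# Evaluate expr with a temporary RNG seed, restoring any prior RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("%s must be finite and >= 0", what), call. = FALSE)
  invisible(x)
}
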