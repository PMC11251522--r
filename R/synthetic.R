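#' Noise model for synthetic experiments
#'
#' Additive Gaussian noise with an optional common-mode linear drift (used
#' for SPR channels). Defaults keep parameters on the scale of the published
#' constants identifiable: 0.005 anisotropy units for FP, 0.5 RU for SPR.
#'
#' @param sigma additive Gaussian standard deviation (signal units), >= 0.
#' @param seed integer seed; generation is reproducible per seed.
#' @param drift linear drift (signal units per second; SPR only).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.005, seed = 1L, drift = 0) {
  stopifnot(sigma >= 0, is.finite(drift))
  structure(list(sigma = sigma, seed = as.integer(seed), drift = drift),
            class = "noise_model")
}

#' Catalog of published binding and kinetic constants
#'
#' The apparent equilibrium and kinetic constants measured by FP for the two
#' transcription factor domains (an estrogen-receptor-alpha DNA-binding
#' domain with its basic hinge extension, and the Sox2 HMG domain) against
#' their nucleic-acid ligands, as published, normalized to molar and
#' per-second units. Kinetic entries also carry the inferred
#' sequential-scheme rate constants where those were reported (CBS dsDNA and
#' G4 RNA).
#'
#' @return object of class `bk_catalog`: a named list of entries, each with
#'   `protein`, `ligand`, `equilibrium` (model id plus parameters),
#'   optionally `kon` (M^-1 s^-1), `koff_fast`/`koff_slow` (s^-1) with
#'   percent contributions, `sequential_rates`, and a `provenance` note.
#' @export
catalog <- function() {
  eq_hill <- function(Kd_nM, n) list(model = "hill", Kd = Kd_nM * 1e-9, n = n)
  eq_two <- function(Kd1_nM, Kd2_nM, alpha)
    list(model = "two_transition", Kd1 = Kd1_nM * 1e-9, Kd2 = Kd2_nM * 1e-9,
         alpha = alpha)
  tab <- "published kinetic constants table (FP)"
  leg <- "published sequential-scheme rate constants"
  entries <- list(
    ERE = list(protein = "ERalpha_DBD-Ext", ligand = "ERE dsDNA",
               equilibrium = eq_hill(11, 2.1), kon = 5.8e4,
               koff_fast = 4.7e-2, pct_fast = 71, koff_slow = 7.3e-4,
               pct_slow = 29, provenance = tab),
    dERE = list(protein = "ERalpha_DBD-Ext", ligand = "dERE dsDNA",
                equilibrium = eq_hill(2.8, 1.5), kon = 8.7e4,
                koff_fast = 8.9e-2, pct_fast = 60, koff_slow = 5.9e-4,
                pct_slow = 40, provenance = tab),
    XBP1 = list(protein = "ERalpha_DBD-Ext", ligand = "XBP1 hRNA",
                equilibrium = eq_hill(370, 0.91), kon = 1.4e5,
                koff_fast = 5.6e-2, pct_fast = 64, koff_slow = 6.6e-4,
                pct_slow = 36, provenance = tab),
    CBS = list(protein = "Sox2_HMG", ligand = "CBS dsDNA",
               equilibrium = eq_two(1, 420, 0.54), kon = 7.5e5,
               koff_fast = 5.0e-2, pct_fast = 67, koff_slow = 1.3e-3,
               pct_slow = 33,
               sequential_rates = c(k1 = 8e5, k_m1 = 1e-3, k2 = 8e5,
                                    k_m2 = 5e-2),
               provenance = paste(tab, "+", leg)),
    rG4 = list(protein = "Sox2_HMG", ligand = "G4 RNA",
               equilibrium = eq_two(1, 110, 0.44), kon = 1.1e6,
               koff_fast = 5.4e-2, pct_fast = 73, koff_slow = 9.6e-4,
               pct_slow = 27,
               sequential_rates = c(k1 = 1e6, k_m1 = 1e-3, k2 = 7e4,
                                    k_m2 = 5e-2),
               provenance = paste(tab, "+", leg)),
    NBS = list(protein = "Sox2_HMG", ligand = "NBS dsDNA",
               equilibrium = eq_hill(29, 0.57), provenance = tab),
    hRNA = list(protein = "Sox2_HMG", ligand = "hRNA",
                equilibrium = eq_hill(53, 1.1), provenance = tab),
    polyA = list(protein = "Sox2_HMG", ligand = "poly(A) RNA",
                 equilibrium = eq_hill(40, 0.68), provenance = tab))
  structure(entries, class = "bk_catalog")
}

#' @export
print.bk_catalog <- function(x, ...) {
  cat("<bk_catalog>", length(x), "interactions:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.bk_catalog <- function(x, ...) {
  rows <- lapply(names(x), function(nm) {
    e <- x[[nm]]
    eq <- e$equilibrium
    data.frame(
      interaction = nm, protein = e$protein, ligand = e$ligand,
      model = eq$model,
      Kd_M = if (eq$model == "hill") eq$Kd else eq$Kd1,
      Kd2_M = if (eq$model == "hill") NA_real_ else eq$Kd2,
      n_or_alpha = if (eq$model == "hill") eq$n else eq$alpha,
      kon = e$kon %||% NA_real_,
      koff_fast = e$koff_fast %||% NA_real_,
      pct_fast = e$pct_fast %||% NA_real_,
      koff_slow = e$koff_slow %||% NA_real_,
      pct_slow = e$pct_slow %||% NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

add_noise <- function(x, noise, t = NULL) {
  if (is.null(noise)) return(x)
  with_seed(noise$seed, {
    x <- x + stats::rnorm(length(x), 0, noise$sigma)
    if (!is.null(t) && noise$drift != 0) x <- x + noise$drift * t
    x
  })
}

#' Synthetic equilibrium isotherm
#'
#' Evaluates a forward binding model on a concentration grid and adds seeded
#' Gaussian noise; with `sigma = 0` the curve is exact.
#'
#' @param model `"hill"` or `"two_transition"` (see [eval_model()]).
#' @param params model parameters; `L_total` is injected for the
#'   two-transition model.
#' @param E_grid total protein concentrations (M).
#' @param L_total total ligand concentration (M).
#' @param noise a [noise_model()] or `NULL` for none.
#' @return a [bk_isotherm()].
#' @export
make_isotherm <- function(model, params, E_grid, L_total = 5e-9, noise = NULL) {
  params <- as.list(params)
  if (is.null(params$A_min)) params$A_min <- 0
  if (is.null(params$A_max)) params$A_max <- 1
  if (model == "two_transition" && is.null(params$L_total))
    params$L_total <- L_total
  y <- eval_model(model, params, E_grid)
  bk_isotherm(E_grid, add_noise(y, noise), L_total,
              kind = "fraction_bound")
}

map_anisotropy <- function(a_rel, free = 0.06, sat = 0.16)
  free + (sat - free) * a_rel

#' Synthetic FP experiment (association, FPCD, or FPJD)
#'
#' Simulates the mechanistic scheme through the two-phase protocol, maps the
#' relative anisotropy observable to raw anisotropy through a fixed affine
#' transform (free-ligand and saturated anisotropy levels), and generates the
#' two flat internal-control traces at those levels. All downstream rate
#' estimates are invariant to the affine mapping. `"association"` returns the
#' phase-1 trace; `"fpcd"` emulates competitor addition as a large dilution
#' (default from the protocol, 10^6); `"fpjd"` uses an ~80-fold jump
#' dilution.
#'
#' @param kind experiment kind.
#' @param scheme a [reaction_scheme()].
#' @param protocol a [sim_protocol()].
#' @param E_total total protein concentration (M).
#' @param noise a [noise_model()] or `NULL`.
#' @param anis_free,anis_sat anisotropy levels for free and saturated ligand.
#' @param dilution_factor override for the phase-2 dilution.
#' @return list with `sample`, `baseline_ctrl`, `max_ctrl` ([bk_trace()]s of
#'   kind `anisotropy`) and `truth` (the noiseless [run_two_phase()] result).
#' @export
make_fp_experiment <- function(kind = c("association", "fpcd", "fpjd"),
                               scheme, protocol, E_total, noise = NULL,
                               anis_free = 0.06, anis_sat = 0.16,
                               dilution_factor = NULL) {
  kind <- match.arg(kind)
  df <- dilution_factor %||% switch(kind, fpjd = 80, protocol$dilution_factor)
  proto <- protocol
  proto$dilution_factor <- if (kind == "association") 1 else df
  run <- run_two_phase(scheme, proto, E_total)
  tr <- if (kind == "association") run$association else run$dissociation
  sig <- map_anisotropy(tr$signal, anis_free, anis_sat)
  mk_ctrl <- function(level, shift) {
    n2 <- if (is.null(noise)) NULL else noise_model(noise$sigma, noise$seed + shift)
    bk_trace(tr$time, add_noise(rep(level, length(tr$time)), n2),
             kind = "anisotropy", meta = list(role = "control"))
  }
  list(sample = bk_trace(tr$time, add_noise(sig, noise), kind = "anisotropy",
                         meta = c(tr$meta, kind = kind)),
       baseline_ctrl = mk_ctrl(anis_free, 1L),
       max_ctrl = mk_ctrl(anis_sat, 2L),
       truth = run)
}

#' Synthetic SPR sensorgrams for a concentration series
#'
#' For each protein concentration, simulates association (protein flowed over
#' the surface-bound ligand for `t_assoc`) followed by a wash phase, converts
#' the protein mass bound per ligand to response units, and returns paired
#' sample/reference channels sharing offset, drift and independent noise.
#' The wash is modeled as removal of the free solutes (free protein and any
#' displaced ligand set to zero) while surface-bound complexes are retained,
#' matching buffer flow over the chip. Reference subtraction
#' ([spr_delta_ru()]) recovers the scaled bound-mass trajectory.
#'
#' @param scheme a [reaction_scheme()].
#' @param E_grid protein concentrations (M).
#' @param t_assoc association duration (s), default 300.
#' @param t_wash wash (dissociation) duration (s).
#' @param noise a [noise_model()]; drift is applied as common mode to both
#'   channels. Default 0.5 RU noise.
#' @param rmax response at full ligand saturation by a single protein
#'   monomer (RU).
#' @param offset absolute channel offset (RU).
#' @param dt_out output grid (s).
#' @return list of per-concentration experiments, each with `sample`,
#'   `reference` ([bk_trace()]s) and `truth` (noiseless ΔRU trace).
#' @export
make_spr_experiment <- function(scheme, E_grid, t_assoc = 300, t_wash = 1800,
                                noise = noise_model(sigma = 0.5, seed = 1),
                                rmax = 100, offset = 500, dt_out = 1) {
  stopifnot(length(E_grid) >= 1)
  L_total <- 5e-9
  # protein mass bound per ligand: one unit per protein monomer in a complex
  protein_mass <- function(conc) {
    w <- scheme$weights
    stopifnot(!is.null(w))
    bound <- names(w)[w > 0]
    m <- ifelse(w[bound] >= 1, 2, 1)  # two-protein complexes weigh double
    drop(conc[, bound, drop = FALSE] %*% m)
  }
  lapply(seq_along(E_grid), function(i) {
    y0 <- stats::setNames(numeric(length(scheme$species)), scheme$species)
    y0["E"] <- E_grid[i]
    y0["L"] <- L_total
    ph1 <- integrate_scheme(scheme, y0, t_assoc, dt_out)
    y1 <- ph1$conc[nrow(ph1$conc), ]
    y1[c("E", "L")] <- 0
    # buffer flow keeps the free solutes cleared: first-order washout sinks
    wash <- reaction_scheme(
      scheme$species,
      c(scheme$reactions,
        list(reaction(c(E = 1), numeric(0), 0.5, "washout_E"),
             reaction(c(L = 1), numeric(0), 0.5, "washout_L"))),
      label = paste0(scheme$label, "_wash"), weights = scheme$weights)
    ph2 <- integrate_scheme(wash, y1, t_wash, dt_out)
    t_all <- c(ph1$time, t_assoc + ph2$time[-1])
    mass <- c(protein_mass(ph1$conc), protein_mass(ph2$conc)[-1])
    ru <- rmax * mass / L_total
    nm_s <- if (is.null(noise)) NULL else
      noise_model(noise$sigma, noise$seed + 2L * i, noise$drift)
    nm_r <- if (is.null(noise)) NULL else
      noise_model(noise$sigma, noise$seed + 2L * i + 1L, noise$drift)
    list(sample = bk_trace(t_all, add_noise(offset + ru, nm_s, t_all),
                           kind = "delta_RU",
                           meta = list(E_total = E_grid[i], role = "sample")),
         reference = bk_trace(t_all,
                              add_noise(rep(offset, length(t_all)), nm_r, t_all),
                              kind = "delta_RU",
                              meta = list(E_total = E_grid[i], role = "reference")),
         truth = bk_trace(t_all, ru, kind = "delta_RU",
                          meta = list(E_total = E_grid[i])))
  })
}
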