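#' Mass-action reaction schemes
#'
#' A `reaction_scheme` is a named list of species plus a list of elementary
#' reactions, each with reactant/product stoichiometries and a non-negative
#' rate constant. Reversible steps are represented as two irreversible
#' reactions. Reactant stoichiometry is limited to at most bimolecular
#' elementary steps.
#'
#' @param species character vector of species names.
#' @param reactions list of reactions created with [reaction()].
#' @param label scheme identifier.
#' @param weights optional named anisotropy weights in `[0, 1]` for the
#'   ligand-containing species (see [relative_anisotropy()]).
#' @return an object of class `reaction_scheme`.
#' @seealso [build_scheme()] for the schemes used in the analysis.
#' @export
reaction_scheme <- function(species, reactions, label = "scheme", weights = NULL) {
  stopifnot(is.character(species), length(species) >= 1, !anyDuplicated(species))
  for (rx in reactions) {
    if (!inherits(rx, "bk_reaction"))
      stop("reactions must be built with reaction()", call. = FALSE)
    nm <- union(names(rx$reactants), names(rx$products))
    if (!all(nm %in% species))
      stop("reaction references species not in the species list: ",
           paste(setdiff(nm, species), collapse = ", "), call. = FALSE)
    if (sum(rx$reactants) > 2)
      stop("at most bimolecular reactant stoichiometry is supported", call. = FALSE)
  }
  if (!is.null(weights)) {
    stopifnot(is.numeric(weights), !is.null(names(weights)))
    if (any(weights < 0 | weights > 1))
      stop("anisotropy weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(species = species, reactions = reactions, label = label,
                 weights = weights),
            class = "reaction_scheme")
}

#' Define one elementary reaction
#'
#' @param reactants,products named integer vectors of stoichiometries
#'   (e.g. `c(E = 1, L = 1)`); empty vectors are allowed for sources/sinks.
#' @param rate non-negative rate constant (per second, or per molar per
#'   second for bimolecular steps).
#' @param label optional reaction label.
#' @return an object of class `bk_reaction`.
#' @export
reaction <- function(reactants, products, rate, label = NULL) {
  stopifnot(length(rate) == 1)
  stopifnot_nonneg(rate, "rate constant")
  as_sto <- function(x) {
    if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    stopifnot(!is.null(names(x)), all(x > 0))
    x
  }
  structure(list(reactants = as_sto(reactants), products = as_sto(products),
                 rate = as.numeric(rate), label = label),
            class = "bk_reaction")
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat(sprintf("<reaction_scheme '%s'>: %d species, %d reactions\n",
              x$label, length(x$species), length(x$reactions)))
  side <- function(s) if (length(s) == 0) "0" else
    paste(ifelse(s > 1, paste0(s, " "), ""), names(s), sep = "", collapse = " + ")
  for (rx in x$reactions)
    cat(sprintf("  %s -> %s  @ %.3g\n", side(rx$reactants), side(rx$products), rx$rate))
  invisible(x)
}

#' Stoichiometric matrices of a scheme
#'
#' @param scheme a [reaction_scheme()].
#' @return list with `net` (species x reactions net stoichiometry) and
#'   `reactant` (species x reactions reactant orders).
#' @export
stoich_matrix <- function(scheme) {
  ns <- length(scheme$species); nr <- length(scheme$reactions)
  net <- matrix(0, ns, nr, dimnames = list(scheme$species, NULL))
  rct <- net
  for (j in seq_len(nr)) {
    rx <- scheme$reactions[[j]]
    rct[names(rx$reactants), j] <- rx$reactants
    net[names(rx$reactants), j] <- net[names(rx$reactants), j] - rx$reactants
    net[names(rx$products), j] <- net[names(rx$products), j] + rx$products
  }
  list(net = net, reactant = rct)
}

#' Mass-action rate laws
#'
#' Evaluates the time derivative of every species under standard mass-action
#' kinetics: each reaction proceeds at `k * prod(conc^stoichiometry)` over its
#' reactants, consuming reactants and producing products.
#'
#' @param scheme a [reaction_scheme()].
#' @param conc named numeric vector of concentrations (molar) covering every
#'   species of the scheme.
#' @return named numeric vector of derivatives (molar per second).
#' @export
mass_action_rhs <- function(scheme, conc) {
  if (is.null(names(conc)) || !setequal(names(conc), scheme$species))
    stop("concentrations must be named and match the scheme species", call. = FALSE)
  conc <- conc[scheme$species]
  S <- stoich_matrix(scheme)
  rates <- vapply(seq_along(scheme$reactions), function(j) {
    rx <- scheme$reactions[[j]]
    rx$rate * prod(conc[names(rx$reactants)]^rx$reactants)
  }, numeric(1))
  drop(S$net %*% rates)
}

#' Conserved linear combinations of a scheme
#'
#' Computes a basis for the left null space of the net stoichiometric matrix;
#' every returned vector `w` satisfies `w' * dx/dt = 0` along any trajectory,
#' e.g. total protein `E + EL + EL* + 2 E2L` and total ligand
#' `L + EL + EL* + E2L` for the conserving feedback scheme. Basis vectors are
#' rescaled to small integers when possible.
#'
#' @param scheme a [reaction_scheme()].
#' @return matrix with one column per conserved combination, rows named by
#'   species; zero columns when nothing is conserved.
#' @export
conserved_totals <- function(scheme) {
  S <- stoich_matrix(scheme)$net
  sv <- svd(t(S), nu = 0, nv = length(scheme$species))
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  null_idx <- which(c(sv$d, rep(0, length(scheme$species) - length(sv$d))) <= tol)
  basis <- sv$v[, null_idx, drop = FALSE]
  rownames(basis) <- scheme$species
  # rationalize columns to small integers where the pattern allows it
  apply_int <- function(v) {
    nz <- abs(v) > 1e-10
    if (!any(nz)) return(v)
    w <- v / min(abs(v[nz]))
    if (max(abs(w - round(w))) < 1e-8) round(w) else v
  }
  basis <- apply(basis, 2, apply_int)
  basis <- matrix(basis, nrow = length(scheme$species),
                  dimnames = list(scheme$species, NULL))
  # prefer non-negative orientation
  for (j in seq_len(ncol(basis)))
    if (sum(basis[, j]) < 0) basis[, j] <- -basis[, j]
  basis
}

#' Construct the candidate binding schemes
#'
#' Builds the mass-action reaction networks considered for multiphasic
#' transcription factor-nucleic acid binding:
#'
#' * `"feedback"`: isomer-limited sequential binding with feedback-catalyzed
#'   isomerization. Reactions: `E + L <-> EL` (`k1`/`k_m1`), `EL <-> ELstar`
#'   (`k2`/`k_m2`), `EL + ELstar -> 2 ELstar` (`k_alpha`),
#'   `EL + E2L -> ELstar + E2L` (`k_beta`), `E + ELstar <-> E2L`
#'   (`k3`/`k_m3`), and the irreversible `E + EL -> E2L` (`k3b`). Its
#'   mass-action derivatives equal [feedback_rhs()] with
#'   `verbatim = FALSE`.
#' * `"sequential"`: `E + L <-> EL` (`k1`/`k_m1`), `E + EL <-> E2L`
#'   (`k2`/`k_m2`).
#' * `"locked"`: `E + L <-> EL` (`k1`/`k_m1`), `EL <-> EL_locked`
#'   (`k2`/`k_m2`); the locked complex cannot release ligand directly.
#' * `"protein_isomer"`: `E <-> Estar` (`k_iso`/`k_m_iso`) with both protein
#'   forms binding ligand (`k1`/`k_m1`, `k1s`/`k_m1s`).
#' * `"ligand_isomer"`: `L <-> Lstar` (`k_iso`/`k_m_iso`) with both ligand
#'   forms binding protein (`k1`/`k_m1`, `k1s`/`k_m1s`).
#'
#' Default anisotropy weights are attached: 0 for free ligand, 0.5 for
#' single-protein complexes, 1 for two-protein complexes; isomerized or locked
#' complexes share the weight of their parent state.
#'
#' @param name scheme name (see above).
#' @param constants named list/vector of non-negative rate constants; see the
#'   reaction lists for the names each scheme expects. Missing constants
#'   default to 0.
#' @return a [reaction_scheme()] with anisotropy weights attached.
#' @export
build_scheme <- function(name = c("feedback", "sequential", "protein_isomer",
                                  "ligand_isomer", "locked"),
                         constants = list()) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unsupported scheme: ", name[1], call. = FALSE))
  k <- function(nm) {
    v <- constants[[nm]] %||% 0
    stopifnot_nonneg(v, nm)
    v
  }
  rev_pair <- function(r, p, kf, kb, lab) {
    out <- list(reaction(r, p, kf, paste0(lab, "+")))
    if (TRUE) out <- c(out, list(reaction(p, r, kb, paste0(lab, "-"))))
    out
  }
  switch(name,
    feedback = reaction_scheme(
      species = c("E", "L", "EL", "ELstar", "E2L"),
      reactions = c(
        rev_pair(c(E = 1, L = 1), c(EL = 1), k("k1"), k("k_m1"), "bind"),
        rev_pair(c(EL = 1), c(ELstar = 1), k("k2"), k("k_m2"), "isom"),
        list(reaction(c(EL = 1, ELstar = 1), c(ELstar = 2), k("k_alpha"), "fb_isom")),
        list(reaction(c(EL = 1, E2L = 1), c(ELstar = 1, E2L = 1), k("k_beta"), "fb_e2l")),
        rev_pair(c(E = 1, ELstar = 1), c(E2L = 1), k("k3"), k("k_m3"), "bind2"),
        list(reaction(c(E = 1, EL = 1), c(E2L = 1), k("k3b"), "bind2_direct"))
      ),
      label = "feedback",
      weights = c(L = 0, EL = 0.5, ELstar = 0.5, E2L = 1)),
    sequential = reaction_scheme(
      species = c("E", "L", "EL", "E2L"),
      reactions = c(
        rev_pair(c(E = 1, L = 1), c(EL = 1), k("k1"), k("k_m1"), "bind"),
        rev_pair(c(E = 1, EL = 1), c(E2L = 1), k("k2"), k("k_m2"), "bind2")
      ),
      label = "sequential",
      weights = c(L = 0, EL = 0.5, E2L = 1)),
    locked = reaction_scheme(
      species = c("E", "L", "EL", "EL_locked"),
      reactions = c(
        rev_pair(c(E = 1, L = 1), c(EL = 1), k("k1"), k("k_m1"), "bind"),
        rev_pair(c(EL = 1), c(EL_locked = 1), k("k2"), k("k_m2"), "lock")
      ),
      label = "locked",
      weights = c(L = 0, EL = 0.5, EL_locked = 0.5)),
    protein_isomer = reaction_scheme(
      species = c("E", "Estar", "L", "EL", "EstarL"),
      reactions = c(
        rev_pair(c(E = 1), c(Estar = 1), k("k_iso"), k("k_m_iso"), "isom"),
        rev_pair(c(E = 1, L = 1), c(EL = 1), k("k1"), k("k_m1"), "bind"),
        rev_pair(c(Estar = 1, L = 1), c(EstarL = 1), k("k1s"), k("k_m1s"), "bind_star")
      ),
      label = "protein_isomer",
      weights = c(L = 0, EL = 0.5, EstarL = 0.5)),
    ligand_isomer = reaction_scheme(
      species = c("E", "L", "Lstar", "EL", "ELstar"),
      reactions = c(
        rev_pair(c(L = 1), c(Lstar = 1), k("k_iso"), k("k_m_iso"), "isom"),
        rev_pair(c(E = 1, L = 1), c(EL = 1), k("k1"), k("k_m1"), "bind"),
        rev_pair(c(E = 1, Lstar = 1), c(ELstar = 1), k("k1s"), k("k_m1s"), "bind_star")
      ),
      label = "ligand_isomer",
      weights = c(L = 0, Lstar = 0, EL = 0.5, ELstar = 0.5))
  )
}

#' Write or read a scheme as a plain-text config
#'
#' Serializes a scheme as JSON: species, reactions as
#' `"reactants -> products @ k"`, anisotropy weights, and the label. Rate
#' constants are in molar/second units.
#'
#' @param scheme a [reaction_scheme()].
#' @param path file path.
#' @return `write_scheme` returns `path` invisibly; `read_scheme` returns a
#'   [reaction_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  side <- function(s) if (length(s) == 0) "0" else
    paste(ifelse(s > 1, paste0(s, " "), ""), names(s), sep = "", collapse = " + ")
  obj <- list(
    label = scheme$label,
    species = scheme$species,
    reactions = vapply(scheme$reactions, function(rx)
      sprintf("%s -> %s @ %.17g", side(rx$reactants), side(rx$products), rx$rate),
      character(1)),
    weights = as.list(scheme$weights)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_side <- function(txt) {
    txt <- trimws(txt)
    if (txt == "0") return(stats::setNames(numeric(0), character(0)))
    parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    sto <- numeric(0)
    for (p in parts) {
      m <- regmatches(p, regexec("^([0-9]+)?\\s*([A-Za-z0-9_]+)$", p))[[1]]
      if (length(m) == 0) stop("cannot parse reaction side: ", p, call. = FALSE)
      n <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      sto[m[3]] <- (sto[m[3]] %||% 0) + n
      sto[is.na(sto)] <- n
    }
    sto
  }
  reactions <- lapply(obj$reactions, function(txt) {
    halves <- strsplit(txt, "@", fixed = TRUE)[[1]]
    sides <- strsplit(halves[1], "->", fixed = TRUE)[[1]]
    reaction(parse_side(sides[1]), parse_side(sides[2]), as.numeric(trimws(halves[2])))
  })
  w <- if (length(obj$weights)) unlist(obj$weights) else NULL
  reaction_scheme(obj$species, reactions, label = obj$label, weights = w)
}
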