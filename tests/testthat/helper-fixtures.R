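# Shared fixtures, all built in code.

seq_cbs_scheme <- function() {
  build_scheme("sequential", list(k1 = 8e5, k_m1 = 1e-3, k2 = 8e5, k_m2 = 5e-2))
}

feedback_scheme <- function(rates = feedback_demo_rates()) {
  build_scheme("feedback", as.list(rates))
}

random_feedback_state <- function() {
  s <- stats::runif(5, 0, 1e-6)
  names(s) <- c("E", "L", "EL", "ELstar", "E2L")
  s
}

# Rate matrix of a purely first-order scheme: dy/dt = M %*% y
linear_rate_matrix <- function(scheme) {
  S <- stoich_matrix(scheme)
  M <- matrix(0, length(scheme$species), length(scheme$species),
              dimnames = list(scheme$species, scheme$species))
  for (j in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[j]]
    if (rx$rate == 0) next
    stopifnot(sum(rx$reactants) == 1)  # oracle only valid for linear networks
    r <- names(rx$reactants)
    M[, r] <- M[, r] + S$net[, j] * rx$rate
  }
  M
}

expm_trajectory <- function(M, y0, times) {
  t(vapply(times, function(s)
    as.vector(Matrix::expm(M * s) %*% y0), numeric(length(y0))))
}

# relative drift of conserved totals along a trajectory
max_conservation_drift <- function(scheme, traj) {
  B <- conserved_totals(scheme)
  drifts <- apply(B, 2, function(w) {
    tot <- drop(traj$conc %*% w)
    if (abs(tot[1]) == 0) return(0)
    max(abs(tot - tot[1])) / abs(tot[1])
  })
  max(drifts)
}
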