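test_that("feedback rate equations activate only the initial binding pathway from free species", {
  rates <- feedback_demo_rates()
  st <- c(E = 1e-6, L = 5e-9, EL = 0, ELstar = 0, E2L = 0)
  d <- feedback_rhs(st, rates)
  flux <- rates[["k1"]] * st[["E"]] * st[["L"]]
  expect_equal(d[["EL"]], flux)
  expect_equal(d[["L"]], -flux)
  expect_equal(d[["ELstar"]], 0)
  expect_equal(d[["E2L"]], 0)
})

test_that("conserving form preserves protein and ligand totals; verbatim form leaks protein at k3b*E*EL", {
  rates <- feedback_demo_rates()
  w_protein <- c(E = 1, L = 0, EL = 1, ELstar = 1, E2L = 2)
  w_ligand <- c(E = 0, L = 1, EL = 1, ELstar = 1, E2L = 1)
  set.seed(42)
  for (i in 1:50) {
    st <- random_feedback_state()
    d <- feedback_rhs(st, rates)
    expect_equal(sum(w_protein * d[names(w_protein)]), 0, tolerance = 1e-12)
    expect_equal(sum(w_ligand * d[names(w_ligand)]), 0, tolerance = 1e-12)
    dv <- feedback_rhs(st, rates, verbatim = TRUE)
    leak <- rates[["k3b"]] * st[["E"]] * st[["EL"]]
    expect_equal(sum(w_protein * dv[names(w_protein)]), leak, tolerance = 1e-9)
  }
  # with k3b = 0 the two forms agree exactly
  r0 <- rate_constants(k1 = 1e6, k_m1 = 1e-3, k2 = 1e-5, k_m2 = 3e-3,
                       k3 = 1e9, k_m3 = 2e-2, k_alpha = 2e7, k_beta = 2e6)
  st <- random_feedback_state()
  expect_identical(feedback_rhs(st, r0), feedback_rhs(st, r0, verbatim = TRUE))
})

test_that("derivatives never drive an exactly-zero species negative", {
  rates <- feedback_demo_rates()
  set.seed(7)
  for (i in 1:20) {
    st <- random_feedback_state()
    for (sp in names(st)) {
      st2 <- st; st2[sp] <- 0
      expect_gte(feedback_rhs(st2, rates)[[sp]], 0)
    }
  }
})

test_that("negative input concentrations beyond tolerance are rejected", {
  st <- c(E = -1e-6, L = 5e-9, EL = 0, ELstar = 0, E2L = 0)
  expect_error(feedback_rhs(st, feedback_demo_rates()), "invalid state")
})

test_that("relative anisotropy weighs species by protein stoichiometry", {
  expect_equal(relative_anisotropy(c(L = 1e-9, EL = 0, ELstar = 0, E2L = 0)), 0)
  expect_equal(relative_anisotropy(c(L = 0, EL = 0, ELstar = 0, E2L = 3e-9)), 1)
  expect_equal(relative_anisotropy(c(L = 0, EL = 2e-9, ELstar = 2e-9, E2L = 0)), 0.5)
  expect_error(relative_anisotropy(c(L = 0, EL = 0, ELstar = 0, E2L = 0)),
               "undefined observable")
})

test_that("relative anisotropy is invariant under uniform dilution", {
  set.seed(11)
  for (i in 1:20) {
    st <- random_feedback_state() + 1e-12
    for (f in c(10, 1e3, 1e6))
      expect_equal(relative_anisotropy(st / f), relative_anisotropy(st))
  }
})

test_that("sequential scheme has the expected structure", {
  sch <- seq_cbs_scheme()
  expect_length(sch$reactions, 4)
  expect_setequal(sch$species, c("E", "L", "EL", "E2L"))
})

test_that("feedback scheme mass-action derivatives equal the dedicated rate equations", {
  rates <- feedback_demo_rates()
  sch <- feedback_scheme(rates)
  set.seed(3)
  for (i in 1:100) {
    st <- random_feedback_state()
    expect_equal(mass_action_rhs(sch, st)[names(st)],
                 feedback_rhs(st, rates)[names(st)], tolerance = 1e-12)
  }
})

test_that("locked complex cannot release ligand in one step", {
  sch <- build_scheme("locked", list(k1 = 1e6, k_m1 = 1e-3, k2 = 1e-3,
                                     k_m2 = 1e-4))
  for (rx in sch$reactions) {
    if ("EL_locked" %in% names(rx$reactants))
      expect_false(all(c("E", "L") %in% names(rx$products)))
  }
})

test_that("unknown scheme names are rejected", {
  expect_error(build_scheme("soup"), "unsupported scheme")
})

test_that("mass-action rate laws follow stoichiometry", {
  sch <- reaction_scheme(c("A", "B", "C"),
                         list(reaction(c(A = 1, B = 1), c(C = 1), 2)))
  d <- mass_action_rhs(sch, c(A = 3, B = 4, C = 0))
  expect_equal(d[["C"]], 24)
  expect_equal(d[["A"]], -24)
  expect_equal(d[["B"]], -24)
  empty <- reaction_scheme(c("A", "B"), list())
  expect_equal(mass_action_rhs(empty, c(A = 1, B = 2)), c(A = 0, B = 0))
  expect_error(mass_action_rhs(sch, c(A = 1, B = 1)), "match the scheme")
})

test_that("left null space vectors of the stoichiometric matrix are conserved", {
  set.seed(5)
  for (sch in list(feedback_scheme(), seq_cbs_scheme())) {
    B <- conserved_totals(sch)
    S <- stoich_matrix(sch)$net
    expect_true(all(abs(t(B) %*% S) < 1e-9))
    for (i in 1:25) {
      st <- stats::runif(length(sch$species), 0, 1e-6)
      names(st) <- sch$species
      d <- mass_action_rhs(sch, st)
      expect_true(all(abs(t(B) %*% d) < 1e-6 * max(abs(d), 1e-300)))
    }
  }
})

test_that("conserved totals include protein and ligand totals", {
  in_span <- function(B, w) {
    # w lies in the column span of B
    resid <- w - B %*% solve(crossprod(B), crossprod(B, w))
    max(abs(resid)) < 1e-8
  }
  fb <- feedback_scheme()
  B <- conserved_totals(fb)
  expect_equal(ncol(B), 2)
  prot <- c(E = 1, L = 0, EL = 1, ELstar = 1, E2L = 2)[fb$species]
  lig <- c(E = 0, L = 1, EL = 1, ELstar = 1, E2L = 1)[fb$species]
  expect_true(in_span(B, prot))
  expect_true(in_span(B, lig))
  sq <- seq_cbs_scheme()
  Bs <- conserved_totals(sq)
  expect_true(in_span(Bs, c(E = 1, L = 0, EL = 1, E2L = 2)[sq$species]))
  iso <- reaction_scheme(c("A", "B"), list(reaction(c(A = 1), c(B = 1), 1)))
  Bi <- conserved_totals(iso)
  expect_equal(ncol(Bi), 1)
  expect_true(in_span(Bi, c(1, 1)))
})

test_that("schemes serialize to plain text and back", {
  sch <- feedback_scheme()
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, path)
  sch2 <- read_scheme(path)
  expect_equal(sch2$species, sch$species)
  expect_equal(sch2$weights[sch2$species[-1]], sch$weights[sch2$species[-1]])
  st <- random_feedback_state()
  expect_equal(mass_action_rhs(sch2, st), mass_action_rhs(sch, st))
})
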