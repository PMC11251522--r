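test_that("a scheme with all-zero rates stays constant", {
  sch <- build_scheme("sequential", list())
  y0 <- c(E = 1e-7, L = 5e-9, EL = 1e-9, E2L = 0)
  traj <- integrate_scheme(sch, y0, duration = 100, dt_out = 10)
  expect_true(all(abs(sweep(traj$conc, 2, y0[colnames(traj$conc)])) < 1e-18))
})

test_that("simple binding equilibrates to the tight-binding closed form", {
  sch <- build_scheme("sequential", list(k1 = 1e6, k_m1 = 1e-3))
  ET <- 1e-7; LT <- 5e-9; Kd <- 1e-3 / 1e6
  y0 <- c(E = ET, L = LT, EL = 0, E2L = 0)
  traj <- integrate_scheme(sch, y0, duration = 5e4, dt_out = 100)
  b <- ET + LT + Kd
  el_closed <- (b - sqrt(b^2 - 4 * ET * LT)) / 2
  el_end <- unname(traj$conc[nrow(traj$conc), "EL"])
  expect_equal(el_end, el_closed, tolerance = 1e-4)
})

test_that("linear dissociation networks match the matrix-exponential oracle", {
  # post-dilution sequential scheme with rebinding removed: purely first order
  sch <- build_scheme("sequential", list(k_m1 = 1e-3, k_m2 = 5e-2))
  y0 <- c(E = 0, L = 0, EL = 5e-16, E2L = 4.5e-15)
  traj <- integrate_scheme(sch, y0, duration = 3600, dt_out = 60,
                           rel_tol = 1e-10, abs_tol = 1e-25)
  M <- linear_rate_matrix(sch)
  oracle <- expm_trajectory(M, y0[sch$species], traj$time)
  # relative agreement down to 1e-3 of the dominant concentration scale
  scale_ref <- max(abs(y0))
  rel <- abs(traj$conc - oracle) / pmax(abs(oracle), 1e-3 * scale_ref)
  expect_lt(max(rel), 1e-6)
})

test_that("two-phase runs are dilution-invariant in the observable and continuous at d_f = 1", {
  sch <- seq_cbs_scheme()
  proto <- sim_protocol(t_on = 1800, t_off = 900, dilution_factor = 1e6)
  run <- run_two_phase(sch, proto, 5e-7)
  expect_identical(run$dissociation$signal[1],
                   run$association$signal[length(run$association$signal)])
  proto1 <- sim_protocol(t_on = 36000, t_off = 900, dilution_factor = 1)
  run1 <- run_two_phase(sch, proto1, 5e-7)
  expect_lt(diff(range(run1$dissociation$signal)), 1e-6)
})

test_that("feedback association at high protein is monotone non-decreasing", {
  proto <- sim_protocol(t_off = 60, rel_tol = 1e-12, abs_tol = 1e-18)
  run <- run_two_phase(feedback_scheme(), proto, 1e-6)
  expect_gte(min(diff(run$association$signal)), -1e-9)
})

test_that("the output grid is a sampling grid, not the integration step", {
  sch <- feedback_scheme()
  proto_a <- sim_protocol(dt_out = 2, t_on = 600, t_off = 60)
  proto_b <- sim_protocol(dt_out = 1, t_on = 600, t_off = 60)
  ra <- run_two_phase(sch, proto_a, 2^-6 * 1e-6)
  rb <- run_two_phase(sch, proto_b, 2^-6 * 1e-6)
  shared <- match(ra$association$time, rb$association$time)
  expect_lt(max(abs(ra$association$signal - rb$association$signal[shared])), 1e-6)
})

test_that("titrations produce one experiment per grid point and match the closed form", {
  sch <- build_scheme("sequential", list(k1 = 1e6, k_m1 = 1e-3))
  grid <- 2^seq(-12, 0) * 1e-6
  proto <- sim_protocol(t_on = 4e4, t_off = 10, dt_out = 20,
                        E_total_grid = grid)
  tit <- run_titration(sch, proto)
  expect_length(tit$experiments, 13)
  expect_length(tit$isotherm$E_total, 13)
  Kd <- 1e-9; LT <- proto$L_total
  b <- grid + LT + Kd
  frac <- (b - sqrt(b^2 - 4 * grid * LT)) / (2 * LT)
  expect_equal(tit$isotherm$signal, 0.5 * frac, tolerance = 1e-4)
})

test_that("a zero-protein titration point gives zero observable", {
  sch <- seq_cbs_scheme()
  proto <- sim_protocol(t_on = 60, t_off = 60, E_total_grid = 0)
  tit <- run_titration(sch, proto)
  expect_true(all(tit$isotherm$signal == 0))
})

test_that("incubation equal to t_on reproduces the standard two-phase run", {
  sch <- seq_cbs_scheme()
  proto <- sim_protocol(t_on = 1200, t_off = 300)
  ref <- run_two_phase(sch, proto, 5e-7)
  vi <- run_variable_incubation(sch, proto, 5e-7, incubation_times = 1200)
  expect_equal(vi[[1]]$dissociation$signal, ref$dissociation$signal)
})

test_that("short incubations ablate the slow dissociation phase of a locked-conformation scheme", {
  sch <- build_scheme("locked", list(k1 = 1e6, k_m1 = 5e-3, k2 = 1e-3,
                                     k_m2 = 1e-4))
  proto <- sim_protocol(t_on = 14400, t_off = 3600, dilution_factor = 1e6,
                        dt_out = 5)
  runs <- run_variable_incubation(sch, proto, 3e-8,
                                  incubation_times = c(120, 14400))
  slow_frac <- vapply(runs, function(r) {
    f <- fit_dissociation(r$dissociation, A_max = r$dissociation$signal[1])
    1 - f$estimate[["beta_fast"]]
  }, numeric(1))
  expect_lt(slow_frac[1], slow_frac[2])
  # incomplete association: short incubation starts dissociation lower
  expect_lt(runs[[1]]$dissociation$signal[1], runs[[2]]$dissociation$signal[1])
})

test_that("conserved totals drift less than 1e-6 along simulated trajectories", {
  fb <- feedback_scheme()
  proto <- sim_protocol(t_on = 1800, t_off = 600)
  for (ET in c(2^-6, 1) * 1e-6) {
    run <- run_two_phase(fb, proto, ET)
    expect_lt(max_conservation_drift(fb, run$phase1), 1e-6)
    expect_lt(max_conservation_drift(fb, run$phase2), 1e-6)
  }
  sq <- seq_cbs_scheme()
  run <- run_two_phase(sq, proto, 5e-7)
  expect_lt(max_conservation_drift(sq, run$phase1), 1e-6)
})

test_that("the verbatim free-protein equation leaks protein along a trajectory", {
  rates <- feedback_demo_rates()
  y0 <- c(E = 1e-7, L = 5e-9, EL = 0, ELstar = 0, E2L = 0)
  w <- c(E = 1, L = 0, EL = 1, ELstar = 1, E2L = 2)
  tv <- integrate_feedback(rates, y0, duration = 1800, dt_out = 10,
                           verbatim = TRUE)
  tot_v <- drop(tv$conc[, names(w)] %*% w)
  expect_true(all(diff(tot_v) > 0))
  tc <- integrate_feedback(rates, y0, duration = 1800, dt_out = 10)
  tot_c <- drop(tc$conc[, names(w)] %*% w)
  expect_lt(max(abs(tot_c - tot_c[1])) / tot_c[1], 1e-6)
})
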