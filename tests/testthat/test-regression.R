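test_that("forward model evaluation obeys the defining identities", {
  # Hill signal is the midpoint at E_T = Kd for any n
  for (n in c(0.5, 1, 2.1))
    expect_equal(eval_model("hill", list(A_min = 0.1, A_max = 0.5, Kd = 1e-8,
                                         n = n), 1e-8), 0.3)
  # saturation at large E_T
  expect_equal(eval_model("hill", list(A_min = 0, A_max = 1, Kd = 1e-8, n = 2),
                          1e-2), 1, tolerance = 1e-10)
  # biexponential decay with beta_fast = 1 halves at t = ln 2 / k_fast
  expect_equal(eval_model("dissoc_biexp",
                          list(A_min = 0.2, A_max = 0.8, k_fast = 1e-2,
                               k_slow = 1e-3, beta_fast = 1), log(2) / 1e-2),
               0.5)
  # two-transition curve is the alpha-weighted sum of its sub-curves
  E <- 10^seq(-10, -6, length.out = 7); LT <- 5e-9
  p <- list(A_min = 0, A_max = 1, Kd1 = 1e-9, Kd2 = 4.2e-7, alpha = 0.54,
            L_total = LT)
  p1 <- modifyList(p, list(alpha = 1)); p0 <- modifyList(p, list(alpha = 0))
  expect_equal(eval_model("two_transition", p, E),
               0.54 * eval_model("two_transition", p1, E) +
                 0.46 * eval_model("two_transition", p0, E))
  # biphasic association with beta_fast = 1 is the monophasic curve
  t <- seq(0, 100, 5)
  expect_equal(eval_model("assoc_biexp",
                          list(A_min = 0, A_max = 1, k_fast = 0.05,
                               k_slow = 0.01, beta_fast = 1), t),
               eval_model("assoc_mono",
                          list(A_min = 0, A_max = 1, k_on = 0.05), t))
  # both association forms start at A_min
  expect_equal(eval_model("assoc_mono",
                          list(A_min = 0.06, A_max = 0.16, k_on = 0.01), 0), 0.06)
  # invariant violations are rejected
  expect_error(eval_model("hill", list(A_min = 1, A_max = 0, Kd = 1e-8, n = 1),
                          1e-8), "parameter error")
  expect_error(eval_model("dissoc_biexp",
                          list(A_min = 0, A_max = 1, k_fast = 1e-3,
                               k_slow = 1e-2, beta_fast = 0.5), 1),
               "parameter error")
})

test_that("Hill regression recovers generating parameters from a noiseless isotherm", {
  E <- 2000e-9 * 2^-(0:14)
  iso <- make_isotherm("hill", list(A_min = 0.05, A_max = 0.17, Kd = 11e-9,
                                    n = 2.1), E)
  fit <- fit_hill(iso)
  expect_true(fit$converged)
  expect_equal(fit$estimate[["Kd"]], 11e-9, tolerance = 1e-4)
  expect_equal(fit$estimate[["n"]], 2.1, tolerance = 1e-4)
  expect_equal(fit$estimate[["A_min"]], 0.05, tolerance = 1e-4)
  expect_equal(fit$estimate[["A_max"]], 0.17, tolerance = 1e-4)
})

test_that("a Kd far outside the sampled range is flagged, not raised", {
  E <- 2^seq(0, 8) * 1e-10  # up to 25.6 nM, far below the generating Kd
  iso <- make_isotherm("hill", list(Kd = 1e-5, n = 1), E)
  # with a known saturation level the Kd is identified and lands > 100x
  # beyond the sampled range; the fit reports it instead of failing
  fit <- fit_hill(iso, bounds = list(lower = c(A_max = 1), upper = c(A_max = 1)))
  expect_true(fit$converged)
  expect_true(any(grepl("outside data range", fit$flags)))
})

test_that("two-transition regression recovers parameters and honors Kd ordering", {
  E <- 2^seq(0, 14) * 1e-10
  iso <- make_isotherm("two_transition",
                       list(Kd1 = 1e-9, Kd2 = 420e-9, alpha = 0.54), E,
                       L_total = 5e-9)
  fit <- fit_two_transition(iso)
  expect_equal(fit$estimate[["Kd1"]], 1e-9, tolerance = 1e-3)
  expect_equal(fit$estimate[["Kd2"]], 420e-9, tolerance = 1e-3)
  expect_equal(fit$estimate[["alpha"]], 0.54, tolerance = 1e-3)
  expect_lte(fit$estimate[["Kd1"]], fit$estimate[["Kd2"]])
})

test_that("a single-transition curve pins alpha and warns about degeneracy", {
  E <- 2^seq(0, 14) * 1e-10
  iso <- make_isotherm("two_transition",
                       list(Kd1 = 2e-9, Kd2 = 2.0001e-9, alpha = 1), E,
                       L_total = 5e-9)
  expect_warning(fit_two_transition(iso), "degenerate")
})

test_that("association fits round-trip noiseless curves", {
  t <- seq(0, 2700, 3)
  tr3 <- bk_trace(t, eval_model("assoc_mono",
                                list(A_min = 0.06, A_max = 0.16, k_on = 0.01), t),
                  "anisotropy")
  f3 <- fit_association(tr3, n_phases = 1)
  expect_equal(f3$estimate[["k_on"]], 0.01, tolerance = 1e-6)
  p4 <- list(A_min = 0, A_max = 1, k_fast = 0.015, k_slow = 0.001,
             beta_fast = 0.65)
  tr4 <- bk_trace(t, eval_model("assoc_biexp", p4, t), "fraction_bound")
  f4 <- fit_association(tr4, n_phases = 2)
  for (nm in names(p4))
    expect_equal(f4$estimate[[nm]], p4[[nm]], tolerance = 1e-3)
  # information-criterion selection picks the biphasic model on its own
  fsel <- fit_association(tr4)
  expect_identical(fsel$model, "assoc_biexp")
})

test_that("association fit warns when phases are not separated", {
  t <- seq(0, 2700, 3)
  y <- eval_model("assoc_biexp",
                  list(A_min = 0, A_max = 1, k_fast = 2e-3, k_slow = 1e-3,
                       beta_fast = 0.5), t)
  expect_warning(fit_association(bk_trace(t, y, "fraction_bound"), n_phases = 2),
                 "indistinguishable")
})

test_that("the fit window restricts association data before fitting", {
  t <- seq(0, 5400, 3)
  y <- eval_model("assoc_mono", list(A_min = 0, A_max = 1, k_on = 0.01), t)
  f <- fit_association(bk_trace(t, y, "fraction_bound"), n_phases = 1,
                       window = 600)
  expect_equal(f$n, sum(t <= 600))
  expect_equal(f$estimate[["k_on"]], 0.01, tolerance = 1e-6)
})

test_that("dissociation fits honor constraints exactly", {
  t <- seq(0, 3600, 5)
  p <- list(A_min = 0.02, A_max = 0.95, k_fast = 5e-2, k_slow = 1e-3,
            beta_fast = 0.67)
  y <- eval_model("dissoc_biexp", p, t)
  # fixed A_max stays bit-identical
  f <- fit_dissociation(bk_trace(t, y, "fraction_bound"), A_max = 0.95)
  expect_identical(f$estimate[["A_max"]], 0.95)
  expect_true(f$constraints$A_max_fixed)
  for (nm in c("k_fast", "k_slow", "beta_fast"))
    expect_equal(f$estimate[[nm]], p[[nm]], tolerance = 1e-3)
  expect_equal(f$derived$pct_fast, 67, tolerance = 1e-3)
  # monophasic constraint forces k_fast = 0, beta_fast = 0
  y1 <- eval_model("dissoc_biexp",
                   list(A_min = 0, A_max = 1, k_fast = 0, k_slow = 1e-3,
                        beta_fast = 0), t)
  fm <- fit_dissociation(bk_trace(t, y1, "fraction_bound"), monophasic = TRUE)
  expect_identical(fm$estimate[["k_fast"]], 0)
  expect_identical(fm$estimate[["beta_fast"]], 0)
  expect_equal(fm$estimate[["k_slow"]], 1e-3, tolerance = 1e-6)
  expect_true(fm$constraints$monophasic)
})

test_that("an increasing trace is rejected as not a decay", {
  t <- seq(0, 100, 1)
  expect_error(fit_dissociation(bk_trace(t, 0.1 + 0.001 * t, "fraction_bound")),
               "not a decay")
})

test_that("reported phases are always ordered k_fast >= k_slow", {
  t <- seq(0, 3600, 5)
  set.seed(9)
  for (i in 1:5) {
    kf <- 10^stats::runif(1, -2.5, -1.5)
    ks <- kf / 10^stats::runif(1, 1, 2)
    y <- eval_model("dissoc_biexp",
                    list(A_min = 0, A_max = 1, k_fast = kf, k_slow = ks,
                         beta_fast = stats::runif(1, 0.3, 0.7)), t) +
      stats::rnorm(length(t), 0, 0.002)
    f <- fit_dissociation(bk_trace(t, y, "fraction_bound"))
    expect_gte(f$estimate[["k_fast"]], f$estimate[["k_slow"]])
  }
})
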