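make_flat <- function(t, level) bk_trace(t, rep(level, length(t)), "anisotropy")

test_that("fraction-bound normalization maps the controls to 0 and 1", {
  t <- seq(0, 1200, 10)
  base <- make_flat(t, 0.06); maxc <- make_flat(t, 0.16)
  raw_hi <- make_flat(t, 0.16)
  expect_equal(to_fraction_bound(raw_hi, base, maxc)$signal, rep(1, length(t)))
  raw_lo <- make_flat(t, 0.06)
  expect_equal(to_fraction_bound(raw_lo, base, maxc)$signal, rep(0, length(t)))
  raw_mid <- make_flat(t, 0.11)
  expect_equal(to_fraction_bound(raw_mid, base, maxc)$signal,
               rep(0.5, length(t)))
})

test_that("normalization is idempotent on already-normalized traces", {
  t <- seq(0, 1200, 10)
  y <- 0.8 * exp(-0.002 * t)
  tr <- bk_trace(t, y, "fraction_bound")
  norm <- to_fraction_bound(tr, make_flat(t, 0), make_flat(t, 1))
  expect_equal(norm$signal, y)
})

test_that("degenerate control dynamic range is rejected", {
  t <- seq(0, 1200, 10)
  expect_error(to_fraction_bound(make_flat(t, 0.1), make_flat(t, 0.1),
                                 make_flat(t, 0.1)),
               "degenerate dynamic range")
})

test_that("reference subtraction cancels common-mode signal and offsets", {
  t <- seq(0, 600, 1)
  s <- bk_trace(t, 500 + 0.01 * t, "delta_RU")
  r <- bk_trace(t, 500 + 0.01 * t, "delta_RU")
  expect_true(all(abs(spr_delta_ru(s, r)$signal) < 1e-12))
  s2 <- bk_trace(t, 507 + 0.01 * t, "delta_RU")
  expect_true(all(abs(spr_delta_ru(s2, r)$signal) < 1e-12))
  expect_error(spr_delta_ru(bk_trace(t + 1000, t, "delta_RU"), r),
               "alignment error")
})

test_that("initial FP rate equals the rate constant of a monoexponential rise", {
  t <- seq(0, 600, 2)
  y <- 0.06 + 0.1 * (1 - exp(-0.01 * t))
  r <- initial_rate_fp(bk_trace(t, y, "anisotropy"))
  expect_equal(r, 0.01, tolerance = 0.02)
  # affine invariance: same rate on any linear transform of the signal
  r2 <- initial_rate_fp(bk_trace(t, 3.7 * y - 1.2, "anisotropy"))
  expect_equal(r2, r, tolerance = 1e-9)
})

test_that("initial FP rate of a biphasic rise is the amplitude-weighted rate sum", {
  t <- seq(0, 3600, 2)
  p <- list(A_min = 0, A_max = 1, k_fast = 0.015, k_slow = 0.001,
            beta_fast = 0.65)
  r <- initial_rate_fp(bk_trace(t, eval_model("assoc_biexp", p, t),
                                "fraction_bound"))
  expect_equal(r, 0.65 * 0.015 + 0.35 * 0.001, tolerance = 0.05)
})

test_that("SPR initial rates follow the windowed-slope definition", {
  # linear ramp reaching its plateau exactly at the segment end
  t <- seq(0, 100, 0.5)
  ramp <- bk_trace(t, t / 100, "delta_RU")
  expect_equal(initial_rate_spr(ramp), 1 / 100, tolerance = 1e-9)
  # exact monoexponential: closed-form windowed slope over the dynamic range
  k <- 0.02; T <- 300
  t2 <- seq(0, T, 0.5)
  tr <- bk_trace(t2, 80 * (1 - exp(-k * t2)), "delta_RU")
  expected <- (1 - exp(-3 * k)) / 3 / (1 - exp(-k * T))
  expect_equal(initial_rate_spr(tr), expected, tolerance = 1e-6)
  expect_error(initial_rate_spr(bk_trace(t2, rep(0, length(t2)), "delta_RU")),
               "excluded point")
})

test_that("zero-intercept kon regression recovers exact linear rate series", {
  E <- c(1, 2, 4, 8) * 1e-8
  rs <- rate_series(E, 1e6 * E)
  out <- fit_kon(rs)
  expect_equal(out$kon, 1e6, tolerance = 1e-10)
  expect_true(all(out$mask))
  one <- fit_kon(rate_series(2e-8, 0.03))
  expect_equal(one$kon, 0.03 / 2e-8)
})

test_that("auto-pruning excludes the high-concentration plateau", {
  E <- c(12.5, 25, 50, 100, 200, 400, 800) * 1e-9
  r <- pmin(1e6 * E, 1e6 * 150e-9)  # linear then flat above ~150 nM
  auto <- fit_kon(rate_series(E, r), pruning = "auto")
  manual <- fit_kon(rate_series(E, r), pruning = E <= 100e-9)
  expect_equal(auto$mask, c(rep(TRUE, 4), rep(FALSE, 3)))
  expect_equal(auto$kon, manual$kon)
  expect_equal(auto$kon, 1e6, tolerance = 1e-10)
  expect_error(fit_kon(rate_series(E, r), pruning = rep(FALSE, 7)),
               "empty regime")
})

test_that("koff/kon ratios reproduce the printed apparent Kd values", {
  expect_identical(format_kd(kd_from_rates(7.3e-4, 5.8e4)), "13 nM")
  expect_identical(format_kd(kd_from_rates(5.0e-2, 7.5e5)), "67 nM")
  expect_identical(kd_from_rates(0, 1e6), 0)
  expect_error(kd_from_rates(1e-3, 0), "division error")
})

test_that("equilibrium averaging warns on unequilibrated traces", {
  t <- seq(0, 1800, 5)
  expect_equal(equilibrium_signal(bk_trace(t, rep(0.3, length(t)), "anisotropy")),
               0.3)
  rise <- 0.3 * (1 - exp(-0.01 * t))
  expect_equal(equilibrium_signal(bk_trace(t, rise, "anisotropy")), 0.3,
               tolerance = 1e-3)
  expect_warning(equilibrium_signal(bk_trace(t, 1e-4 * t, "anisotropy")),
                 "not equilibrated")
})
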