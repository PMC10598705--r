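test_that("fluorescence yield maps closure through the connected-units model", {
  # boundary identities
  expect_equal(yield_from_closure(0, 1000, 3000, 0.3), 1000)
  expect_equal(yield_from_closure(1, 1000, 3000, 0.3), 3000)
  # hand arithmetic: 1000 + 2000 * 0.5*0.6/0.8
  expect_equal(yield_from_closure(0.5, 1000, 3000, 0.4), 1750)
  # linear in C at rho = 0
  C <- seq(0, 1, by = 0.05)
  expect_equal(yield_from_closure(C, 800, 2400, 0), 800 + 1600 * C)
  # bounded and strictly increasing for rho > 0
  f <- yield_from_closure(C, 1000, 3000, 0.6)
  expect_true(all(f >= 1000 & f <= 3000))
  expect_true(all(diff(f) > 0))
  # domain errors
  expect_error(yield_from_closure(1.2, 1000, 3000, 0.3), "closed fraction")
  expect_error(yield_from_closure(0.5, 1000, 3000, 1), "rho")
  expect_error(yield_from_closure(0.5, 3000, 1000, 0.3), "Fm > F0")
})

test_that("flashlet schedules enforce the acquisition timing invariants", {
  ind <- induction_schedule(32)
  expect_equal(length(ind$times_us), 32L)
  expect_equal(diff(ind$times_us), rep(4.7, 31))  # 1.3 us flash + 3.4 us gap
  rel <- relaxation_schedule(40)
  expect_equal(length(rel$times_us), 40L)
  gaps <- diff(rel$times_us)
  expect_true(all(diff(gaps) > 0))            # strictly growing dark gaps
  expect_equal(rel$times_us[1], 59, tolerance = 1e-9)
  expect_equal(max(rel$times_us), 3e5, tolerance = 1e-6)
  expect_error(flashlet_schedule("induction", c(3, 2, 5)), "increasing")
  expect_error(flashlet_schedule("relaxation", cumsum(c(59, 40, 30))),
               "gaps")
  expect_error(flashlet_schedule("relaxation", c(59, 4e5)), "300 ms")
})

test_that("wavelengths canonicalize and set induction flashlet counts", {
  expect_equal(canonical_wavelength(520), 525L)
  expect_equal(induction_flashlets_for(c(420, 442, 458)), rep(32L, 3))
  expect_equal(induction_flashlets_for(c(505, 520, 525)), rep(40L, 3))
  expect_error(canonical_wavelength(600), "unknown")
})

test_that("induction forward model saturates, bounds and orders correctly", {
  p <- default_truth()
  sch <- induction_schedule(32)
  tr <- simulate_induction(p, sch)
  expect_true(all(diff(tr$fluorescence) >= 0))    # monotone, reopening off
  expect_true(all(tr$fluorescence >= p$F0 & tr$fluorescence <= p$Fm))
  # zero dose: constant at F0
  sch0 <- induction_schedule(32, dose_per_flashlet = 0)
  expect_equal(simulate_induction(p, sch0)$fluorescence, rep(p$F0, 32))
  # saturating dose: final flashlet within 1% of Fm
  schs <- induction_schedule(32, dose_per_flashlet = 5e-3)
  expect_equal(tail(simulate_induction(p, schs)$fluorescence, 1), p$Fm,
               tolerance = 0.01)
  expect_error(simulate_induction(p, relaxation_schedule()), "induction")
})

test_that("closure recursion matches a fine-step dose-integration oracle", {
  for (rho in c(0, 0.3, 0.6)) {
    p <- default_truth(rho = rho)
    for (n_fl in c(32L, 40L)) {
      sch <- induction_schedule(n_fl)
      C <- closure_recursion(p, sch)
      expect_lt(max(abs(C / closure_oracle(p, sch) - 1)), 0.005)
    }
  }
  # cumulative sigma*dose*J ~ 3 reaches ~95% of Fv (saturation example)
  p <- default_truth(sigma_PSII = 500, rho = 0.3)
  sch <- induction_schedule(32, dose_per_flashlet = 3 / (500 * 32))
  tr <- simulate_induction(p, sch)
  frac <- (tail(tr$fluorescence, 1) - p$F0) / (p$Fm - p$F0)
  expect_gt(frac, 0.93)
})

test_that("relaxation decays biexponentially from the induction end state", {
  p <- default_truth(alpha = 1, tau1_us = 600, tau2_us = 15000)
  sch <- relaxation_schedule(40)
  tr <- simulate_relaxation(p, C_end = 0.8, sch)
  expect_true(all(diff(tr$fluorescence) <= 0))
  # single-exponential e-folding: C(tau1) = C_end / e
  C_at <- function(t) 0.8 * exp(-t / 600)
  f_exp <- yield_from_closure(C_at(sch$times_us), p$F0, p$Fm, p$rho)
  expect_equal(tr$fluorescence, f_exp, tolerance = 1e-12)
  # t -> infinity returns to F0
  sch_far <- flashlet_schedule("relaxation", cumsum(59 * 1.25^(0:29)))
  trf <- simulate_relaxation(default_truth(tau2_us = 2000), 1, sch_far)
  expect_equal(tail(trf$fluorescence, 1), 1000, tolerance = 1)
  expect_error(simulate_relaxation(p, 0, sch), "degenerate")
  expect_error(simulate_relaxation(p, 0.5, induction_schedule()),
               "relaxation")
})

test_that("paired simulation is continuous across phases and reproducible", {
  p <- default_truth()
  pair <- simulate_st_pair(p, 442)
  # relaxation starts from the induction end closure
  f_start <- yield_from_closure(pair$C_end * (p$alpha * exp(-59 / p$tau1_us) +
                                  (1 - p$alpha) * exp(-59 / p$tau2_us)),
                                p$F0, p$Fm, p$rho)
  expect_equal(pair$relaxation$fluorescence[1], f_start, tolerance = 1e-9)
  set.seed(11); a <- simulate_st_pair(p, 442, noise_cv = 0.01)
  set.seed(11); b <- simulate_st_pair(p, 442, noise_cv = 0.01)
  expect_identical(a$induction$fluorescence, b$induction$fluorescence)
  # trace validation
  expect_error(st_trace(442, induction_schedule(32), rep(-1, 32)),
               "positive")
  expect_error(st_trace(442, induction_schedule(32), rep(1, 31)), "length")
})
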