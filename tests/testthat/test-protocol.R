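test_that("default protocol has the documented acquisition structure", {
  p <- build_protocol()
  expect_length(p$timepoint_times_s, 34L)
  expect_equal(p$span_s, 660)  # 30 + 210 + 90 + 210 + 120 s
  expect_equal(diff(p$timepoint_times_s), rep(660 / 34, 33))
  expect_equal(p$segments$irradiance, c(0, 300, 50, 600, 0))
  expect_equal(p$wavelengths, c(420L, 442L, 458L, 505L, 525L))
  expect_equal(p$induction_flashlets, c(32L, 32L, 32L, 40L, 40L))
  expect_equal(p$n_repeats, 5L)
})

test_that("protocol overrides and bounds are enforced", {
  p <- build_protocol(segments = data.frame(irr = 0, dur = 60),
                      n_timepoints = 4L)
  expect_equal(p$timepoint_times_s, c(0, 15, 30, 45))
  expect_error(build_protocol(timepoint_times_s = c(0, 700)), "span")
  expect_error(build_protocol(timepoint_times_s = c(10, 5)), "increasing")
  # segment boundaries at 30/240/330/540 s; boundary times start the new
  # segment
  expect_equal(irradiance_at(build_protocol(), c(0, 31, 250, 330, 500, 650)),
               c(0, 300, 50, 600, 600, 0))
})

test_that("repeat averaging accumulates signal before the fit", {
  truth <- default_truth()
  noiseless <- replicate(5, simulate_st_pair(truth, 442), simplify = FALSE)
  f_avg <- acquire_timepoint(noiseless, dark = TRUE)
  f_one <- st_fit(noiseless[[1]], dark = TRUE)
  expect_equal(coef(f_avg), coef(f_one), tolerance = 1e-9)
  expect_error(acquire_timepoint(list()), "no repeats")
  expect_warning(acquire_timepoint(noiseless[1:3], dark = TRUE), "expected 5")
  # averaged fit beats single-repeat fits on noisy data (most seeds)
  wins <- sapply(1:10, function(i) {
    set.seed(500 + i)
    reps <- replicate(5, simulate_st_pair(truth, 442, noise_cv = 0.01),
                      simplify = FALSE)
    suppressWarnings({
      f5 <- acquire_timepoint(reps, dark = TRUE)
      f1 <- acquire_timepoint(reps[1], n_repeats_expected = 1L, dark = TRUE)
    })
    f5$residual_rms < f1$residual_rms
  })
  expect_gte(mean(wins), 0.9)
  # per-repeat diagnostics path
  prs <- acquire_timepoint(noiseless, per_repeat = TRUE, dark = TRUE)
  expect_length(prs, 5)
})

test_that("metric derivation honours the quenching identities", {
  truth <- default_truth()
  fit_dark <- st_fit(simulate_st_pair(truth, 442), dark = TRUE)
  # dark identity: same fit as reference
  m0 <- derive_metrics(fit_dark, fit_dark)
  v <- setNames(m0$value, m0$metric)
  expect_equal(v[["NPQ"]], 0, tolerance = 1e-6)
  expect_equal(v[["ABQ"]], 0, tolerance = 1e-6)
  expect_equal(v[["qP"]], 1, tolerance = 1e-6)
  expect_equal(v[["PhiPSII"]], fit_dark$phi_PSII, tolerance = 1e-6)
  # Stern-Volmer: halved Fm' gives NPQ = 1
  fit_q <- fit_dark
  fit_q$params$Fm <- fit_dark$params$Fm / 2
  m1 <- derive_metrics(fit_dark, fit_q)
  expect_equal(m1$value[m1$metric == "NPQ"], 1, tolerance = 1e-9)
  # all centers closed: F' = Fm' gives PhiPSII = qP = 0
  fit_c <- fit_dark
  fit_c$params$C0 <- 1
  m2 <- derive_metrics(fit_dark, fit_c)
  expect_equal(m2$value[m2$metric == "PhiPSII"], 0, tolerance = 1e-9)
  expect_equal(m2$value[m2$metric == "qP"], 0, tolerance = 1e-9)
  # non-converged fits propagate missingness, never fabricated values
  bad <- fit_dark
  bad$converged <- FALSE
  expect_true(all(is.na(derive_metrics(fit_dark, bad)$value)))
})

test_that("metric derivation is invariant to instrument rescaling", {
  truth <- default_truth()
  pair <- simulate_st_pair(truth, 442)
  scale_pair <- function(p, k) {
    p$induction$fluorescence <- p$induction$fluorescence * k
    p$relaxation$fluorescence <- p$relaxation$fluorescence * k
    p
  }
  f1 <- st_fit(pair, dark = TRUE)
  f2 <- st_fit(scale_pair(pair, 7.3), dark = TRUE)
  m1 <- derive_metrics(f1, f1)
  m2 <- derive_metrics(f2, f2)
  dimless <- !(m1$metric %in% c("SigmaPSII", "Tau1ST", "Tau2ST"))
  expect_equal(m1$value[dimless], m2$value[dimless], tolerance = 1e-6)
  expect_equal(m2$value[m1$metric == "SigmaPSII"],
               m1$value[m1$metric == "SigmaPSII"], tolerance = 1e-4)
})

test_that("the metric cube holds 1,360 values with a bijective flattening", {
  # full default layout: 8 metrics x 5 wavelengths x 34 timepoints
  recs <- expand.grid(metric = metric_names(),
                      wavelength_nm = c(420, 442, 458, 505, 525),
                      timepoint_index = 1:34, stringsAsFactors = FALSE)
  recs$value <- seq_len(nrow(recs)) * 1.5
  cube <- assemble_metric_cube(recs, "S1")
  expect_equal(prod(dim(cube)), 1360L)
  flat <- flatten_cube(cube)
  expect_length(flat, 1360L)
  expect_equal(names(flat)[1], "PhiPSII_420_1")
  back <- unflatten_cube(flat, "S1")
  expect_equal(unclass(back), unclass(cube))
  # duplicates are an error; missing records are NA-flagged, not invented
  expect_error(assemble_metric_cube(rbind(recs, recs[1, ]), "S1"),
               "duplicate")
  cube3 <- assemble_metric_cube(recs[-(1:3), ], "S1")
  expect_equal(sum(is.na(cube3)), 3L)
  expect_equal(sum(is.finite(flatten_cube(cube3))), 1357L)
  # single cell cube
  small <- assemble_metric_cube(recs[recs$wavelength_nm == 442 &
                                       recs$timepoint_index == 1, ], "S2",
                                wavelengths = 442, n_timepoints = 1L)
  expect_equal(prod(dim(small)), 8L)
  # tidy export carries acquisition times
  td <- cube_to_tidy(cube, build_protocol())
  expect_equal(nrow(td), 1360L)
  expect_equal(sort(unique(td$time_s)), build_protocol()$timepoint_times_s)
})
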