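test_that("the default cohort matches the study design and is reproducible", {
  cfg <- cohort_config()
  expect_equal(cfg$n_colonies * cfg$n_fragments, 60L)
  a <- generate_cohort(cfg, seed = 7, level = "metrics")
  expect_equal(nrow(a$truth), 60L)
  expect_equal(length(unique(a$truth$colony)), 20L)
  expect_setequal(unique(a$truth$dominant_type),
                  c("C1", "C3", "C15", "C21", "C26", "D1"))
  expect_equal(sort(unique(a$truth$archetype)), 1:4)
  b <- generate_cohort(cfg, seed = 7, level = "metrics")
  expect_identical(lapply(a$cubes, unclass), lapply(b$cubes, unclass))
  expect_identical(a$traits, b$traits)
  expect_identical(a$its2, b$its2)
  c2 <- generate_cohort(cfg, seed = 8, level = "metrics")
  expect_false(identical(a$its2$count, c2$its2$count))
  expect_error(cohort_config(archetype_of_colony = rep(9L, 20)),
               "undefined archetype")
})

test_that("archetypes encode the qualitative phenotype orderings", {
  arch <- default_archetypes()
  npq <- vapply(arch, `[[`, numeric(1), "npq_amp")
  tau2 <- vapply(arch, `[[`, numeric(1), "tau2_us")
  qpd <- vapply(arch, `[[`, numeric(1), "qp_dep")
  expect_equal(which.max(npq), 1L)   # archetype 1: largest NPQ response
  expect_equal(which.max(tau2), 1L)  # and slowest tau2
  expect_equal(which.min(npq), 2L)   # archetype 2: flattest NPQ
  expect_equal(which.max(qpd), 2L)   # and deepest sustained qP depression
  # trajectories respect the orderings at the high-light segment
  prot <- build_protocol()
  cubes <- lapply(arch, archetype_metric_cube, protocol = prot)
  hi <- which(irradiance_at(prot, prot$timepoint_times_s) == 600)
  npq_hi <- vapply(cubes, function(cb) max(cb["NPQ", "442", hi]), numeric(1))
  qp_hi <- vapply(cubes, function(cb) min(cb["qP", "442", hi]), numeric(1))
  expect_equal(which.max(npq_hi), 1L)
  expect_equal(which.min(npq_hi), 2L)
  expect_equal(which.min(qp_hi), 2L)
  # sigma declines from blue to green excitation
  sig_by_w <- cubes[[1]]["SigmaPSII", , 1]
  expect_true(all(diff(sig_by_w) < 0))
})

test_that("zero-noise metric cohorts reproduce archetype trajectories", {
  cfg <- tiny_config(colony_cv = 0, fragment_cv = 0, metric_noise_cv = 0)
  coh <- generate_cohort(cfg, seed = 1, level = "metrics")
  tru <- archetype_metric_cube(default_archetypes()[[1]], cfg$protocol)
  smp <- coh$cubes[[which(coh$truth$archetype == 1)[1]]]
  expect_equal(as.vector(smp), as.vector(tru), tolerance = 1e-9)
})

test_that("generated traces satisfy the trace invariants", {
  cfg <- tiny_config(n_colonies = 2L, archetype_of_colony = c(1L, 2L),
                     dominant_type_of_colony = c("C15", "D1"))
  coh <- generate_cohort(cfg, seed = 3, level = "traces")
  for (smp in coh$traces) {
    for (wv in smp$wavelengths) {
      expect_true(all(is.finite(wv$induction)) && all(wv$induction > 0))
      expect_true(all(is.finite(wv$relaxation)) && all(wv$relaxation > 0))
      n_expected <- induction_flashlets_for(wv$wavelength_nm)
      expect_equal(dim(wv$induction)[3], n_expected)
    }
  }
})

test_that("planted trait correlations carry the configured structure", {
  cfg <- cohort_config()
  hits <- t(sapply(1:25, function(s) {
    coh <- generate_cohort(cfg, seed = s, level = "metrics")
    ct <- aggregate_traits(coh$traits, coh$truth)
    lat <- coh$latents
    c(np_phi = cor(ct$NP, lat$mean_phi),
      np_tau2 = cor(ct$NP, lat$mean_tau2),
      cp_npq = cor(ct$CP, lat$npq_amp),
      ctrl = abs(cor(ct$control_a, lat$mean_phi)))
  }))
  # planted signs with |r| above the network threshold in most seeds
  expect_gte(mean(hits[, "np_phi"] < -0.6), 0.8)
  expect_gte(mean(hits[, "np_tau2"] > 0.6), 0.8)
  expect_gte(mean(hits[, "cp_npq"] > 0.6), 0.8)
  expect_true(all(hits[, "np_phi"] < 0))
  # zero-loading control stays uncorrelated in nearly all seeds
  expect_gte(mean(hits[, "ctrl"] < 0.6), 0.95)
})

test_that("exact linear dependence at target r = 1 and r > 1 rejected", {
  cfg <- cohort_config(target_r = 1, trait_frag_cv = 0)
  coh <- generate_cohort(cfg, seed = 2, level = "metrics")
  ct <- aggregate_traits(coh$traits, coh$truth)
  z <- scale(cbind(-coh$latents$mean_phi, coh$latents$mean_tau2))
  u <- rowSums(z)
  expect_gt(abs(cor(log(ct$NP), u)), 0.999)
  expect_error(
    generate_cohort(cohort_config(target_r = 1.2), seed = 1,
                    level = "metrics"),
    "not attainable")
})

test_that("ITS2 counts embed the genus copy-number bias", {
  cfg <- cohort_config(p_dominant = 0.5, its2_reads = 200000L)
  coh <- generate_cohort(cfg, seed = 5, level = "metrics")
  # a 50:50 Cladocopium:Durusdinium cell split must show read shares near
  # the 2119:362 copy ratio before normalization
  d1 <- subset(coh$its2, sample_id == coh$truth$sample_id[
    coh$truth$dominant_type == "C15"][1])
  c_share <- sum(d1$count[d1$its2_type == "C15"]) / sum(d1$count)
  expect_equal(c_share, 2119 / (2119 + 362), tolerance = 0.02)
  # single-type colony stays pure
  one <- cohort_config(n_colonies = 1L, n_fragments = 1L, p_dominant = 1,
                       archetype_of_colony = 1L,
                       dominant_type_of_colony = "C15")
  its <- generate_cohort(one, seed = 1, level = "metrics")$its2
  expect_equal(sum(its$count > 0), 1L)
  expect_equal(its$its2_type[its$count > 0], "C15")
})

test_that("noisier fragments degrade phenotype recovery monotonically", {
  ari_at <- function(frag_cv) {
    coh <- generate_cohort(tiny_config(fragment_cv = frag_cv,
                                       metric_noise_cv = 0.02),
                           seed = 42, level = "metrics")
    wide <- cubes_to_wide(coh$cubes)
    wide <- wide[, apply(wide, 2, sd) > 0]
    zmat <- zscore_matrix(t(wide))
    assign <- cut_phenotypes(stats::hclust(
      stats::as.dist(1 - cor(t(wide))), "average"), k = 4)
    adjusted_rand(assign$assignment$phenotype,
                  coh$truth$archetype[match(assign$assignment$sample_id,
                                            coh$truth$sample_id)])
  }
  aris <- vapply(c(0.02, 0.8), ari_at, numeric(1))
  expect_gt(aris[1], aris[2])
})
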