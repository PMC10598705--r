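#' Light-response phenotype archetypes
#'
#' Each archetype parametrizes how the photophysiology of a symbiont
#' population responds to the actinic protocol. Responses are piecewise
#' first-order: within each actinic segment every quenching variable
#' relaxes exponentially toward a segment asymptote set by a saturating
#' function of irradiance, `amp * I/(I + I50)`.
#'
#' The four defaults encode the qualitative orderings observed across
#' coral-symbiont light-response phenotypes: archetype 1 (C15-like) has the
#' largest NPQ amplitude, the slowest tau2 and the lowest dark quantum
#' yield; archetype 2 (D1-like) has the smallest NPQ amplitude, the deepest
#' sustained qP depression and the largest cells; archetypes 3 and 4 are
#' intermediate in NPQ but differ in qP kinetics and tau2.
#'
#' @return A list of 4 archetype parameter lists.
#' @export
default_archetypes <- function() {
  base <- list(
    Fm_dark = 3000, sigma_dark = 550, rho = 0.5,
    npq_I50 = 250, qp_I50 = 150,
    npq_tau_on_s = 60, npq_tau_off_s = 120,
    qp_tau_on_s = 15, qp_tau_off_s = 1,
    abq_tau_on_s = 60, abq_tau_off_s = 120,
    tau_I50 = 250, tau_resp_s = 20,
    # spectral modifiers, wavelengths 420/442/458/505/525
    sigma_mult = c(1.10, 1.00, 0.95, 0.65, 0.55),
    npq_mult = c(1.15, 1.05, 0.95, 0.85, 0.80),
    # cellular trait log-scale archetype offsets
    cell_size_lof = 0, chla_lof = 0, lipid_lof = 0
  )
  a1 <- utils::modifyList(base, list(
    archetype_id = 1L, phi_dark = 0.45, rho = 0.50,
    npq_amp = 1.40, abq_amp = 0.35, qp_dep = 0.50,
    qp_tau_on_s = 6, qp_tau_off_s = 1,
    tau1_us = 400, tau1_delta = 150,
    tau2_us = 40000, tau2_delta = 25000,
    npq_mult = c(1.30, 1.15, 0.90, 0.80, 0.75),
    cell_size_lof = 0, chla_lof = 0.10, lipid_lof = 0.05
  ))
  a2 <- utils::modifyList(base, list(
    archetype_id = 2L, phi_dark = 0.60, rho = 0.55,
    npq_amp = 0.25, abq_amp = 0.08, qp_dep = 0.75,
    qp_tau_on_s = 40, qp_tau_off_s = 1,
    tau1_us = 800, tau1_delta = 300,
    tau2_us = 8000, tau2_delta = 3000,
    npq_mult = c(1.05, 1.00, 1.00, 0.95, 0.95),
    cell_size_lof = 0.30, chla_lof = -0.25, lipid_lof = 0
  ))
  a3 <- utils::modifyList(base, list(
    archetype_id = 3L, phi_dark = 0.52, rho = 0.45,
    npq_amp = 0.80, abq_amp = 0.20, qp_dep = 0.70,
    qp_tau_on_s = 8, qp_tau_off_s = 1,
    tau1_us = 700, tau1_delta = 250,
    tau2_us = 20000, tau2_delta = 10000,
    npq_mult = c(1.25, 1.10, 0.95, 0.85, 0.75),
    cell_size_lof = 0.05, chla_lof = 0, lipid_lof = 0
  ))
  a4 <- utils::modifyList(base, list(
    archetype_id = 4L, phi_dark = 0.58, rho = 0.50,
    npq_amp = 0.75, abq_amp = 0.18, qp_dep = 0.55,
    qp_tau_on_s = 30, qp_tau_off_s = 1,
    tau1_us = 550, tau1_delta = 200,
    tau2_us = 12000, tau2_delta = 6000,
    cell_size_lof = 0.10, chla_lof = 0.05, lipid_lof = -0.05
  ))
  list(a1, a2, a3, a4)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design: 20 colonies x 3 replicate fragments,
#' six dominant ITS2 symbiont types, four light-response archetypes, 1
#' percent multiplicative trace noise, and lognormal colony and fragment
#' random effects (CV 5 and 2 percent) on archetype parameters.
#'
#' @param n_colonies,n_fragments Cohort design.
#' @param colony_cv,fragment_cv Lognormal coefficients of variation of the
#'   colony- and fragment-level random effects on archetype parameters.
#' @param trace_noise_cv Multiplicative Gaussian noise per flashlet
#'   (trace-level generation).
#' @param metric_noise_cv Multiplicative noise applied to metric values when
#'   generating at `level = "metrics"`.
#' @param archetypes List of archetypes ([default_archetypes()]).
#' @param archetype_of_colony Integer vector mapping colony to archetype.
#' @param dominant_type_of_colony Character vector of dominant ITS2 types
#'   per colony.
#' @param target_r Planted trait-correlation magnitude.
#' @param trait_frag_cv Lognormal fragment-level CV on trait values.
#' @param its2_reads Sequencing depth per sample.
#' @param p_dominant Cell-level proportion of the dominant symbiont type.
#' @param protocol An [build_protocol()] object.
#' @return A config list of class `cohort_config`.
#' @export
cohort_config <- function(n_colonies = 20L, n_fragments = 3L,
                          colony_cv = 0.05, fragment_cv = 0.02,
                          trace_noise_cv = 0.01, metric_noise_cv = 0.02,
                          archetypes = default_archetypes(),
                          archetype_of_colony = rep(1:4, each = 5L),
                          dominant_type_of_colony = c(
                            "C15", "C15", "C15", "C15", "C3",
                            "D1", "D1", "D1", "D1", "C1",
                            "C3", "C3", "D1", "D1", "C1",
                            "C21", "C21", "C26", "C3", "C15"),
                          target_r = 0.75,
                          trait_frag_cv = 0.05,
                          its2_reads = 20000L,
                          p_dominant = 0.9,
                          protocol = build_protocol()) {
  stopifnot(length(archetype_of_colony) == n_colonies,
            length(dominant_type_of_colony) == n_colonies)
  if (any(!archetype_of_colony %in% seq_along(archetypes))) {
    stop("archetype_of_colony references an undefined archetype")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# first-order piecewise response to the actinic segments: within each
# segment x relaxes exponentially toward target[k], continuing from the
# segment-end state of the previous segment
piecewise_response <- function(times_s, segments, targets, tau_on, tau_off) {
  starts <- cumsum(c(0, segments$duration_s))
  out <- numeric(length(times_s))
  x0 <- 0
  for (k in seq_len(nrow(segments))) {
    t0 <- starts[k]
    t1 <- starts[k + 1L]
    tg <- targets[k]
    tau <- if (tg >= x0) tau_on else tau_off
    sel <- times_s >= t0 & (times_s < t1 | k == nrow(segments))
    out[sel] <- tg + (x0 - tg) * exp(-(times_s[sel] - t0) / tau)
    x0 <- tg + (x0 - tg) * exp(-(t1 - t0) / tau)
  }
  out
}

# true biophysical state of one fragment at every (wavelength, timepoint):
# returns a list of per-wavelength data.frames with the instantaneous
# st_params fields plus the true metric values the pipeline should recover
archetype_state <- function(pars, protocol) {
  seg <- protocol$segments
  tt <- protocol$timepoint_times_s
  I <- seg$irradiance
  sat <- function(amp, I50) amp * I / (I + I50)
  npq0 <- piecewise_response(tt, seg, sat(pars$npq_amp, pars$npq_I50),
                             pars$npq_tau_on_s, pars$npq_tau_off_s)
  abq0 <- piecewise_response(tt, seg, sat(pars$abq_amp, pars$npq_I50),
                             pars$abq_tau_on_s, pars$abq_tau_off_s)
  qpd <- piecewise_response(tt, seg, sat(pars$qp_dep, pars$qp_I50),
                            pars$qp_tau_on_s, pars$qp_tau_off_s)
  t1 <- pars$tau1_us + piecewise_response(tt, seg,
                                          sat(pars$tau1_delta, pars$tau_I50),
                                          pars$tau_resp_s, pars$tau_resp_s)
  t2 <- pars$tau2_us + piecewise_response(tt, seg,
                                          sat(pars$tau2_delta, pars$tau_I50),
                                          pars$tau_resp_s, pars$tau_resp_s)
  Fm_dark <- pars$Fm_dark
  Fo_dark <- Fm_dark * (1 - pars$phi_dark)
  fvfm <- pars$phi_dark
  out <- list()
  for (wi in seq_along(protocol$wavelengths)) {
    sig_dark <- pars$sigma_dark * pars$sigma_mult[wi]
    npq <- npq0 * pars$npq_mult[wi]
    Fmp <- Fm_dark / (1 + npq)
    Fop <- Fo_dark / (fvfm + Fo_dark / Fmp)
    qp <- 1 - qpd
    Fp <- Fmp - qp * (Fmp - Fop)
    # invert the yield curve for the steady-state closed fraction
    y <- pmin(pmax((Fp - Fop) / (Fmp - Fop), 0), 1)
    C0 <- y / (1 - pars$rho + pars$rho * y)
    sigp <- sig_dark * (1 - abq0)
    out[[as.character(protocol$wavelengths[wi])]] <- data.frame(
      timepoint_index = seq_along(tt), time_s = tt,
      F0 = Fop, Fm = Fmp, sigma_PSII = sigp, rho = pars$rho, C0 = C0,
      alpha = 0.6, tau1_us = t1, tau2_us = t2,
      PhiPSII = (Fmp - Fp) / Fmp, SigmaPSII = sigp, Rho = pars$rho,
      NPQ = npq, ABQ = abq0, qP = qp, Tau1ST = t1, Tau2ST = t2
    )
  }
  out
}

#' True metric trajectories implied by an archetype
#'
#' Evaluates an archetype's noiseless metric trajectories over a protocol;
#' useful as ground truth for end-to-end recovery checks.
#'
#' @param pars One archetype parameter list (see [default_archetypes()]).
#' @param protocol An [build_protocol()] object.
#' @return A `metric_cube` of true values.
#' @export
archetype_metric_cube <- function(pars, protocol = build_protocol()) {
  st <- archetype_state(pars, protocol)
  recs <- do.call(rbind, lapply(names(st), function(w) {
    s <- st[[w]]
    do.call(rbind, lapply(metric_names(), function(m) {
      data.frame(metric = m, wavelength_nm = as.integer(w),
                 timepoint_index = s$timepoint_index, value = s[[m]])
    }))
  }))
  assemble_metric_cube(recs, sprintf("archetype_%d", pars$archetype_id),
                       wavelengths = protocol$wavelengths,
                       n_timepoints = length(protocol$timepoint_times_s))
}

# multiplicative lognormal jitter with given CV on selected parameters
jitter_pars <- function(pars, cv) {
  if (cv <= 0) return(pars)
  sdlog <- sqrt(log(1 + cv^2))
  for (nm in c("phi_dark", "sigma_dark", "npq_amp", "abq_amp", "qp_dep",
               "tau1_us", "tau2_us", "tau1_delta", "tau2_delta", "rho",
               "Fm_dark")) {
    pars[[nm]] <- pars[[nm]] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  pars$phi_dark <- min(pars$phi_dark, 0.78)
  pars$rho <- min(pars$rho, 0.75)
  pars$qp_dep <- min(pars$qp_dep, 0.92)
  pars
}

#' Generate a complete synthetic cohort
#'
#' Produces, deterministically for a given seed: the study truth table
#' (colony/fragment map, archetypes, dominant symbiont types), per-fragment
#' single-turnover traces over the full protocol (or metric cubes directly
#' at `level = "metrics"`), a cellular trait table with planted
#' trait-photophysiology correlations, and ITS2 count tables with genus
#' copy-number bias.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param level `"traces"` generates flashlet-resolved traces via the
#'   single-turnover forward model (the full study emulation);
#'   `"metrics"` evaluates the true metric trajectories directly with
#'   multiplicative measurement noise, bypassing trace simulation (fast
#'   path that isolates post-fit pipeline stages).
#' @return A list with elements `truth` (data.frame), `traces` (nested
#'   list; `NULL` at level "metrics"), `cubes` (list of `metric_cube`, at
#'   level "metrics"), `traits` (data.frame per fragment), `its2` (count
#'   data.frame), `genus_map`, `latents` (per-colony photophysiology
#'   summaries), `protocol`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            level = c("traces", "metrics")) {
  level <- match.arg(level)
  set.seed(as.integer(seed))
  protocol <- config$protocol
  n_col <- config$n_colonies
  n_frag <- config$n_fragments

  truth <- data.frame(
    colony = rep(sprintf("C%02d", seq_len(n_col)), each = n_frag),
    fragment = rep(seq_len(n_frag), n_col),
    sample_id = paste0(rep(sprintf("C%02d", seq_len(n_col)), each = n_frag),
                       "_F", rep(seq_len(n_frag), n_col)),
    archetype = rep(config$archetype_of_colony, each = n_frag),
    dominant_type = rep(config$dominant_type_of_colony, each = n_frag),
    environment = rep(ifelse(seq_len(n_col) %% 5L == 0L, "indoor",
                             "outdoor"), each = n_frag),
    seed = as.integer(seed)
  )

  colony_pars <- lapply(seq_len(n_col), function(ci) {
    jitter_pars(config$archetypes[[config$archetype_of_colony[ci]]],
                config$colony_cv)
  })
  frag_pars <- lapply(seq_len(nrow(truth)), function(i) {
    ci <- (i - 1L) %/% n_frag + 1L
    jitter_pars(colony_pars[[ci]], config$fragment_cv)
  })

  n_tp <- length(protocol$timepoint_times_s)
  cubes <- traces <- NULL
  if (level == "metrics") {
    cubes <- lapply(seq_len(nrow(truth)), function(i) {
      cube <- archetype_metric_cube(
        utils::modifyList(frag_pars[[i]],
                          list(archetype_id = truth$archetype[i])),
        protocol)
      if (config$metric_noise_cv > 0) {
        noise <- 1 + stats::rnorm(length(cube), 0, config$metric_noise_cv)
        cube[] <- cube * noise
      }
      attr(cube, "sample_id") <- truth$sample_id[i]
      cube
    })
    names(cubes) <- truth$sample_id
  } else {
    traces <- lapply(seq_len(nrow(truth)), function(i) {
      st <- archetype_state(frag_pars[[i]], protocol)
      per_w <- lapply(seq_along(protocol$wavelengths), function(wi) {
        w <- protocol$wavelengths[wi]
        n_fl <- protocol$induction_flashlets[wi]
        isch <- induction_schedule(n_fl,
                                   dose_per_flashlet = protocol$dose_per_flashlet)
        rsch <- relaxation_schedule(protocol$relaxation_flashlets,
                                    dose_per_flashlet = protocol$dose_per_flashlet)
        s <- st[[as.character(w)]]
        ind <- array(NA_real_, c(n_tp, protocol$n_repeats, n_fl))
        rel <- array(NA_real_,
                     c(n_tp, protocol$n_repeats, protocol$relaxation_flashlets))
        for (tp in seq_len(n_tp)) {
          p <- st_params(F0 = s$F0[tp], Fm = s$Fm[tp],
                         sigma_PSII = s$sigma_PSII[tp], rho = s$rho[tp],
                         C0 = min(s$C0[tp], 1), alpha = s$alpha[tp],
                         tau1_us = s$tau1_us[tp], tau2_us = s$tau2_us[tp])
          for (r in seq_len(protocol$n_repeats)) {
            pr <- simulate_st_pair(p, w, ind_schedule = isch,
                                   rel_schedule = rsch,
                                   noise_cv = config$trace_noise_cv)
            ind[tp, r, ] <- pr$induction$fluorescence
            rel[tp, r, ] <- pr$relaxation$fluorescence
          }
        }
        list(wavelength_nm = w, induction = ind, relaxation = rel,
             ind_schedule = isch, rel_schedule = rsch)
      })
      names(per_w) <- as.character(protocol$wavelengths)
      list(sample_id = truth$sample_id[i], wavelengths = per_w)
    })
    names(traces) <- truth$sample_id
  }

  # per-colony latent photophysiology summaries (442 nm, colony-level pars)
  latents <- do.call(rbind, lapply(seq_len(n_col), function(ci) {
    st <- archetype_state(colony_pars[[ci]], protocol)[["442"]]
    data.frame(colony = sprintf("C%02d", ci),
               mean_phi = mean(st$PhiPSII),
               npq_amp = colony_pars[[ci]]$npq_amp,
               mean_tau2 = mean(st$Tau2ST),
               mean_qp = mean(st$qP),
               qp_dep = colony_pars[[ci]]$qp_dep)
  }))

  traits <- plant_trait_correlations(
    latents, config,
    archetypes = config$archetypes[config$archetype_of_colony],
    truth = truth)

  its2 <- generate_its2_counts(truth, config)

  list(truth = truth, traces = traces, cubes = cubes, traits = traits,
       its2 = its2, genus_map = default_genus_map(), latents = latents,
       protocol = protocol, config = config, seed = as.integer(seed))
}

# solve the residual-noise SD so that a unit-loading composite of
# standardized latents hits the pairwise target correlation
composite_z <- function(zmat, target_r) {
  if (abs(target_r) > 1) stop("requested |r| > 1 is not attainable")
  u <- rowSums(zmat)
  k <- ncol(zmat)
  if (k == 1L) {
    if (target_r == 1) return(u)
    z <- target_r * u + sqrt(1 - target_r^2) * stats::rnorm(length(u))
    return(z)
  }
  rbar <- suppressWarnings(mean(stats::cor(zmat)[upper.tri(diag(k))]))
  if (!is.finite(rbar)) rbar <- 0
  # var(u) = k + k(k-1) rbar; cor with one component = (1+(k-1)rbar)/sd(u)
  vu <- k + k * (k - 1) * rbar
  num <- 1 + (k - 1) * rbar
  se2 <- (num / target_r)^2 - vu
  if (se2 < 0) se2 <- 0  # target beyond what latent coupling allows
  (u + sqrt(se2) * stats::rnorm(length(u))) / sqrt(vu + se2)
}

#' Plant trait-photophysiology correlations
#'
#' Generates the cellular trait table on the log scale as linear-Gaussian
#' loadings on per-colony latent photophysiology summaries: atomic N:P
#' loads negatively on mean quantum yield and positively on mean tau2;
#' atomic C:P loads positively on NPQ amplitude and qP depression;
#' granularity loads broadly; two control traits are independent noise.
#' Elemental contents per cell are derived from planted ratios and a
#' lognormal P-per-cell baseline, so ratios are always computable from the
#' stored elements.
#'
#' @param latents Per-colony data.frame with `mean_phi`, `npq_amp`,
#'   `mean_tau2`, `qp_dep`.
#' @param config A [cohort_config()] (uses `target_r`, `trait_frag_cv`,
#'   `n_fragments`).
#' @param archetypes Optional list of per-colony archetype parameter lists
#'   supplying trait offsets.
#' @param truth Optional truth table to expand traits to fragments.
#' @return Data.frame of traits, one row per fragment (or per colony when
#'   `truth` is `NULL`).
#' @export
plant_trait_correlations <- function(latents, config, archetypes = NULL,
                                     truth = NULL) {
  n <- nrow(latents)
  z <- scale(latents[, c("mean_phi", "npq_amp", "mean_tau2", "mean_qp")])
  z[!is.finite(z)] <- 0  # degenerate latents (tiny or uniform cohorts)
  r <- config$target_r

  z_np <- composite_z(cbind(-z[, "mean_phi"], z[, "mean_tau2"]), r)
  z_cp <- composite_z(cbind(z[, "npq_amp"], z[, "mean_qp"]), r)
  z_gran <- composite_z(cbind(-z[, "mean_phi"], z[, "mean_tau2"],
                              z[, "npq_amp"]), r)

  lof <- function(field) {
    if (is.null(archetypes)) rep(0, n) else
      vapply(archetypes, function(a) a[[field]], numeric(1))
  }
  np <- exp(log(20) + 0.30 * z_np)
  cp <- exp(log(110) + 0.25 * z_cp)
  gran <- exp(0.20 * z_gran)
  cell_size <- exp(lof("cell_size_lof") + stats::rnorm(n, 0, 0.08))
  chla <- exp(lof("chla_lof") + stats::rnorm(n, 0, 0.10))
  lipids <- exp(lof("lipid_lof") + stats::rnorm(n, 0, 0.15))
  p_pg <- stats::rlnorm(n, log(1.5), 0.15)
  colony_traits <- data.frame(
    colony = latents$colony,
    cell_size = cell_size, granularity = gran, chla = chla,
    P_per_cell = p_pg,
    N_per_cell = np * p_pg * 14 / 31,
    C_per_cell = cp * p_pg * 12 / 31,
    neutral_lipids = lipids,
    control_a = stats::rlnorm(n, 0, 0.2),
    control_b = stats::rlnorm(n, 0, 0.2)
  )
  out <- if (is.null(truth)) {
    colony_traits
  } else {
    idx <- match(truth$colony, colony_traits$colony)
    ft <- colony_traits[idx, ]
    ft$sample_id <- truth$sample_id
    sdlog <- sqrt(log(1 + config$trait_frag_cv^2))
    for (col in setdiff(names(ft), c("colony", "sample_id"))) {
      ft[[col]] <- ft[[col]] * stats::rlnorm(nrow(ft), -sdlog^2 / 2, sdlog)
    }
    rownames(ft) <- NULL
    ft
  }
  out$CN <- (out$C_per_cell / 12) / (out$N_per_cell / 14)
  out$CP <- (out$C_per_cell / 12) / (out$P_per_cell / 31)
  out$NP <- (out$N_per_cell / 14) / (out$P_per_cell / 31)
  out
}

#' Default ITS2 type to genus map
#'
#' @return Data.frame mapping the six study types to their genera.
#' @export
default_genus_map <- function() {
  data.frame(
    its2_type = c("C1", "C3", "C15", "C21", "C26", "D1"),
    genus = c(rep("Cladocopium", 5), "Durusdinium")
  )
}

#' Generate ITS2 count tables with rDNA copy-number bias
#'
#' Per sample, cell-level type proportions (dominant + secondary type) are
#' multiplied by genus rDNA copies per cell (Cladocopium 2119, Durusdinium
#' 362) and read counts drawn multinomially from the resulting read-pool
#' shares, so copy-number normalization is required to recover the true
#' cell proportions.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param config A [cohort_config()].
#' @param copies Copy-number table as in [copy_number_table()].
#' @return Data.frame: sample_id, its2_type, count, plus true cell
#'   proportions in `true_proportion`.
#' @export
generate_its2_counts <- function(truth, config,
                                 copies = copy_number_table()) {
  gm <- default_genus_map()
  types <- gm$its2_type
  # secondary type: cross-genus partner to exercise the copy-number bias
  secondary_of <- c(C1 = "D1", C3 = "D1", C15 = "D1", C21 = "D1",
                    C26 = "D1", D1 = "C1")
  out <- lapply(seq_len(nrow(truth)), function(i) {
    dom <- truth$dominant_type[i]
    sec <- secondary_of[[dom]]
    prop <- stats::setNames(numeric(length(types)), types)
    prop[dom] <- config$p_dominant
    prop[sec] <- 1 - config$p_dominant
    if (abs(sum(prop) - 1) > 1e-9) stop("cell proportions must sum to 1")
    cpg <- copies$copies[match(gm$genus[match(types, gm$its2_type)],
                               copies$genus)]
    share <- prop * cpg
    share <- share / sum(share)
    counts <- stats::rmultinom(1, config$its2_reads, share)[, 1]
    data.frame(sample_id = truth$sample_id[i], its2_type = types,
               count = counts, true_proportion = unname(prop))
  })
  do.call(rbind, out)
}
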