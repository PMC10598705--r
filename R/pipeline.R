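#' Fit every trace of a cohort into per-sample metric cubes
#'
#' For each sample and wavelength the repeats at each timepoint are
#' averaged flashlet-wise and fitted once ([acquire_timepoint()]); the
#' first timepoint (dark-acclimated, initial closure pinned to 0) provides
#' the reference Fm, Fo and sigma for the quenching metrics at that
#' wavelength, and every timepoint acquired in darkness is also fitted with
#' the closure pinned. Metrics are assembled into one `metric_cube` per
#' sample.
#'
#' @param traces Nested trace structure ([generate_cohort()] or
#'   [read_traces()]).
#' @param protocol The acquisition protocol.
#' @param progress Print per-sample progress.
#' @return List with `cubes` (list of `metric_cube`) and `fits`
#'   (data.frame of all fitted parameters and diagnostics, one row per
#'   sample x wavelength x timepoint).
#' @export
fit_cohort <- function(traces, protocol = build_protocol(),
                       progress = FALSE) {
  dark_tp <- irradiance_at(protocol, protocol$timepoint_times_s) == 0
  cubes <- vector("list", length(traces))
  fit_rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    smp <- traces[[i]]
    recs <- NULL
    rows <- NULL
    for (wv in smp$wavelengths) {
      n_tp <- dim(wv$induction)[1]
      ind_mean <- apply(wv$induction, c(1, 3), mean)
      rel_mean <- apply(wv$relaxation, c(1, 3), mean)
      fit_dark <- NULL
      for (tp in seq_len(n_tp)) {
        pair <- list(
          induction = st_trace(wv$wavelength_nm, wv$ind_schedule,
                               ind_mean[tp, ]),
          relaxation = st_trace(wv$wavelength_nm, wv$rel_schedule,
                                rel_mean[tp, ]))
        # light acquisitions: pin F0' to the Oxborough-Baker estimate
        # (dark Fo, Fv/Fm and a provisional Fm' from the trace plateau)
        # to break the F0-C0 degeneracy of the induction fit
        F0_fix <- NULL
        if (!dark_tp[tp] && !is.null(fit_dark) && isTRUE(fit_dark$converged)) {
          Fo_d <- fit_dark$params$F0
          fvfm <- fit_dark$phi_PSII
          Fmp_prov <- 1.02 * max(ind_mean[tp, ])
          F0_fix <- Fo_d / (fvfm + Fo_d / Fmp_prov)
        }
        fit <- st_fit(pair, dark = dark_tp[tp], F0_fixed = F0_fix)
        if (tp == 1L) fit_dark <- fit
        m <- derive_metrics(fit_dark, fit)
        m$wavelength_nm <- wv$wavelength_nm
        m$timepoint_index <- tp
        recs <- rbind(recs, m)
        rows <- rbind(rows, data.frame(
          sample_id = smp$sample_id, wavelength_nm = wv$wavelength_nm,
          timepoint_index = tp, as.data.frame(fit$params),
          phi_PSII = fit$phi_PSII, residual_rms = fit$residual_rms,
          converged = fit$converged))
      }
    }
    cubes[[i]] <- assemble_metric_cube(
      recs, smp$sample_id,
      wavelengths = protocol$wavelengths,
      n_timepoints = length(protocol$timepoint_times_s))
    fit_rows[[i]] <- rows
    if (progress) message("fitted ", smp$sample_id, " (", i, "/",
                          length(traces), ")")
  }
  names(cubes) <- vapply(traces, `[[`, "", "sample_id")
  list(cubes = cubes, fits = do.call(rbind, fit_rows))
}

#' Run the full phenotyping pipeline on a synthetic cohort
#'
#' Executes the stages in order -- simulate, fit (at trace level), metric
#' cube assembly, symbiont typing, metric screening and Z-scoring,
#' bootstrap clustering and the k-phenotype cut, cellular trait
#' comparisons, and the trait correlation network -- writing every stage
#' output plus a manifest of file hashes and the resolved configuration to
#' `outdir`. Rerunning with the same config and seed reproduces the
#' manifest.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Seed threaded through cohort generation and clustering.
#' @param config A [cohort_config()].
#' @param level `"metrics"` (fast; metric cubes generated directly) or
#'   `"traces"` (full trace simulation and nonlinear fitting).
#' @param k Number of phenotypes to cut.
#' @param n_boot Bootstrap iterations for the clustering support.
#' @param network_threshold Pearson threshold for the trait network.
#' @param progress Verbose per-stage logging.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(outdir, seed = 1L, config = cohort_config(),
                         level = c("metrics", "traces"), k = 4L,
                         n_boot = 1000L, network_threshold = 0.6,
                         progress = FALSE) {
  level <- match.arg(level)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (progress) message(format(Sys.time(), "%H:%M:%S "),
                                             ...)
  say("simulate: cohort at level '", level, "'")
  coh <- generate_cohort(config, seed = seed, level = level)
  if (level == "traces") {
    say("fit: ", length(coh$traces), " samples")
    fc <- fit_cohort(coh$traces, coh$protocol, progress = progress)
    cubes <- fc$cubes
    write_table_v(fc$fits, file.path(outdir, "fits.tsv"), "fits")
  } else {
    cubes <- coh$cubes
  }
  write_cubes(cubes, file.path(outdir, "metrics_tidy.tsv"),
              file.path(outdir, "metrics_wide.tsv"), coh$protocol)
  write_table_v(coh$truth, file.path(outdir, "truth.tsv"), "truth")
  write_table_v(coh$traits, file.path(outdir, "traits.tsv"), "traits")
  write_table_v(coh$its2, file.path(outdir, "its2.tsv"), "its2")

  say("typing: dominant symbiont types")
  dom <- call_dominant_types(coh$its2)
  write_table_v(dom, file.path(outdir, "dominant_types.tsv"),
                "dominant_types")

  say("screen: ", ncol(cubes_to_wide(cubes)), " metrics")
  wide <- cubes_to_wide(cubes)
  groups <- dom$dominant_type[match(rownames(wide), dom$sample_id)]
  scr <- screen_metrics(wide, groups)
  write_table_v(scr, file.path(outdir, "screen.tsv"), "screen")
  kept <- scr$metric[scr$kept]
  zmat <- zscore_matrix(t(wide[, kept, drop = FALSE]))

  say("cluster: ", n_boot, " bootstrap iterations")
  dend <- bootstrap_cluster(zmat, n_boot = n_boot, seed = seed)
  assign <- cut_phenotypes(dend, k = k)
  write_table_v(assign$assignment, file.path(outdir, "phenotypes.tsv"),
                "phenotypes")
  write_dendrogram_newick(dend, file.path(outdir, "dendrogram.nwk"))
  drivers <- rank_driver_metrics(zmat, assign)
  write_table_v(drivers$families, file.path(outdir, "driver_families.tsv"),
                "driver_families")

  say("stats: cellular traits across phenotypes")
  tc <- compare_cellular_traits(coh$traits, assign,
                                trait_cols = c("cell_size", "granularity",
                                               "chla", "NP", "CP", "CN"))
  write_table_v(tc$pairwise, file.path(outdir, "trait_pairwise.tsv"),
                "trait_pairwise")

  net <- NULL
  if (length(unique(coh$truth$colony)) >= 5L) {
    say("network: colony-level correlations")
    avg <- average_replicates(cubes, coh$truth)
    net <- correlate_traits(avg$means,
                            aggregate_traits(coh$traits, coh$truth),
                            threshold = network_threshold)
    if (!is.null(net$edges) && nrow(net$edges) > 0) {
      export_graph(net, file.path(outdir, "network.graphml"), "graphml")
      export_graph(net, file.path(outdir, "network_edges.tsv"), "edgelist")
    }
  } else {
    say("network: skipped (needs at least 5 colonies)")
  }

  cfg <- config
  cfg$protocol <- NULL
  cfg$archetypes <- NULL
  jsonlite::write_json(
    list(seed = seed, level = level, k = k, n_boot = n_boot,
         network_threshold = network_threshold,
         config = cfg[!vapply(cfg, is.function, logical(1))]),
    file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(outdir, full.names = TRUE),
                   file.path(outdir, "manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", nrow(manifest), " files in ", outdir)
  invisible(list(cohort = coh, cubes = cubes, dominant = dom, screen = scr,
                 dendrogram = dend, assignment = assign, drivers = drivers,
                 traits_compared = tc, network = net,
                 manifest = manifest))
}

#' Average fragment trait rows to colony level
#'
#' @param traits Fragment-level trait table.
#' @param colony_map Data.frame with `sample_id`, `colony`.
#' @return Colony-level data.frame with a `colony` column.
#' @export
aggregate_traits <- function(traits, colony_map) {
  colony <- colony_map$colony[match(traits$sample_id,
                                    colony_map$sample_id)]
  num <- names(traits)[vapply(traits, is.numeric, logical(1))]
  agg <- stats::aggregate(traits[num], list(colony = colony), mean,
                          na.rm = TRUE)
  agg
}
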