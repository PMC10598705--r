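#' Build the variable actinic light protocol
#'
#' The default protocol is an 11-minute (660 s) sequence: 30 s dark, 300
#' umol photons m^-2 s^-1 for 3.5 min, 50 for 1.5 min, 600 for 3.5 min, and
#' a final 2 min dark recovery, with 34 acquisition timepoints evenly spaced
#' over the full span (one every 660/34 ~ 19.4 s) and five sequential
#' repeats of the five-wavelength single-turnover acquisition per timepoint.
#'
#' @param segments Two-column matrix/data.frame: irradiance
#'   (umol photons m^-2 s^-1) and duration (s) per segment, in order.
#' @param n_timepoints Number of acquisition timepoints.
#' @param timepoint_times_s Optional explicit acquisition times (s); default
#'   evenly spaced from 0 over the protocol span.
#' @param n_repeats Sequential acquisitions per timepoint.
#' @param wavelengths Excitation wavelengths (canonicalized).
#' @param dose_per_flashlet,relaxation_flashlets Flashlet excitation dose
#'   and relaxation train length shared across wavelengths.
#' @return An object of class `actinic_protocol`.
#' @export
#' @examples
#' p <- build_protocol()
#' length(p$timepoint_times_s)  # 34
build_protocol <- function(segments = default_segments(),
                           n_timepoints = 34L,
                           timepoint_times_s = NULL,
                           n_repeats = 5L,
                           wavelengths = c(420, 442, 458, 505, 525),
                           dose_per_flashlet = 2.5e-4,
                           relaxation_flashlets = 40L) {
  segments <- as.data.frame(segments)
  names(segments) <- c("irradiance", "duration_s")
  if (any(segments$duration_s <= 0) || any(segments$irradiance < 0)) {
    stop("segments need positive durations and non-negative irradiances")
  }
  span <- sum(segments$duration_s)
  if (is.null(timepoint_times_s)) {
    timepoint_times_s <- (seq_len(n_timepoints) - 1L) * span / n_timepoints
  }
  if (any(diff(timepoint_times_s) <= 0)) {
    stop("timepoint times must be strictly increasing")
  }
  if (any(timepoint_times_s < 0 | timepoint_times_s > span)) {
    stop("timepoint times fall outside the protocol span [0, ", span, "] s")
  }
  wavelengths <- canonical_wavelength(wavelengths)
  structure(
    list(segments = segments,
         span_s = span,
         timepoint_times_s = timepoint_times_s,
         n_repeats = as.integer(n_repeats),
         wavelengths = wavelengths,
         induction_flashlets = induction_flashlets_for(wavelengths),
         relaxation_flashlets = as.integer(relaxation_flashlets),
         dose_per_flashlet = dose_per_flashlet),
    class = "actinic_protocol"
  )
}

#' Default actinic segments
#'
#' @return A data.frame of (irradiance, duration_s) totalling 660 s.
#' @export
default_segments <- function() {
  data.frame(irradiance = c(0, 300, 50, 600, 0),
             duration_s = c(30, 210, 90, 210, 120))
}

#' @export
print.actinic_protocol <- function(x, ...) {
  cat("Variable actinic light protocol:", x$span_s, "s,",
      length(x$timepoint_times_s), "timepoints,", x$n_repeats,
      "repeats/timepoint\n")
  cat("  segments (irradiance umol m^-2 s^-1 x duration s): ",
      paste(sprintf("%gx%g", x$segments$irradiance, x$segments$duration_s),
            collapse = ", "), "\n")
  cat("  wavelengths:", paste(x$wavelengths, collapse = ", "), "nm;",
      "induction flashlets:", paste(x$induction_flashlets, collapse = "/"),
      "\n")
  invisible(x)
}

#' Actinic irradiance at a protocol time
#'
#' @param protocol An [build_protocol()] object.
#' @param time_s Time(s) in seconds from protocol start.
#' @return Irradiance in umol photons m^-2 s^-1 (vectorized).
#' @export
irradiance_at <- function(protocol, time_s) {
  ends <- cumsum(protocol$segments$duration_s)
  idx <- findInterval(time_s, c(0, ends[-length(ends)]), rightmost.closed = FALSE)
  idx[time_s >= ends[length(ends)]] <- nrow(protocol$segments)
  protocol$segments$irradiance[pmax(idx, 1L)]
}

#' Average repeated acquisitions and fit once
#'
#' The five sequential acquisitions at one timepoint/wavelength are averaged
#' flashlet-wise into one mean trace pair, which is then fitted once; this
#' accumulates signal before the nonlinear fit rather than averaging fitted
#' parameters. Per-repeat fitting is available with `per_repeat = TRUE` for
#' diagnostics.
#'
#' @param pairs A list of trace pairs (each a list with `induction` and
#'   `relaxation` [st_trace()] objects) sharing wavelength and schedules.
#' @param n_repeats_expected Configured repeat count; a differing supplied
#'   count triggers a warning but proceeds.
#' @param per_repeat If `TRUE`, return a list of per-repeat [st_fit()]s
#'   instead of one pooled fit.
#' @param ... Passed to [st_fit()].
#' @return An [st_fit()] (or a list of them when `per_repeat = TRUE`).
#' @export
acquire_timepoint <- function(pairs, n_repeats_expected = 5L,
                              per_repeat = FALSE, ...) {
  if (length(pairs) == 0L) stop("no repeats supplied")
  if (length(pairs) != n_repeats_expected) {
    warning("expected ", n_repeats_expected, " repeats, got ", length(pairs),
            "; proceeding with available repeats")
  }
  w <- vapply(pairs, function(p) p$induction$wavelength_nm, numeric(1))
  if (length(unique(w)) != 1L) stop("repeats mix wavelengths")
  if (per_repeat) return(lapply(pairs, st_fit, ...))
  ind_mat <- do.call(rbind, lapply(pairs, function(p) p$induction$fluorescence))
  rel_mat <- do.call(rbind, lapply(pairs, function(p) p$relaxation$fluorescence))
  mean_pair <- list(
    induction = st_trace(w[1], pairs[[1]]$induction$schedule, colMeans(ind_mat)),
    relaxation = st_trace(w[1], pairs[[1]]$relaxation$schedule, colMeans(rel_mat))
  )
  st_fit(mean_pair, ...)
}

# canonical metric ordering of the cube
METRICS <- c("PhiPSII", "SigmaPSII", "Rho", "NPQ", "ABQ", "qP",
             "Tau1ST", "Tau2ST")

#' Metric names of the photophysiology cube
#' @return Character vector of the 8 metric names in canonical order.
#' @export
metric_names <- function() METRICS

# steady-state fluorescence F' implied by a fit: the fitted induction
# baseline, i.e. the yield at the fitted initial closure C0
fprime_of <- function(fit) {
  p <- fit$params
  yield_from_closure(p$C0, p$F0, p$Fm, p$rho)
}

#' Derive the time-resolved photophysiology metrics at one timepoint
#'
#' Combines the dark-acclimated reference fit (timepoint 1) with the fit at
#' a later timepoint to compute, at one wavelength:
#' \itemize{
#'   \item `PhiPSII` = (Fm' - F')/Fm', with F' the fitted induction baseline
#'     (steady-state fluorescence under actinic light);
#'   \item `NPQ` = (Fm_dark - Fm')/Fm' (Stern-Volmer);
#'   \item `qP` = (Fm' - F')/(Fm' - Fo') with Fo' from the Oxborough-Baker
#'     estimate Fo' = Fo / (Fv/Fm + Fo/Fm');
#'   \item `ABQ` = (sigma_dark - sigma')/sigma_dark, the fractional loss of
#'     functional cross-section attributed to antenna-bed quenching;
#'   \item `SigmaPSII`, `Rho`, `Tau1ST`, `Tau2ST` passed through from the
#'     timepoint fit.
#' }
#' Non-converged fits yield `NA` metric values rather than fabricated ones.
#'
#' @param fit_dark Reference [st_fit()] from the dark-acclimated first
#'   timepoint (same wavelength).
#' @param fit_t [st_fit()] at the timepoint of interest.
#' @return A data.frame with columns `metric` and `value` (8 rows).
#' @export
derive_metrics <- function(fit_dark, fit_t) {
  na_out <- data.frame(metric = METRICS, value = NA_real_)
  if (!isTRUE(fit_dark$converged) || !isTRUE(fit_t$converged)) return(na_out)
  pd <- fit_dark$params
  pt <- fit_t$params
  Fm_dark <- pd$Fm
  Fo_dark <- pd$F0
  fvfm <- (Fm_dark - Fo_dark) / Fm_dark
  Fmp <- pt$Fm
  Fp <- fprime_of(fit_t)
  Fop <- Fo_dark / (fvfm + Fo_dark / Fmp)
  phi <- (Fmp - Fp) / Fmp
  npq <- (Fm_dark - Fmp) / Fmp
  qp <- (Fmp - Fp) / (Fmp - Fop)
  abq <- (pd$sigma_PSII - pt$sigma_PSII) / pd$sigma_PSII
  data.frame(
    metric = METRICS,
    value = c(phi, pt$sigma_PSII, pt$rho, npq, abq, qp, pt$tau1_us,
              pt$tau2_us)
  )
}

#' Assemble per-timepoint metric records into a sample metric cube
#'
#' @param records Data.frame with columns `metric`, `wavelength_nm`,
#'   `timepoint_index`, `value`. Missing combinations are allowed (stored as
#'   `NA`); duplicates are an error.
#' @param sample_id Sample identifier.
#' @param wavelengths,n_timepoints Cube dimensions.
#' @return An object of class `metric_cube`: a 3-d array
#'   \[metric x wavelength x timepoint\] with a `sample_id` attribute.
#' @export
assemble_metric_cube <- function(records, sample_id,
                                 wavelengths = c(420, 442, 458, 505, 525),
                                 n_timepoints = 34L) {
  wavelengths <- canonical_wavelength(wavelengths)
  stopifnot(all(c("metric", "wavelength_nm", "timepoint_index", "value")
                %in% names(records)))
  if (!all(records$metric %in% METRICS)) {
    stop("unknown metric name(s): ",
         paste(setdiff(unique(records$metric), METRICS), collapse = ", "))
  }
  key <- paste(records$metric, records$wavelength_nm,
               records$timepoint_index)
  if (anyDuplicated(key)) {
    stop("duplicate (metric, wavelength, timepoint) records")
  }
  arr <- array(NA_real_,
               dim = c(length(METRICS), length(wavelengths), n_timepoints),
               dimnames = list(metric = METRICS,
                               wavelength = as.character(wavelengths),
                               timepoint = as.character(seq_len(n_timepoints))))
  mi <- match(records$metric, METRICS)
  wi <- match(canonical_wavelength(records$wavelength_nm), wavelengths)
  ti <- as.integer(records$timepoint_index)
  if (any(is.na(wi))) stop("records contain wavelengths outside the cube")
  if (any(ti < 1L | ti > n_timepoints)) stop("timepoint index out of range")
  arr[cbind(mi, wi, ti)] <- records$value
  structure(arr, sample_id = sample_id, class = c("metric_cube", "array"))
}

#' @export
print.metric_cube <- function(x, ...) {
  d <- dim(x)
  cat("Metric cube for sample", attr(x, "sample_id"), ":",
      d[1], "metrics x", d[2], "wavelengths x", d[3], "timepoints =",
      prod(d), "values (", sum(is.na(x)), "missing )\n")
  invisible(x)
}

#' Flatten a metric cube to its canonical 1,360-value vector
#'
#' Ordering is metric-major, then wavelength ascending, then timepoint;
#' names are `metric_wavelength_timepoint`.
#'
#' @param cube A [assemble_metric_cube()] object.
#' @return Named numeric vector of length `prod(dim(cube))`.
#' @export
flatten_cube <- function(cube) {
  stopifnot(inherits(cube, "metric_cube"))
  d <- dimnames(cube)
  # timepoint varies fastest, then wavelength, then metric
  out <- as.vector(aperm(unclass(cube), c(3, 2, 1)))
  grid <- expand.grid(t = d$timepoint, w = d$wavelength, m = d$metric,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(out) <- paste(grid$m, grid$w, grid$t, sep = "_")
  out
}

#' Rebuild a metric cube from its flattened vector
#'
#' Inverse of [flatten_cube()].
#'
#' @param x Named vector as produced by [flatten_cube()].
#' @param sample_id Sample identifier for the rebuilt cube.
#' @return A `metric_cube`.
#' @export
unflatten_cube <- function(x, sample_id = NA_character_) {
  parts <- strsplit(names(x), "_", fixed = TRUE)
  rec <- data.frame(
    metric = vapply(parts, `[`, "", 1L),
    wavelength_nm = as.integer(vapply(parts, `[`, "", 2L)),
    timepoint_index = as.integer(vapply(parts, `[`, "", 3L)),
    value = unname(x)
  )
  assemble_metric_cube(rec, sample_id,
                       wavelengths = sort(unique(rec$wavelength_nm)),
                       n_timepoints = max(rec$timepoint_index))
}

#' Tidy long-form view of a metric cube
#'
#' @param cube A `metric_cube`.
#' @param protocol Optional protocol used to attach acquisition times.
#' @return Data.frame: sample_id, metric, wavelength_nm, timepoint_index,
#'   time_s, value.
#' @export
cube_to_tidy <- function(cube, protocol = NULL) {
  d <- dimnames(cube)
  out <- expand.grid(timepoint_index = as.integer(d$timepoint),
                     wavelength_nm = as.integer(d$wavelength),
                     metric = d$metric,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- as.vector(aperm(unclass(cube), c(3, 2, 1)))
  out$time_s <- if (is.null(protocol)) NA_real_ else
    protocol$timepoint_times_s[out$timepoint_index]
  out$sample_id <- attr(cube, "sample_id")
  out[, c("sample_id", "metric", "wavelength_nm", "timepoint_index",
          "time_s", "value")]
}

#' Wide matrix of flattened metric cubes
#'
#' @param cubes A list of `metric_cube` objects.
#' @return Matrix samples x metrics with deterministic
#'   `metric_wavelength_timepoint` column names.
#' @export
cubes_to_wide <- function(cubes) {
  rows <- lapply(cubes, flatten_cube)
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(cubes, function(x) attr(x, "sample_id"), "")
  mat
}
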