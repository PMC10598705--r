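#' Flashlet schedules for single-turnover fluorescence acquisition
#'
#' A flashlet schedule describes the excitation timing of one acquisition
#' phase: a rapid train of microsecond flashlets that progressively closes
#' PSII reaction centers (induction), or a sparse train with exponentially
#' growing dark gaps that probes reopening (relaxation).
#'
#' @param phase `"induction"` or `"relaxation"`.
#' @param times_us Strictly increasing flashlet onset times, in microseconds
#'   from the start of the phase.
#' @param dose_per_flashlet Excitation dose per flashlet, in quanta per
#'   square Angstrom, so that `sigma_PSII * dose` is the dimensionless
#'   closure probability increment per flashlet for an open center.
#' @param flashlet_duration_us Flashlet duration in microseconds.
#' @return An object of class `flashlet_schedule`.
#' @export
flashlet_schedule <- function(phase = c("induction", "relaxation"),
                              times_us,
                              dose_per_flashlet = 2.5e-4,
                              flashlet_duration_us = 1.3) {
  phase <- match.arg(phase)
  times_us <- as.numeric(times_us)
  if (length(times_us) < 1L || any(!is.finite(times_us))) {
    stop("times_us must be a non-empty finite numeric vector")
  }
  if (any(diff(times_us) <= 0)) {
    stop("flashlet times must be strictly increasing")
  }
  if (phase == "relaxation") {
    gaps <- diff(times_us)
    if (length(gaps) > 1L && any(diff(gaps) <= 0)) {
      stop("relaxation gaps must be strictly increasing")
    }
    if (max(times_us) > 3e5) {
      stop("relaxation span exceeds 300 ms")
    }
  }
  if (dose_per_flashlet < 0) stop("dose_per_flashlet must be non-negative")
  structure(
    list(
      phase = phase,
      times_us = times_us,
      dose_per_flashlet = dose_per_flashlet,
      flashlet_duration_us = flashlet_duration_us
    ),
    class = "flashlet_schedule"
  )
}

#' Default induction schedule
#'
#' 1.3-microsecond flashlets separated by 3.4-microsecond dark intervals
#' (4.7 us pitch). Blue excitation wavelengths use 32 flashlets; green
#' wavelengths, where the functional cross-section is smaller, use 40.
#'
#' @param n_flashlets Number of flashlets (32 or 40 in the default protocol).
#' @inheritParams flashlet_schedule
#' @param gap_us Dark interval between flashlets (microseconds).
#' @export
induction_schedule <- function(n_flashlets = 32L,
                               flashlet_duration_us = 1.3,
                               gap_us = 3.4,
                               dose_per_flashlet = 2.5e-4) {
  pitch <- flashlet_duration_us + gap_us
  flashlet_schedule(
    phase = "induction",
    times_us = (seq_len(n_flashlets) - 1L) * pitch,
    dose_per_flashlet = dose_per_flashlet,
    flashlet_duration_us = flashlet_duration_us
  )
}

#' Default relaxation schedule
#'
#' Probe flashlets separated by geometrically increasing dark periods
#' (first gap 59 us), spanning 300 ms in total. The common ratio is solved
#' so the final flashlet lands at the requested span.
#'
#' @param n_flashlets Number of probe flashlets.
#' @param first_gap_us First dark gap (microseconds).
#' @param span_us Total phase span (microseconds, at most 3e5).
#' @inheritParams flashlet_schedule
#' @export
relaxation_schedule <- function(n_flashlets = 40L,
                                first_gap_us = 59,
                                span_us = 3e5,
                                flashlet_duration_us = 1.3,
                                dose_per_flashlet = 2.5e-4) {
  stopifnot(n_flashlets >= 2L, first_gap_us > 0, span_us <= 3e5)
  # solve first_gap * (q^n - 1)/(q - 1) = span for the geometric ratio q
  f <- function(q) first_gap_us * (q^n_flashlets - 1) / (q - 1) - span_us
  q <- stats::uniroot(f, c(1 + 1e-9, 3), tol = 1e-12)$root
  gaps <- first_gap_us * q^(seq_len(n_flashlets) - 1L)
  flashlet_schedule(
    phase = "relaxation",
    times_us = cumsum(gaps),
    dose_per_flashlet = dose_per_flashlet,
    flashlet_duration_us = flashlet_duration_us
  )
}

#' Canonical excitation wavelengths
#'
#' The instrument excites at 420, 442, 458, 505 and 525 nm; 520 is accepted
#' as an alias for 525.
#'
#' @param wavelength_nm Integer wavelength to canonicalize.
#' @return The canonical wavelength.
#' @export
canonical_wavelength <- function(wavelength_nm) {
  w <- as.integer(wavelength_nm)
  w[w == 520L] <- 525L
  bad <- !(w %in% c(420L, 442L, 458L, 505L, 525L))
  if (any(bad)) {
    stop("unknown excitation wavelength: ", paste(unique(w[bad]), collapse = ", "))
  }
  w
}

#' Induction flashlet count for a wavelength
#'
#' @inheritParams canonical_wavelength
#' @return 32 for 420/442/458 nm, 40 for 505/525 nm.
#' @export
induction_flashlets_for <- function(wavelength_nm) {
  w <- canonical_wavelength(wavelength_nm)
  ifelse(w %in% c(420L, 442L, 458L), 32L, 40L)
}
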