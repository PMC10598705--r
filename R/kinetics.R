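#' Fluorescence yield from the closed fraction of PSII centers
#'
#' Maps the fraction of closed PSII reaction centers to fluorescence yield
#' under the connected-units model: excitons reaching a closed center can
#' migrate to a neighbouring open one with probability `rho`, which makes
#' the yield a saturating (for rho > 0) function of closure,
#' \deqn{F = F_0 + (F_m - F_0)\,\frac{C (1-\rho)}{1 - \rho C}.}
#'
#' @param C Closed fraction of PSII centers, in \[0, 1\] (vectorized).
#' @param F0 Minimal fluorescence (all centers open), instrument units.
#' @param Fm Maximal fluorescence (all centers closed), instrument units.
#' @param rho Excitonic connectivity, in \[0, 1).
#' @return Fluorescence in instrument units, bounded by \[F0, Fm\].
#' @export
#' @examples
#' yield_from_closure(0.5, F0 = 1000, Fm = 3000, rho = 0.4)
yield_from_closure <- function(C, F0, Fm, rho) {
  if (any(C < 0 | C > 1)) stop("closed fraction C must lie in [0, 1]")
  if (rho < 0 || rho >= 1) stop("connectivity rho must lie in [0, 1)")
  if (!(Fm > F0) || F0 <= 0) stop("requires Fm > F0 > 0")
  F0 + (Fm - F0) * C * (1 - rho) / (1 - rho * C)
}

#' Biophysical parameters of a single-turnover transient
#'
#' @param F0 Minimal fluorescence (instrument units).
#' @param Fm Maximal fluorescence (instrument units); must exceed `F0`.
#' @param sigma_PSII Functional absorption cross-section of PSII
#'   (Angstrom^2 quanta^-1).
#' @param rho Excitonic connectivity, \[0, 1).
#' @param C0 Initial closed fraction at the start of induction, \[0, 1\].
#' @param alpha Amplitude of the fast relaxation component, \[0, 1\].
#' @param tau1_us Fast reoxidation time constant (microseconds); the
#'   Qa-to-Qb electron transfer.
#' @param tau2_us Slow reoxidation time constant (microseconds);
#'   plastoquinone-pool and downstream reoxidation. Must exceed `tau1_us`.
#' @return A named list of class `st_params`.
#' @export
st_params <- function(F0 = 1000, Fm = 3000, sigma_PSII = 550, rho = 0.3,
                      C0 = 0, alpha = 0.6, tau1_us = 600, tau2_us = 12000) {
  stopifnot(F0 > 0, Fm > F0, sigma_PSII > 0,
            rho >= 0, rho < 1, C0 >= 0, C0 <= 1,
            alpha >= 0, alpha <= 1, tau1_us > 0, tau2_us > tau1_us)
  structure(list(F0 = F0, Fm = Fm, sigma_PSII = sigma_PSII, rho = rho,
                 C0 = C0, alpha = alpha, tau1_us = tau1_us,
                 tau2_us = tau2_us),
            class = "st_params")
}

#' Single-turnover fluorescence trace
#'
#' One flashlet-resolved fluorescence record at one wavelength.
#'
#' @param wavelength_nm Excitation wavelength (canonicalized; 520 -> 525).
#' @param schedule A [flashlet_schedule()].
#' @param fluorescence Numeric vector, one value per flashlet, finite and
#'   positive.
#' @return An object of class `st_trace`.
#' @export
st_trace <- function(wavelength_nm, schedule, fluorescence) {
  stopifnot(inherits(schedule, "flashlet_schedule"))
  wavelength_nm <- canonical_wavelength(wavelength_nm)
  if (length(fluorescence) != length(schedule$times_us)) {
    stop("fluorescence length must equal the flashlet count (",
         length(schedule$times_us), ")")
  }
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0)) {
    stop("fluorescence values must be finite and positive")
  }
  structure(list(wavelength_nm = wavelength_nm, schedule = schedule,
                 fluorescence = as.numeric(fluorescence)),
            class = "st_trace")
}

# Closure recursion over an induction flashlet train: returns the closed
# fraction AFTER each flashlet. Within a flashlet the closure follows the
# dose ODE dC/dD = sigma (1-C)/(1 - rho C), whose integral is
#   g(C) = -(1-rho) log(1-C) + rho C = g(C_prev) + sigma * dose,
# so without reopening the whole train is g^{-1}(g(C0) + j sigma dose),
# inverted by vectorized Newton. With inter-flashlet reopening enabled the
# train is stepped sequentially, removing gap/tau1 of the closed pool in
# each dark gap.
closure_recursion <- function(params, schedule, reopening = FALSE) {
  n <- length(schedule$times_us)
  s <- schedule$dose_per_flashlet * params$sigma_PSII
  rho <- params$rho
  C0 <- min(max(params$C0, 0), 1 - 1e-12)
  g <- function(C) -(1 - rho) * log1p(-C) + rho * C
  # invert g in u = -log(1-C) space, where f(u) = (1-rho) u + rho(1-e^-u)
  # is monotone with derivative in [1-rho, 1]: Newton is safe there
  g_inv <- function(gt) {
    u <- pmax(gt, 0)
    for (it in 1:30) {
      eu <- exp(-u)
      f <- (1 - rho) * u + rho * (1 - eu) - gt
      u <- u - f / ((1 - rho) + rho * eu)
      u[u < 0] <- 0
    }
    -expm1(-u)
  }
  if (!reopening) {
    return(g_inv(g(C0) + s * seq_len(n)))
  }
  tau1 <- params$tau1_us
  gaps <- c(0, diff(schedule$times_us) - schedule$flashlet_duration_us)
  C <- numeric(n)
  c_prev <- C0
  for (j in seq_len(n)) {
    if (j > 1L) c_prev <- max(c_prev - gaps[j] * c_prev / tau1, 0)
    c_prev <- g_inv(g(min(c_prev, 1 - 1e-12)) + s)
    C[j] <- c_prev
  }
  C
}

#' Simulate a single-turnover induction transient
#'
#' Applies the discrete closure recursion per flashlet: each flashlet closes
#' a fraction `dose * sigma_PSII * (1 - C)/(1 - rho C)` of the remaining
#' open centers, and (optionally) centers reopen during the dark gaps with
#' rate `1/tau1`. Fluorescence is read out through [yield_from_closure()].
#'
#' @param params An [st_params()] object.
#' @param schedule An induction [flashlet_schedule()].
#' @param reopening If `TRUE`, include reopening during inter-flashlet dark
#'   gaps (off by default: it contributes under 3 percent for
#'   tau1 >= 400 us over the ~150-190 us induction train).
#' @param wavelength_nm Excitation wavelength stored on the trace.
#' @return An [st_trace()].
#' @export
simulate_induction <- function(params, schedule, reopening = FALSE,
                               wavelength_nm = 442) {
  stopifnot(inherits(schedule, "flashlet_schedule"))
  if (schedule$phase != "induction") {
    stop("simulate_induction requires an induction schedule")
  }
  C <- closure_recursion(params, schedule, reopening = reopening)
  st_trace(wavelength_nm, schedule,
           yield_from_closure(C, params$F0, params$Fm, params$rho))
}

#' Simulate a single-turnover relaxation transient
#'
#' The closed fraction decays biexponentially from its value at the end of
#' induction,
#' \deqn{C(t) = C_{end}\,[\alpha e^{-t/\tau_1} + (1-\alpha) e^{-t/\tau_2}],}
#' probed by sparse flashlets whose own actinic effect is neglected.
#'
#' @param params An [st_params()] object.
#' @param C_end Closed fraction at the end of induction, in (0, 1\].
#' @param schedule A relaxation [flashlet_schedule()].
#' @inheritParams simulate_induction
#' @return An [st_trace()]; fluorescence is monotone non-increasing.
#' @export
simulate_relaxation <- function(params, C_end, schedule,
                                wavelength_nm = 442) {
  stopifnot(inherits(schedule, "flashlet_schedule"))
  if (schedule$phase != "relaxation") {
    stop("simulate_relaxation requires a relaxation schedule")
  }
  if (C_end <= 0 || C_end > 1) {
    stop("C_end must lie in (0, 1]: degenerate relaxation input")
  }
  t <- schedule$times_us
  C <- C_end * (params$alpha * exp(-t / params$tau1_us) +
                  (1 - params$alpha) * exp(-t / params$tau2_us))
  st_trace(wavelength_nm, schedule,
           yield_from_closure(C, params$F0, params$Fm, params$rho))
}

#' Simulate a paired induction + relaxation acquisition
#'
#' Runs the induction recursion, hands its final closure to the relaxation
#' model, and optionally adds multiplicative Gaussian instrument noise.
#'
#' @inheritParams simulate_induction
#' @param ind_schedule,rel_schedule Induction and relaxation schedules; by
#'   default built from the wavelength's canonical flashlet count.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise
#'   applied per flashlet (0 = noiseless).
#' @return A list with elements `induction` and `relaxation` (both
#'   [st_trace()]) and `C_end`, the true closure at the end of induction.
#' @export
simulate_st_pair <- function(params, wavelength_nm = 442,
                             ind_schedule = NULL, rel_schedule = NULL,
                             noise_cv = 0, reopening = FALSE) {
  w <- canonical_wavelength(wavelength_nm)
  if (is.null(ind_schedule)) {
    ind_schedule <- induction_schedule(induction_flashlets_for(w))
  }
  if (is.null(rel_schedule)) rel_schedule <- relaxation_schedule()
  ind <- simulate_induction(params, ind_schedule, reopening = reopening,
                            wavelength_nm = w)
  C_end <- closure_recursion(params, ind_schedule, reopening = reopening)
  C_end <- C_end[length(C_end)]
  rel <- simulate_relaxation(params, C_end, rel_schedule, wavelength_nm = w)
  if (noise_cv > 0) {
    ind$fluorescence <- ind$fluorescence *
      pmax(1 + stats::rnorm(length(ind$fluorescence), 0, noise_cv), 0.01)
    rel$fluorescence <- rel$fluorescence *
      pmax(1 + stats::rnorm(length(rel$fluorescence), 0, noise_cv), 0.01)
  }
  list(induction = ind, relaxation = rel, C_end = C_end)
}
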