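# shared fixtures: everything is generated in code at test time

default_truth <- function(...) {
  args <- utils::modifyList(
    list(F0 = 1000, Fm = 3000, sigma_PSII = 600, rho = 0.5, C0 = 0,
         alpha = 0.6, tau1_us = 600, tau2_us = 15000),
    list(...))
  do.call(st_params, args)
}

# a small cohort that exercises every stage quickly: 8 colonies x 2
# fragments over a shortened protocol
tiny_protocol <- function(n_timepoints = 10L) {
  build_protocol(n_timepoints = n_timepoints, n_repeats = 2L)
}

tiny_config <- function(...) {
  defaults <- list(
    n_colonies = 8L, n_fragments = 2L,
    archetype_of_colony = rep(1:4, each = 2L),
    dominant_type_of_colony = c("C15", "C15", "D1", "D1", "C3", "C3",
                                "C21", "C1"),
    protocol = tiny_protocol())
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# brute-force closure integration at fine dose steps: independent oracle
# for the per-flashlet recursion
closure_oracle <- function(params, schedule, n_sub = 200L) {
  dose_step <- schedule$dose_per_flashlet / n_sub
  C <- params$C0
  out <- numeric(length(schedule$times_us))
  for (j in seq_along(schedule$times_us)) {
    for (s in seq_len(n_sub)) {
      C <- C + dose_step * params$sigma_PSII * (1 - C) / (1 - params$rho * C)
    }
    C <- min(max(C, 0), 1)
    out[j] <- C
  }
  out
}
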