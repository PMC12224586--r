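# Independent individual-level microsimulation oracle for the three-state
# disease model: exchangeable individuals simulated as binomial counts with
# the same annual probabilities q_i = 1 - exp(-i), q_f = 1 - exp(-f). Used
# only as a cross-check; never calls the cohort recursion.

microsim_incident_cases <- function(incidence, case_fatality, prev_start,
                                    start_age, n) {
  S <- n - round(prev_start * n)
  C <- n - S
  total_new <- 0
  for (a in start_age:99) {
    q_i <- 1 - exp(-incidence[a + 1L])
    q_f <- 1 - exp(-case_fatality[a + 1L])
    new_cases <- stats::rbinom(1L, S, q_i)
    deaths <- stats::rbinom(1L, C, q_f)
    S <- S - new_cases
    C <- C + new_cases - deaths
    total_new <- total_new + new_cases
  }
  total_new
}

# Replicated prevented-case estimate (baseline minus scenario arms, each of
# n individuals) returning per-replicate prevented proportions.
microsim_prevented_prop <- function(incidence, case_fatality, pif,
                                    prev_start, start_age, n, reps) {
  vapply(seq_len(reps), function(r) {
    base <- microsim_incident_cases(incidence, case_fatality, prev_start,
                                    start_age, n)
    scen <- microsim_incident_cases(incidence * (1 - pif), case_fatality,
                                    prev_start, start_age, n)
    (base - scen) / n
  }, numeric(1))
}
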