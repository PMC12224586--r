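# Per-disease three-state Markov cohort model: disease-free (S), diseased
# (C), dead from the disease (D). Annual cycles; rates are converted to
# probabilities with q = 1 - exp(-rate). No remission. Other-cause
# mortality is handled in the lifetable (proportional separation), so
# S + C + D is conserved within this sub-model.

#' One annual cycle of the three-state disease model
#'
#' @param S Disease-free count (or proportion).
#' @param C Diseased count (or proportion).
#' @param i Incidence rate per year (among disease-free).
#' @param f Case-fatality rate per year (among diseased).
#' @return List with `S`, `C` (end-of-year states), `new_cases` and
#'   `disease_deaths` occurring during the year.
#' @export
disease_step <- function(S, C, i, f) {
  if (any(i < 0) || any(f < 0)) stop("rates must be non-negative")
  q_i <- 1 - exp(-i)
  q_f <- 1 - exp(-f)
  new_cases <- S * q_i
  disease_deaths <- C * q_f
  list(
    S = S - new_cases,
    C = C + new_cases - disease_deaths,
    new_cases = new_cases,
    disease_deaths = disease_deaths
  )
}

#' Run a closed disease cohort from a starting age to age 100
#'
#' States are proportions of the cohort (other-cause death excluded by the
#' proportional lifetable separation). The cohort starts with the observed
#' prevalence at `start_age` and experiences the supplied age-specific
#' incidence and case fatality. Transitions occur during the year starting
#' at each age up to 99; states are recorded at ages `start_age..100`.
#'
#' @param incidence Numeric vector of incidence rates indexed by age 0..100.
#' @param case_fatality Numeric vector of case-fatality rates, age 0..100.
#' @param prev_start Prevalence proportion at `start_age` (initial C).
#' @param start_age Integer starting age (0..100).
#' @return Data frame with columns `age`, `S`, `C`, `D` (cumulative dead
#'   from disease), `new_cases`, `disease_deaths`; the flow columns hold
#'   events during the year beginning at that age (0 in the final row).
#' @export
run_disease_cohort <- function(incidence, case_fatality, prev_start,
                               start_age) {
  stopifnot(start_age >= 0, start_age <= 100,
            prev_start >= 0, prev_start <= 1,
            length(incidence) == 101L, length(case_fatality) == 101L)
  ages <- seq.int(start_age, 100)
  n <- length(ages)
  S <- C <- D <- nc <- dd <- numeric(n)
  S[1L] <- 1 - prev_start
  C[1L] <- prev_start
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      a <- ages[k]
      st <- disease_step(S[k], C[k], incidence[a + 1L], case_fatality[a + 1L])
      nc[k] <- st$new_cases
      dd[k] <- st$disease_deaths
      S[k + 1L] <- st$S
      C[k + 1L] <- st$C
      D[k + 1L] <- D[k] + st$disease_deaths
    }
  }
  data.frame(age = ages, S = S, C = C, D = D,
             new_cases = nc, disease_deaths = dd)
}

#' Run baseline and counterfactual disease cohorts
#'
#' The counterfactual applies the potential impact fraction to incidence,
#' `i'(a) = i(a) * (1 - pif(a))`; case fatality is identical in both runs.
#'
#' @param incidence,case_fatality Age-indexed rate vectors (0..100).
#' @param pif Age-indexed potential impact fraction vector (0..100).
#' @param prev_start Prevalence proportion at `start_age`.
#' @param start_age Integer starting age.
#' @return List with elements `baseline` and `scenario`, each a trajectory
#'   from [run_disease_cohort()].
#' @export
run_cohort <- function(incidence, case_fatality, pif, prev_start, start_age) {
  stopifnot(length(pif) == 101L, all(pif <= 1))
  list(
    baseline = run_disease_cohort(incidence, case_fatality, prev_start,
                                  start_age),
    scenario = run_disease_cohort(incidence * (1 - pif), case_fatality,
                                  prev_start, start_age)
  )
}

#' Prevented incident cases between two trajectories
#'
#' @param baseline,scenario Aligned trajectories (or any data frames with a
#'   `new_cases` column on the same age grid).
#' @return Total `sum(baseline$new_cases - scenario$new_cases)`.
#' @export
prevented_incident_cases <- function(baseline, scenario) {
  if (!identical(baseline$age, scenario$age)) {
    stop("trajectories are not aligned on the same ages")
  }
  sum(baseline$new_cases - scenario$new_cases)
}

# Vectorised multi-cohort run used by the engine: all cohorts (one per
# starting age) stepped in lock-step over simulation years. Row j of each
# returned matrix is the cohort starting at start_ages[j]; column t is
# simulation year t (1-based column = year t-1). States are recorded at the
# start of each year; flows occur during the year.
run_cohort_matrix <- function(incidence, case_fatality, prev_start_vec,
                              start_ages) {
  ncoh <- length(start_ages)
  tmax <- max(100 - start_ages)          # number of transition years
  S <- C <- matrix(0, ncoh, tmax + 1L)
  NC <- DD <- matrix(0, ncoh, tmax + 1L)
  S[, 1L] <- 1 - prev_start_vec
  C[, 1L] <- prev_start_vec
  if (tmax >= 1L) {
    for (t in seq_len(tmax)) {
      age <- start_ages + (t - 1L)
      active <- age <= 99L
      idx <- pmin(age, 99L) + 1L
      q_i <- (1 - exp(-incidence[idx])) * active
      q_f <- (1 - exp(-case_fatality[idx])) * active
      nc <- S[, t] * q_i
      dd <- C[, t] * q_f
      NC[, t] <- nc
      DD[, t] <- dd
      S[, t + 1L] <- S[, t] - nc
      C[, t + 1L] <- C[, t] + nc - dd
    }
  }
  list(S = S, C = C, new_cases = NC, disease_deaths = DD,
       start_ages = start_ages)
}
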