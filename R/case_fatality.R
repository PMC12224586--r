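# Back-calculation of age-specific case fatality from cause-specific
# incidence, prevalence and mortality, consistent with the three-state
# disease process: a direct deaths-over-prevalent-cases estimator followed
# by a consistency refinement that forward-runs the disease model and
# adjusts case fatality so the model-implied prevalence reproduces the
# observed prevalence. Case fatality is held constant below age 35, where
# sparse counts make the ratio unstable.

#' Direct case-fatality estimator
#'
#' `f(a) = cause_deaths(a) / prevalent_cases(a)`, with cause deaths taken
#' as `cause_mortality * population` and prevalent cases as
#' `prevalence * population`. Ages with fewer than `case_floor` prevalent
#' cases are filled from the nearest valid age (older preferred). Ages
#' below `young_age` are then replaced by their prevalence-weighted mean.
#'
#' @param prevalence Prevalence proportion vector, age 0..100.
#' @param cause_mortality Cause-specific mortality rate vector (per capita,
#'   per year), age 0..100.
#' @param population Population count vector, age 0..100.
#' @param case_floor Minimum prevalent cases for a direct ratio (default 5).
#' @param young_age Age below which case fatality is constant (default 35).
#' @return Case-fatality rate vector, age 0..100.
#' @export
estimate_case_fatality_direct <- function(prevalence, cause_mortality,
                                          population, case_floor = 5,
                                          young_age = 35) {
  stopifnot(length(prevalence) == 101L, length(cause_mortality) == 101L,
            length(population) == 101L)
  cases <- prevalence * population
  deaths <- cause_mortality * population
  if (all(cases == 0) && any(deaths > 0)) {
    stop("cause-specific deaths observed with all-zero prevalence")
  }
  f <- rep(NA_real_, 101L)
  valid <- cases >= case_floor
  f[valid] <- deaths[valid] / cases[valid]
  f[!valid & deaths == 0] <- ifelse(any(valid), NA_real_, 0)
  if (anyNA(f)) {
    if (!any(valid)) {
      f[is.na(f)] <- 0
    } else {
      vidx <- which(valid)
      for (k in which(is.na(f))) {
        # nearest valid age; older neighbour wins ties
        j <- vidx[order(abs(vidx - k), -(vidx))][1L]
        f[k] <- f[j]
      }
    }
  }
  young <- model_ages() < young_age
  w <- cases[young]
  f[young] <- if (sum(w) > 0) sum(f[young] * w) / sum(w) else mean(f[young])
  pmax(f, 0)
}

# Model-implied prevalence from forward-running the three-state process
# from age 0 (unit cohort, zero initial prevalence at the onset of life).
implied_prevalence <- function(incidence, case_fatality) {
  forward_epi(incidence, case_fatality)$prevalence
}

#' Refine case fatality for consistency with the disease model
#'
#' Iteratively adjusts the case-fatality schedule so that forward-running
#' the three-state recursion from age 0 with the observed incidence
#' reproduces the observed prevalence. Each sweep solves, age by age, for
#' the case fatality that maps the current model state onto the next
#' observed prevalence (the exact per-age minimiser of the squared
#' prevalence discrepancy), clamped to non-negative rates; the below-35
#' constancy is re-imposed between sweeps. Ages where observed or model
#' prevalence vanishes keep their initial value.
#'
#' @param f Initial case-fatality vector (e.g. from
#'   [estimate_case_fatality_direct()]), age 0..100.
#' @param incidence Observed incidence rate vector, age 0..100.
#' @param prevalence Observed prevalence proportion vector, age 0..100.
#' @param population Population count vector (used for the prevalence
#'   weighting of the below-35 constant and the residual report).
#' @param max_iter Maximum sweeps (default 25).
#' @param tol Convergence tolerance on the change in maximum relative
#'   prevalence residual (default 1e-10).
#' @param young_age Age below which case fatality is constant (default 35).
#' @param f_cap Upper clamp on rates (default 5 per year).
#' @return List of class `case_fatality_solution` with `case_fatality`,
#'   `fit_residual` (per-age relative prevalence discrepancy), `converged`,
#'   `iterations`. Non-convergence raises a warning, not an error.
#' @export
refine_case_fatality <- function(f, incidence, prevalence, population,
                                 max_iter = 25L, tol = 1e-10,
                                 young_age = 35, f_cap = 5) {
  stopifnot(length(f) == 101L, length(incidence) == 101L,
            length(prevalence) == 101L)
  if (any(f < 0)) stop("initial case fatality must be non-negative")
  ages <- model_ages()
  f_cur <- f
  resid_of <- function(fv) {
    p <- implied_prevalence(incidence, fv)
    ifelse(prevalence > 0, (p - prevalence) / prevalence, p)
  }
  last <- max(abs(resid_of(f_cur)))
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    f_new <- f_cur
    # forward sweep: states follow the model with the updated f
    S <- 1 - prevalence[1L]
    C <- prevalence[1L]
    for (a in 0:99) {
      k <- a + 1L
      q_i <- 1 - exp(-incidence[k])
      new_cases <- S * q_i
      A <- C + new_cases            # diseased before deaths
      B <- S - new_cases            # disease-free entering next age
      p_next <- prevalence[k + 1L]
      if (p_next > 0 && C > 1e-12 && p_next < 1) {
        target_C <- p_next * B / (1 - p_next)
        q_f <- (A - target_C) / C
        q_f <- min(max(q_f, 0), 1 - 1e-12)
        f_new[k] <- min(-log(1 - q_f), f_cap)
      }
      q_f_used <- 1 - exp(-f_new[k])
      deaths <- C * q_f_used
      S <- B
      C <- A - deaths
    }
    # re-impose the below-35 constancy (prevalence-weighted)
    young <- ages < young_age
    w <- prevalence[young] * population[young]
    f_new[young] <- if (sum(w) > 0) {
      sum(f_new[young] * w) / sum(w)
    } else {
      mean(f_new[young])
    }
    f_cur <- pmax(f_new, 0)
    cur <- max(abs(resid_of(f_cur)))
    if (abs(cur - last) < tol) {
      converged <- TRUE
      last <- cur
      break
    }
    last <- cur
  }
  if (!converged) {
    warning("case-fatality refinement did not converge in ", max_iter,
            " sweeps (residual ", signif(last, 3), ")")
  }
  structure(
    list(case_fatality = f_cur, fit_residual = resid_of(f_cur),
         converged = converged, iterations = iterations),
    class = "case_fatality_solution"
  )
}

#' Solve case fatality from observed epidemiology
#'
#' Convenience wrapper: direct estimator followed by the consistency
#' refinement.
#'
#' @inheritParams estimate_case_fatality_direct
#' @inheritParams refine_case_fatality
#' @param refine Run the refinement step (default TRUE).
#' @return A `case_fatality_solution` (see [refine_case_fatality()]).
#' @export
solve_case_fatality <- function(prevalence, cause_mortality, population,
                                incidence, refine = TRUE, case_floor = 5,
                                young_age = 35, max_iter = 25L,
                                tol = 1e-10) {
  f0 <- estimate_case_fatality_direct(prevalence, cause_mortality,
                                      population, case_floor = case_floor,
                                      young_age = young_age)
  if (!refine) {
    return(structure(
      list(case_fatality = f0,
           fit_residual = rep(NA_real_, 101L),
           converged = NA, iterations = 0L),
      class = "case_fatality_solution"
    ))
  }
  refine_case_fatality(f0, incidence, prevalence, population,
                       max_iter = max_iter, tol = tol,
                       young_age = young_age)
}
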