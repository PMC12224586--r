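# Seeded generators for every model input, with the structure of the
# national sources the model is designed for: a 1-year population pyramid
# with Gompertz-Makeham mortality, disease epidemiology produced by
# forward-running the three-state disease process from known parameters
# (so the case-fatality solver has a ground truth), sodium intakes by DRI
# age/sex group calibrated to a configured population mean, systolic blood
# pressure by survey band with the 80+ carry-forward, and banded
# healthcare costs and utility weights.

#' DRI age/sex groups used for sodium intakes and interventions
#'
#' @return Data frame with columns `sex`, `age_lo`, `age_hi`, `group`
#'   (adult Dietary Reference Intake strata 19-30, 31-50, 51-70, 71+).
#' @export
dri_groups <- function() {
  g <- data.frame(
    age_lo = c(19L, 31L, 51L, 71L),
    age_hi = c(30L, 50L, 70L, 100L),
    group = c("19-30", "31-50", "51-70", "71+")
  )
  out <- rbind(
    cbind(sex = "male", g, stringsAsFactors = FALSE),
    cbind(sex = "female", g, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Generate a synthetic population with Gompertz-Makeham mortality
#'
#' All-cause mortality follows `m(a) = min(1, alpha + beta * exp(gamma * a))`
#' for both sexes. Population counts are drawn from a multinomial over ages
#' whose weights follow the survivorship implied by that hazard times a
#' small lognormal perturbation, so the pyramid decreases stochastically
#' with age and the requested total is conserved exactly.
#'
#' @param seed Integer seed.
#' @param total_size Total population across both sexes (> 0).
#' @param sex_ratio Proportion male (default 0.5).
#' @param gompertz List with `alpha` (>= 0), `beta` (> 0 unless degenerate),
#'   `gamma` (> 0).
#' @param jitter_sd Lognormal sd of the age-weight perturbation.
#' @return List with grids `population` (counts) and `all_cause_mortality`
#'   (rates per year).
#' @export
generate_population <- function(seed = 1L, total_size = 1e6,
                                sex_ratio = 0.5,
                                gompertz = list(alpha = 5e-4, beta = 3e-5,
                                                gamma = 0.095),
                                jitter_sd = 0.02) {
  if (total_size <= 0) stop("total_size must be positive")
  if (gompertz$alpha < 0 || gompertz$beta < 0 || gompertz$gamma < 0) {
    stop("gompertz parameters must be non-negative")
  }
  ages <- model_ages()
  m <- pmin(1, gompertz$alpha + gompertz$beta * exp(gompertz$gamma * ages))
  mort <- age_sex_grid(m)

  set.seed(seed)
  surv <- exp(-cumsum(c(0, m[-length(m)])))
  pop <- age_sex_grid(0)
  n_male <- round(total_size * sex_ratio)
  n_by_sex <- c(male = n_male, female = total_size - n_male)
  for (s in model_sexes()) {
    w <- surv * exp(stats::rnorm(length(surv), 0, jitter_sd))
    pop[, s] <- as.numeric(stats::rmultinom(1L, n_by_sex[[s]], w / sum(w)))
  }
  list(population = pop, all_cause_mortality = mort)
}

#' Default true epidemiological parameters for the synthetic diseases
#'
#' Incidence is zero below an onset age, flat to 35, then log-linear in
#' age; case fatality is constant below 35 (mirroring the back-calculation
#' assumption) and log-linear above. Male rates exceed female rates by a
#' configurable multiplier, as for cardiovascular disease.
#'
#' @return Nested list by disease (`ihd`, `stroke`) with fields `i35`,
#'   `i_growth`, `onset_age`, `f35`, `f_growth`, `sex_mult` (male, female)
#'   and `remission` (identically 0).
#' @export
default_epi_params <- function() {
  list(
    ihd = list(i35 = 8e-4, i_growth = 0.045, onset_age = 20L,
               f35 = 0.02, f_growth = 0.030,
               sex_mult = c(male = 1.4, female = 1.0), remission = 0),
    stroke = list(i35 = 3e-4, i_growth = 0.055, onset_age = 20L,
                  f35 = 0.03, f_growth = 0.035,
                  sex_mult = c(male = 1.2, female = 1.0), remission = 0)
  )
}

incidence_curve <- function(p, sex) {
  ages <- model_ages()
  i <- p$i35 * exp(p$i_growth * pmax(ages - 35, 0))
  i[ages < p$onset_age] <- 0
  pmin(i * p$sex_mult[[sex]], 1)
}

case_fatality_curve <- function(p, sex) {
  ages <- model_ages()
  f <- p$f35 * exp(p$f_growth * pmax(ages - 35, 0))
  pmin(f * p$sex_mult[[sex]], 1)
}

# Forward-run the three-state process from age 0 on a unit cohort and read
# off start-of-age prevalence (C / (S + C)) and the cause-specific
# mortality rate among the alive, -log(1 - deaths / (S + C)).
forward_epi <- function(incidence, case_fatality) {
  traj <- run_disease_cohort(incidence, case_fatality, 0, 0)
  alive <- traj$S + traj$C
  prev <- ifelse(alive > 0, traj$C / alive, 0)
  q_d <- ifelse(alive > 0, traj$disease_deaths / alive, 0)
  cmort <- -log(pmax(1 - q_d, .Machine$double.eps))
  list(prevalence = prev, cause_mortality = cmort)
}

#' Generate disease epidemiology consistent with the three-state model
#'
#' For each disease and sex, prevalence and cause-specific mortality are
#' produced by forward-running the three-state disease process with the
#' known ("true") incidence and case fatality, so the case-fatality
#' back-calculation can be validated by parameter recovery. Optionally the
#' grids are re-aggregated to 5-year source groups (20 to 90+) to mimic
#' surveillance granularity.
#'
#' @param seed Integer seed (the generator is deterministic; kept for
#'   interface symmetry).
#' @param params Nested parameter list as [default_epi_params()].
#' @param population Output of [generate_population()] (needed for source
#'   granularity aggregation weights).
#' @param granularity `"1y"` (default) or `"source"`.
#' @return List with per-disease grids `incidence`, `prevalence`,
#'   `cause_mortality` (or grouped series at source granularity) and the
#'   ground-truth `case_fatality_true` grids.
#' @export
generate_disease_epi <- function(seed = 1L, params = default_epi_params(),
                                 population = NULL,
                                 granularity = c("1y", "source")) {
  granularity <- match.arg(granularity)
  out <- list(granularity = granularity, diseases = names(params))
  for (d in names(params)) {
    p <- params[[d]]
    if (!is.null(p$remission) && p$remission != 0) {
      stop("remission must be identically 0 in the three-state model")
    }
    inc <- age_sex_grid(0); prev <- age_sex_grid(0)
    cmort <- age_sex_grid(0); cf <- age_sex_grid(0)
    for (s in model_sexes()) {
      inc[, s] <- incidence_curve(p, s)
      cf[, s] <- case_fatality_curve(p, s)
      fwd <- forward_epi(inc[, s], cf[, s])
      prev[, s] <- fwd$prevalence
      cmort[, s] <- fwd$cause_mortality
    }
    if (any(inc > 1) || any(cf > 1)) stop("rates outside [0, 1]")
    out[[d]] <- list(incidence = inc, prevalence = prev,
                     cause_mortality = cmort, case_fatality_true = cf)
  }
  if (granularity == "source") {
    stopifnot(!is.null(population))
    for (d in names(params)) {
      for (what in c("incidence", "prevalence", "cause_mortality")) {
        out[[d]][[paste0(what, "_groups")]] <- lapply(
          stats::setNames(model_sexes(), model_sexes()),
          function(s) aggregate_rate_groups(out[[d]][[what]][, s],
                                            population$population[, s])
        )
      }
    }
  }
  out
}

# Population-weighted aggregation of a 1-year rate vector to the source
# granularity: 5-year groups from 20 to 89 plus an open 90+ group.
aggregate_rate_groups <- function(rate_1y, pop_1y,
                                  breaks_lo = c(seq(20L, 85L, 5L), 90L)) {
  ages <- model_ages()
  lo <- breaks_lo
  hi <- c(breaks_lo[-1L] - 1L, 100L)
  value <- vapply(seq_along(lo), function(k) {
    sel <- ages >= lo[k] & ages <= hi[k]
    w <- pop_1y[sel]
    if (sum(w) > 0) sum(rate_1y[sel] * w) / sum(w) else mean(rate_1y[sel])
  }, numeric(1))
  data.frame(age_lo = lo, age_hi = hi, value = value)
}

#' Default DRI-group sodium intake configuration
#'
#' Group-shape means (mg/day) decline with age and are higher in males, as
#' in Canadian survey data; they are rescaled at generation time so the
#' population-weighted mean matches the configured baseline.
#'
#' @return List with `means`, `ses` (named `sex.group` in [dri_groups()]
#'   order) and `target_mean` (2758 mg/day).
#' @export
default_sodium_config <- function() {
  g <- dri_groups()
  key <- paste(g$sex, g$group, sep = ".")
  list(
    means = stats::setNames(
      c(3306, 3203, 2906, 2426, 2437, 2384, 2279, 1966), key),
    ses = stats::setNames(
      c(95, 80, 85, 110, 75, 65, 70, 95), key),
    target_mean = 2758
  )
}

#' Generate usual sodium intakes by DRI age/sex group
#'
#' Group weights default to the adult population shares over each group's
#' age range. When `target_mean` is non-NULL, group means are rescaled by a
#' single factor so that the population-weighted mean equals the target
#' exactly.
#'
#' @param seed Integer seed (interface symmetry; generation is
#'   deterministic).
#' @param config List as [default_sodium_config()].
#' @param population Output of [generate_population()]; required when
#'   `weights` is NULL.
#' @param weights Optional named group weights summing to 1.
#' @return Data frame (one row per DRI group) with columns `sex`, `group`,
#'   `age_lo`, `age_hi`, `mean_mg_day`, `se_mg_day`, `weight`, and
#'   attribute `weighted_mean`.
#' @export
generate_sodium_intakes <- function(seed = 1L,
                                    config = default_sodium_config(),
                                    population = NULL, weights = NULL) {
  g <- dri_groups()
  key <- paste(g$sex, g$group, sep = ".")
  if (is.null(weights)) {
    stopifnot(!is.null(population))
    pop <- population$population
    ages <- model_ages()
    w <- vapply(seq_len(nrow(g)), function(k) {
      sum(pop[ages >= g$age_lo[k] & ages <= g$age_hi[k], g$sex[k]])
    }, numeric(1))
    weights <- w / sum(w)
  } else {
    weights <- weights[key]
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  means <- config$means[key]
  if (any(means <= 0)) stop("group means must be positive")
  if (!is.null(config$target_mean)) {
    means <- means * config$target_mean / sum(weights * means)
  }
  out <- data.frame(
    sex = g$sex, group = g$group, age_lo = g$age_lo, age_hi = g$age_hi,
    mean_mg_day = as.numeric(means),
    se_mg_day = as.numeric(config$ses[key]),
    weight = as.numeric(weights),
    stringsAsFactors = FALSE
  )
  attr(out, "weighted_mean") <- sum(out$weight * out$mean_mg_day)
  out
}

#' Default mean systolic blood pressure by survey band (mmHg)
#' @return Data frame with `sex`, `age_lo`, `age_hi`, `value` through the
#'   60-79 band.
#' @export
default_sbp_bands <- function() {
  lo <- c(6L, 12L, 20L, 40L, 60L)
  hi <- c(11L, 19L, 39L, 59L, 79L)
  rbind(
    data.frame(sex = "male", age_lo = lo, age_hi = hi,
               value = c(102, 110, 114, 122, 131)),
    data.frame(sex = "female", age_lo = lo, age_hi = hi,
               value = c(100, 106, 109, 119, 129))
  )
}

#' Generate mean SBP by band with the 80+ carry-forward
#'
#' Measurements are unavailable for ages 80+; each sex's 80+ band is
#' assigned the 60-79 value.
#'
#' @param seed Integer seed (interface symmetry).
#' @param bands Data frame as [default_sbp_bands()]; must include a 60-79
#'   band per sex.
#' @return Band data frame including the 80-100 band.
#' @export
generate_sbp <- function(seed = 1L, bands = default_sbp_bands()) {
  if (any(bands$value <= 0)) stop("SBP values must be positive")
  out <- bands
  for (s in unique(bands$sex)) {
    ref <- bands[bands$sex == s & bands$age_lo == 60L & bands$age_hi == 79L, ]
    if (nrow(ref) != 1L) stop("missing 60-79 band for sex ", s)
    out <- rbind(out, data.frame(sex = s, age_lo = 80L, age_hi = 100L,
                                 value = ref$value))
  }
  out[order(out$sex, out$age_lo), ]
}

#' EBIC-style cost bands
#' @return Data frame with `age_lo`, `age_hi` for bands 0-14, 15-34, 35-54,
#'   55-64, 65-74, 75+.
#' @export
cost_bands <- function() {
  data.frame(age_lo = c(0L, 15L, 35L, 55L, 65L, 75L),
             age_hi = c(14L, 34L, 54L, 64L, 74L, 100L))
}

#' Default cost and utility configuration
#'
#' @return List with per-case attributable cost targets by disease (CAD/yr,
#'   cost-source currency year), band age multipliers, the unattributable
#'   share of total attributable costs, the healthcare CPI inflation factor
#'   to 2019 CAD, background utilities by 10-year band and per-disease
#'   utility decrements.
#' @export
default_cost_utility_config <- function() {
  list(
    per_case_attributable = c(ihd = 3200, stroke = 4100),
    band_age_mult = c(0.4, 0.6, 0.8, 1.0, 1.1, 1.2),
    unattributable_share = 0.25,
    cpi_factor = 1.17,
    background_utility = c(0.94, 0.93, 0.92, 0.91, 0.89,
                           0.87, 0.84, 0.80, 0.75, 0.70, 0.62),
    disease_utility_decrement = c(ihd = 0.07, stroke = 0.12),
    cost_noise_sd = 0.05
  )
}

#' Generate banded healthcare costs and utility weights
#'
#' Attributable direct costs per band, sex and disease are built as a
#' per-case target times the band's prevalent cases (from the supplied
#' epidemiology), with a small lognormal perturbation; unattributable
#' totals per band and sex are a configured share of total attributable
#' costs. Utilities are a background weight per 10-year age band and a
#' decrement per prevalent disease.
#'
#' @param seed Integer seed.
#' @param config List as [default_cost_utility_config()].
#' @param population Output of [generate_population()].
#' @param epi Output of [generate_disease_epi()].
#' @return List with `attributable` (data frame band x sex x disease total
#'   CAD/yr), `unattributable` (band x sex totals), `prevalent_cases`
#'   (band x sex x disease), `cpi_factor`, `background_utility` (10-year
#'   band data frame) and `disease_utility_decrement`.
#' @export
generate_costs_utilities <- function(seed = 1L,
                                     config = default_cost_utility_config(),
                                     population, epi) {
  if (any(config$background_utility < 0 | config$background_utility > 1)) {
    stop("background utilities must lie in [0, 1]")
  }
  if (any(config$disease_utility_decrement < 0 |
          config$disease_utility_decrement > 1)) {
    stop("utility decrements must lie in [0, 1]")
  }
  set.seed(seed + 1L)
  bands <- cost_bands()
  ages <- model_ages()
  diseases <- epi$diseases
  rows <- list()
  prevrows <- list()
  for (s in model_sexes()) {
    for (k in seq_len(nrow(bands))) {
      sel <- ages >= bands$age_lo[k] & ages <= bands$age_hi[k]
      for (d in diseases) {
        cases <- sum(epi[[d]]$prevalence[sel, s] *
                       population$population[sel, s])
        noise <- exp(stats::rnorm(1L, 0, config$cost_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          sex = s, age_lo = bands$age_lo[k], age_hi = bands$age_hi[k],
          disease = d,
          value = config$per_case_attributable[[d]] *
            config$band_age_mult[k] * cases * noise
        )
        prevrows[[length(prevrows) + 1L]] <- data.frame(
          sex = s, age_lo = bands$age_lo[k], age_hi = bands$age_hi[k],
          disease = d, value = cases
        )
      }
    }
  }
  attributable <- do.call(rbind, rows)
  prevalent <- do.call(rbind, prevrows)
  unattr <- stats::aggregate(value ~ sex + age_lo + age_hi,
                             data = attributable, FUN = sum)
  unattr$value <- unattr$value * config$unattributable_share
  bg <- data.frame(
    age_lo = seq(0L, 100L, 10L),
    age_hi = c(seq(9L, 99L, 10L), 100L),
    value = config$background_utility
  )
  list(attributable = attributable, unattributable = unattr,
       prevalent_cases = prevalent, cpi_factor = config$cpi_factor,
       background_utility = bg,
       disease_utility_decrement = config$disease_utility_decrement)
}

#' Generate the complete synthetic input set
#'
#' Orchestrates all generators under one seed; the result is the raw-input
#' object consumed by [prepare_inputs()].
#'
#' @param seed Integer seed.
#' @param total_size Total population size.
#' @param granularity `"1y"` or `"source"` for the epidemiology grids.
#' @param epi_params,sodium_config,cost_config,sbp_bands,gompertz Optional
#'   overrides of the module defaults.
#' @return List with components `population`, `epi`, `sodium`, `sbp`,
#'   `costs`, `granularity`, `seed`.
#' @export
synthetic_inputs <- function(seed = 1L, total_size = 1e6,
                             granularity = c("1y", "source"),
                             epi_params = default_epi_params(),
                             sodium_config = default_sodium_config(),
                             cost_config = default_cost_utility_config(),
                             sbp_bands = default_sbp_bands(),
                             gompertz = list(alpha = 5e-4, beta = 3e-5,
                                             gamma = 0.095)) {
  granularity <- match.arg(granularity)
  popn <- generate_population(seed, total_size = total_size,
                              gompertz = gompertz)
  epi <- generate_disease_epi(seed, params = epi_params, population = popn,
                              granularity = granularity)
  sodium <- generate_sodium_intakes(seed, config = sodium_config,
                                    population = popn)
  sbp <- generate_sbp(seed, bands = sbp_bands)
  costs <- generate_costs_utilities(seed, config = cost_config,
                                    population = popn, epi = epi)
  list(population = popn, epi = epi, sodium = sodium, sbp = sbp,
       costs = costs, granularity = granularity, seed = seed)
}

#' Write the synthetic input tables as CSV files
#'
#' One file per table with columns (`age` or `age_lo`/`age_hi`, `sex`,
#' `value`[, `disease`]).
#'
#' @param inputs Output of [synthetic_inputs()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_inputs_csv <- function(inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(grid_to_df(inputs$population$population), "population")
  wr(grid_to_df(inputs$population$all_cause_mortality), "all_cause_mortality")
  for (d in inputs$epi$diseases) {
    for (what in c("incidence", "prevalence", "cause_mortality")) {
      df <- grid_to_df(inputs$epi[[d]][[what]])
      df$disease <- d
      wr(df, paste(d, what, sep = "_"))
    }
  }
  wr(inputs$sodium, "sodium_intakes")
  wr(inputs$sbp, "sbp_bands")
  wr(inputs$costs$attributable, "costs_attributable")
  wr(inputs$costs$unattributable, "costs_unattributable")
  wr(inputs$costs$background_utility, "background_utility")
  invisible(files)
}
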