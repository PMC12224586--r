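# Pipeline orchestration: raw inputs -> prepared 1-year model inputs
# (age preparation + case-fatality back-calculation + cost construction),
# scenario runs over the closed adult cohort, Monte Carlo uncertainty and
# discount/horizon sensitivity analyses.

#' Prepare raw inputs for simulation
#'
#' Brings every table to the 1-year 0-100 grid: source-granularity disease
#' epidemiology is disaggregated (counts-conserving) and extrapolated
#' beyond its last closed group with a polynomial trend; case fatality is
#' back-calculated per disease and sex; banded SBP, utilities and costs
#' are expanded piecewise-constant; per-case costs are built by allocating
#' unattributable costs proportionally to attributable shares, dividing by
#' prevalent cases and inflating to the reference currency year.
#'
#' @param raw Raw input list from [synthetic_inputs()] (or the same
#'   structure read from CSV).
#' @param effect Effect model (see [default_effect_model()]).
#' @param poly_order,n_fit Extrapolation settings passed to
#'   [rates_to_1y()] for source-granularity epidemiology.
#' @param refine_cf Run the case-fatality consistency refinement.
#' @return Object of class `pmsalt_model`: 1-year grids for population,
#'   all-cause mortality, per-disease incidence/prevalence/case fatality,
#'   SBP, per-case costs, utilities; the DRI-group sodium intakes; and the
#'   effect model.
#' @export
prepare_inputs <- function(raw, effect = default_effect_model(),
                           poly_order = 2, n_fit = 6, refine_cf = TRUE) {
  pop <- raw$population$population
  acm <- raw$population$all_cause_mortality
  diseases <- raw$epi$diseases
  ages <- model_ages()

  inc <- prev <- cmort <- cf <- stats::setNames(
    vector("list", length(diseases)), diseases)
  cf_solutions <- list()
  for (d in diseases) {
    if (identical(raw$granularity, "source")) {
      gi <- age_sex_grid(0); gp <- age_sex_grid(0); gm <- age_sex_grid(0)
      for (s in model_sexes()) {
        gi[, s] <- rates_to_1y(raw$epi[[d]]$incidence_groups[[s]],
                               pop[, s], poly_order, n_fit)
        gp[, s] <- rates_to_1y(raw$epi[[d]]$prevalence_groups[[s]],
                               pop[, s], poly_order, n_fit)
        gm[, s] <- rates_to_1y(raw$epi[[d]]$cause_mortality_groups[[s]],
                               pop[, s], poly_order, n_fit)
      }
      inc[[d]] <- gi; prev[[d]] <- gp; cmort[[d]] <- gm
    } else {
      inc[[d]] <- raw$epi[[d]]$incidence
      prev[[d]] <- raw$epi[[d]]$prevalence
      cmort[[d]] <- raw$epi[[d]]$cause_mortality
    }
    g <- age_sex_grid(0)
    for (s in model_sexes()) {
      sol <- solve_case_fatality(prev[[d]][, s], cmort[[d]][, s], pop[, s],
                                 inc[[d]][, s], refine = refine_cf)
      g[, s] <- sol$case_fatality
      cf_solutions[[paste(d, s, sep = ".")]] <- sol
    }
    cf[[d]] <- g
  }

  # SBP: bands start at age 6; carry the youngest band down to age 0
  sbp <- age_sex_grid(0)
  for (s in model_sexes()) {
    b <- raw$sbp[raw$sbp$sex == s, ]
    b0 <- b[which.min(b$age_lo), ]
    if (b0$age_lo > 0) {
      b <- rbind(data.frame(sex = s, age_lo = 0L, age_hi = b0$age_lo - 1L,
                            value = b0$value), b)
    }
    sbp[, s] <- expand_bands(b, ages)
  }

  # per-case costs: allocate unattributable, divide by prevalent cases,
  # inflate, expand to 1-year ages
  cpc <- stats::setNames(vector("list", length(diseases)), diseases)
  for (d in diseases) cpc[[d]] <- age_sex_grid(0)
  bands <- cost_bands()
  for (s in model_sexes()) {
    for (k in seq_len(nrow(bands))) {
      sel <- function(df) df[df$sex == s & df$age_lo == bands$age_lo[k], ]
      attr_d <- lapply(stats::setNames(diseases, diseases), function(d) {
        x <- sel(raw$costs$attributable)
        x$value[x$disease == d]
      })
      un <- sel(raw$costs$unattributable)$value
      add <- allocate_unattributable(attr_d, un)
      age_sel <- ages >= bands$age_lo[k] & ages <= bands$age_hi[k]
      for (d in diseases) {
        x <- sel(raw$costs$prevalent_cases)
        cases <- x$value[x$disease == d]
        total <- attr_d[[d]] + add[[d]]
        cpc[[d]][age_sel, s] <- inflate(cost_per_case(total, cases),
                                        raw$costs$cpi_factor)
      }
    }
  }

  util_bg <- age_sex_grid(expand_bands(raw$costs$background_utility, ages))

  structure(
    list(population = pop, all_cause_mortality = acm, diseases = diseases,
         incidence = inc, prevalence = prev, cause_mortality = cmort,
         case_fatality = cf, cf_solutions = cf_solutions, sbp = sbp,
         cost_per_case = cpc, background_utility = util_bg,
         disease_utility_decrement = raw$costs$disease_utility_decrement,
         sodium = raw$sodium, effect = effect, seed = raw$seed),
    class = "pmsalt_model"
  )
}

# Core engine: outcomes for a given PIF table. Cohorts start at every adult
# age 19..100 and are followed to age 100 (ages above 99 accrue nothing).
# Returns a tidy data frame of undiscounted prevented cases and discounted
# QALY gains / cost savings by disease and sex, with aggregates.
outcomes_for_pif <- function(model, pif_list, econ = econ_settings()) {
  diseases <- model$diseases
  r <- econ$discount_rate
  H <- if (identical(econ$horizon, "lifetime")) Inf else econ$horizon
  a0s <- 19:100
  rows <- list()
  for (s in model_sexes()) {
    N <- model$population[a0s + 1L, s]
    tmax <- max(100 - a0s)
    tcols <- seq_len(tmax)                      # transition years (1-based)
    age_mat <- outer(a0s, tcols - 1L, `+`)       # age during year t
    active <- age_mat <= 99L
    in_horizon <- matrix(rep((tcols - 1L) < H, each = length(a0s)),
                         nrow = length(a0s))
    disc <- matrix(rep(discount_factor(tcols, r), each = length(a0s)),
                   nrow = length(a0s))
    use <- active & in_horizon

    m_mat <- matrix(0, length(a0s), tmax)
    m_mat[active] <- model$all_cause_mortality[age_mat[active] + 1L, s]

    base <- scen <- list()
    mx_b <- mx_s <- list()
    for (d in diseases) {
      incv <- model$incidence[[d]][, s]
      cfv <- model$case_fatality[[d]][, s]
      prev0 <- model$prevalence[[d]][a0s + 1L, s]
      base[[d]] <- run_cohort_matrix(incv, cfv, prev0, a0s)
      scen[[d]] <- run_cohort_matrix(incv * (1 - pif_list[[d]][, s]), cfv,
                                     prev0, a0s)
      rate_of <- function(tr) {
        alive <- tr$S[, tcols] + tr$C[, tcols]
        q <- ifelse(alive > 0, tr$disease_deaths[, tcols] / alive, 0)
        -log(pmax(1 - q, .Machine$double.eps))
      }
      mx_b[[d]] <- rate_of(base[[d]])
      mx_s[[d]] <- rate_of(scen[[d]])
    }

    m_scen <- m_mat
    for (d in diseases) m_scen <- m_scen - (mx_b[[d]] - mx_s[[d]])
    m_scen <- pmax(m_scen, 0)  # arg order: pmax(0, m) drops the dim attribute

    lt_of <- function(mm) {
      l <- matrix(0, length(a0s), tmax + 1L)
      l[, 1L] <- N
      for (t in tcols) l[, t + 1L] <- l[, t] * exp(-mm[, t] * active[, t])
      L <- (l[, tcols, drop = FALSE] + l[, tcols + 1L, drop = FALSE]) / 2
      L * active
    }
    L_b <- lt_of(m_mat)
    L_s <- lt_of(m_scen)

    qw_of <- function(trs, Lm) {
      bg <- matrix(0, length(a0s), tmax)
      bg[active] <- model$background_utility[age_mat[active] + 1L, s]
      w <- bg
      for (d in diseases) {
        alive <- trs[[d]]$S[, tcols] + trs[[d]]$C[, tcols]
        pr <- ifelse(alive > 0, trs[[d]]$C[, tcols] / alive, 0)
        w <- w * (1 - pr * model$disease_utility_decrement[[d]])
      }
      sum((Lm * w * disc)[use])
    }
    qaly_gain <- qw_of(scen, L_s) - qw_of(base, L_b)
    rows[[length(rows) + 1L]] <- data.frame(
      disease = "all", sex = s, outcome = "qalys", value = qaly_gain)

    for (d in diseases) {
      share_of <- function(tr, what) {
        alive <- tr$S[, tcols] + tr$C[, tcols]
        ifelse(alive > 0, tr[[what]][, tcols] / alive, 0)
      }
      prevented <- sum((share_of(base[[d]], "new_cases") * L_b -
                          share_of(scen[[d]], "new_cases") * L_s)[use])
      cost <- matrix(0, length(a0s), tmax)
      cost[active] <- model$cost_per_case[[d]][age_mat[active] + 1L, s]
      savings <- sum(((share_of(base[[d]], "C") * L_b -
                         share_of(scen[[d]], "C") * L_s) * cost * disc)[use])
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, sex = s,
        outcome = c("prevented_cases", "savings_cad"),
        value = c(prevented, savings))
    }
  }
  res <- do.call(rbind, rows)
  add_margins(res)
}

# Aggregate rows: sum over sexes ("both") and over diseases ("all").
add_margins <- function(res) {
  out <- res
  for (oc in unique(res$outcome)) {
    sub <- res[res$outcome == oc, ]
    for (d in unique(sub$disease)) {
      dd <- sub[sub$disease == d, ]
      out <- rbind(out, data.frame(disease = d, sex = "both", outcome = oc,
                                   value = sum(dd$value)))
    }
    if (!all(sub$disease == "all")) {
      for (s in unique(sub$sex)) {
        ss <- sub[sub$sex == s, ]
        out <- rbind(out, data.frame(disease = "all", sex = s, outcome = oc,
                                     value = sum(ss$value)))
      }
      out <- rbind(out, data.frame(disease = "all", sex = "both",
                                   outcome = oc, value = sum(sub$value)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Run one counterfactual scenario deterministically
#'
#' Applies the scenario to the DRI-group intakes, builds the PIF table and
#' runs the full lifetable for baseline and counterfactual.
#'
#' @param model Prepared model from [prepare_inputs()].
#' @param scn A [scenario()].
#' @param econ [econ_settings()].
#' @return Data frame with columns `scenario`, `disease`, `sex`, `outcome`
#'   (`prevented_cases`, `qalys`, `savings_cad`), `value`, including
#'   `disease = "all"` and `sex = "both"` aggregates.
#' @export
run_scenario <- function(model, scn, econ = econ_settings()) {
  stopifnot(inherits(model, "pmsalt_model"))
  pif_list <- pif_table(model$sodium, scn, model$effect)
  res <- outcomes_for_pif(model, pif_list, econ)
  cbind(scenario = scn$id, res)
}

#' Run all scenarios
#'
#' @param model Prepared model.
#' @param scenarios Named list of scenarios (default [default_scenarios()]).
#' @param econ [econ_settings()].
#' @return Row-bound results of [run_scenario()].
#' @export
run_all_scenarios <- function(model, scenarios = default_scenarios(),
                              econ = econ_settings()) {
  do.call(rbind, lapply(scenarios, function(s) run_scenario(model, s, econ)))
}

#' Monte Carlo settings
#'
#' Distribution families for the perturbed parameters: log-normal
#' multipliers for relative risks per 20 mmHg and case fatality, normal
#' draws for sodium-SBP slopes and DRI-group intake means (the latter with
#' their reported standard errors), gamma multipliers for per-case costs.
#'
#' @param n Number of iterations (default 5000).
#' @param seed Master seed.
#' @param rr20_sdlog Log-sd of the RR multipliers.
#' @param slope_sd_frac Coefficient of variation of the SBP slopes.
#' @param cost_cv Coefficient of variation of the per-case cost multiplier.
#' @param cf_sdlog Log-sd of the case-fatality multiplier.
#' @param intake_se_scale Multiplier on the intake standard errors.
#' @return List of settings.
#' @export
mc_settings <- function(n = 5000L, seed = 1L, rr20_sdlog = 0.08,
                        slope_sd_frac = 0.15, cost_cv = 0.2,
                        cf_sdlog = 0.1, intake_se_scale = 1) {
  if (n < 1) stop("n must be >= 1")
  if (any(c(rr20_sdlog, slope_sd_frac, cost_cv, cf_sdlog,
            intake_se_scale) < 0)) {
    stop("distribution parameters must be non-negative")
  }
  list(n = as.integer(n), seed = as.integer(seed), rr20_sdlog = rr20_sdlog,
       slope_sd_frac = slope_sd_frac, cost_cv = cost_cv,
       cf_sdlog = cf_sdlog, intake_se_scale = intake_se_scale)
}

# One parameter draw: returns a perturbed copy of the model.
perturb_model <- function(model, mc) {
  m <- model
  for (d in names(m$effect$rr20_bands)) {
    v <- m$effect$rr20_bands[[d]]$value
    m$effect$rr20_bands[[d]]$value <-
      pmax(1, exp(stats::rnorm(length(v), log(v), mc$rr20_sdlog)))
  }
  v <- m$effect$slope_bands$value
  m$effect$slope_bands$value <-
    pmax(0, stats::rnorm(length(v), v, mc$slope_sd_frac * v))
  m$sodium$mean_mg_day <- pmax(1, stats::rnorm(
    nrow(m$sodium), m$sodium$mean_mg_day,
    mc$intake_se_scale * m$sodium$se_mg_day))
  for (d in m$diseases) {
    mult <- if (mc$cost_cv > 0) {
      stats::rgamma(1L, shape = 1 / mc$cost_cv^2, scale = mc$cost_cv^2)
    } else 1
    m$cost_per_case[[d]] <- m$cost_per_case[[d]] * mult
    m$case_fatality[[d]] <- m$case_fatality[[d]] *
      exp(stats::rnorm(1L, 0, mc$cf_sdlog))
  }
  m
}

#' Monte Carlo uncertainty analysis for one scenario
#'
#' Per iteration, parameters are drawn from their distributions (seeded,
#' order-invariant per-iteration substreams derived from the master seed)
#' and the deterministic pipeline is rerun; uncertainty intervals are the
#' empirical 2.5th and 97.5th percentiles. The point estimate is the
#' unperturbed deterministic run.
#'
#' @param model Prepared model.
#' @param scn A [scenario()].
#' @param econ [econ_settings()].
#' @param mc [mc_settings()].
#' @return Data frame with `scenario`, `disease`, `sex`, `outcome`,
#'   `point`, `lo95`, `hi95`, `mc_mean`, `n_iterations`.
#' @export
monte_carlo <- function(model, scn, econ = econ_settings(),
                        mc = mc_settings(n = 200L)) {
  if (mc$n < 2) stop("n must be >= 2 for percentiles")
  point <- run_scenario(model, scn, econ)
  set.seed(mc$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, mc$n)
  draws <- matrix(NA_real_, nrow(point), mc$n)
  for (k in seq_len(mc$n)) {
    set.seed(iter_seeds[k])
    res_k <- run_scenario(perturb_model(model, mc), scn, econ)
    draws[, k] <- res_k$value
  }
  qs <- apply(draws, 1L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  data.frame(
    scenario = point$scenario, disease = point$disease, sex = point$sex,
    outcome = point$outcome, point = point$value,
    lo95 = qs[1L, ], hi95 = qs[2L, ], mc_mean = rowMeans(draws),
    n_iterations = mc$n
  )
}

#' Discount-rate and horizon sensitivity analysis
#'
#' Reruns a scenario over discount rates 0, 1.5 and 3 percent and horizons
#' of 10 years, 50 years and lifetime, and reports each horizon's share of
#' the lifetime total at the same rate.
#'
#' @param model Prepared model.
#' @param scn A [scenario()].
#' @param rates Discount rates (default `c(0, 0.015, 0.03)`).
#' @param horizons Horizons (default `list(10, 50, "lifetime")`).
#' @return Long data frame with `discount_rate`, `horizon`, result columns
#'   of [run_scenario()], and `share_of_lifetime`.
#' @export
sensitivity_suite <- function(model, scn, rates = c(0, 0.015, 0.03),
                              horizons = list(10, 50, "lifetime")) {
  out <- list()
  for (r in rates) {
    per_h <- list()
    for (h in horizons) {
      res <- run_scenario(model, scn, econ_settings(r, h))
      res$discount_rate <- r
      res$horizon <- if (identical(h, "lifetime")) "lifetime" else
        as.character(h)
      per_h[[length(per_h) + 1L]] <- res
    }
    life <- per_h[[length(per_h)]]
    for (k in seq_along(per_h)) {
      per_h[[k]]$share_of_lifetime <-
        ifelse(life$value != 0, per_h[[k]]$value / life$value, NA_real_)
    }
    out <- c(out, per_h)
  }
  do.call(rbind, out)
}

#' Write a results table as CSV with a metadata JSON
#'
#' @param results Data frame from [run_scenario()], [monte_carlo()] or
#'   [sensitivity_suite()].
#' @param path CSV output path.
#' @param meta Optional named list of run metadata (settings, seed); written
#'   alongside as `<path>.meta.json`.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(results, path, meta = NULL) {
  utils::write.csv(results, path, row.names = FALSE)
  if (!is.null(meta)) {
    meta$package_version <- as.character(utils::packageVersion("pmsalt"))
    meta$r_version <- R.version.string
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
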