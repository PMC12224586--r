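# Counterfactual sodium scenarios and the sodium -> SBP -> relative risk
# pathway. A scenario shifts each DRI group's mean intake (to a target
# level, by an absolute delta, or proportionally); the intake change maps
# linearly to a systolic blood pressure change, and relative risk is
# log-linear in SBP (a constant RR per 20 mmHg within age bands). The
# potential impact fraction (PIF) on incidence defaults to the mean-shift
# form 1 - rr20^(dSBP/20).

#' Sodium reduction required to meet a recommendation
#'
#' @param baseline_mean Baseline mean intake, mg/day (> 0).
#' @param recommendation Recommended intake level, mg/day.
#' @return `max(0, baseline_mean - recommendation)` in mg/day.
#' @export
required_reduction <- function(baseline_mean, recommendation) {
  if (any(baseline_mean <= 0)) stop("baseline must be positive")
  pmax(0, baseline_mean - recommendation)
}

#' Convert a sodium change to its salt equivalent
#'
#' Uses the conventional factor of 2.5 g salt per g sodium; reported at two
#' decimals.
#'
#' @param delta_sodium Sodium change, mg/day (>= 0).
#' @param salt_factor Grams of salt per gram of sodium (default 2.5).
#' @return Salt change in g/day, rounded to 2 decimals.
#' @export
sodium_to_salt <- function(delta_sodium, salt_factor = 2.5) {
  if (any(delta_sodium < 0)) stop("delta must be non-negative")
  round(delta_sodium * salt_factor / 1000, 2)
}

#' Relative sodium reduction in percent
#'
#' @param delta Reduction, mg/day.
#' @param baseline Baseline mean, mg/day (> 0).
#' @return `100 * delta / baseline`.
#' @export
percent_reduction <- function(delta, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * delta / baseline
}

#' Construct a sodium counterfactual scenario
#'
#' @param id Scenario identifier (e.g. "S1").
#' @param kind One of `"target_level"` (mg/day ceiling), `"absolute_delta"`
#'   (mg/day reduction) or `"proportional"` (fraction in `[0, 1]`).
#' @param param Scalar parameter, or a vector named by `sex.group` DRI keys
#'   for group-specific effects.
#' @param label Human-readable description.
#' @return Object of class `sodium_scenario`.
#' @export
scenario <- function(id, kind = c("target_level", "absolute_delta",
                                  "proportional"),
                     param, label = id) {
  kind <- match.arg(kind)
  if (kind == "target_level" && any(param <= 0)) stop("target must be > 0")
  if (kind == "absolute_delta" && any(param < 0)) stop("delta must be >= 0")
  if (kind == "proportional" && any(param < 0 | param > 1)) {
    stop("fraction must lie in [0, 1]")
  }
  structure(list(id = id, kind = kind, param = param, label = label),
            class = "sodium_scenario")
}

#' The ten default sodium-reduction scenarios
#'
#' S1/S2 cap intakes at the Adequate Intake (1,500 mg/day) and WHO
#' (2,000 mg/day) recommendations; S3 is the packaged-food reformulation
#' delta (459 mg/day, reaching roughly the 2,300 mg/day national target);
#' S4-S6 are proportional purchase-shift effects of 'high in'
#' front-of-package labelling (4.7%, 6.4%, 7.8%); S7-S10 are food
#' substitution deltas (73, 131, 182, 259 mg/day) for 30/50/70/100% of
#' adult consumers.
#'
#' @return Named list of [scenario()] objects S1..S10.
#' @export
default_scenarios <- function() {
  list(
    S1 = scenario("S1", "target_level", 1500,
                  "Meeting AI sodium intake recommendations (1,500 mg/day)"),
    S2 = scenario("S2", "target_level", 2000,
                  "Meeting WHO sodium intake recommendations (2,000 mg/day)"),
    S3 = scenario("S3", "absolute_delta", 459,
                  "Sodium reduction targets for packaged foods (2,300 mg/day)"),
    S4 = scenario("S4", "proportional", 0.047,
                  "FOPL: changes in food & beverage purchases (Chilean experience)"),
    S5 = scenario("S5", "proportional", 0.064,
                  "FOPL: WHO cost-effectiveness criteria"),
    S6 = scenario("S6", "proportional", 0.078,
                  "FOPL: systematic review and network meta-analysis"),
    S7 = scenario("S7", "absolute_delta", 73,
                  "FOPL: food substitution, 30% of adult consumers"),
    S8 = scenario("S8", "absolute_delta", 131,
                  "FOPL: food substitution, 50% of adult consumers"),
    S9 = scenario("S9", "absolute_delta", 182,
                  "FOPL: food substitution, 70% of adult consumers"),
    S10 = scenario("S10", "absolute_delta", 259,
                   "FOPL: food substitution, all adult consumers")
  )
}

#' Read scenarios from a YAML configuration file
#'
#' The file layout matches the shipped default
#' (`system.file("extdata", "scenarios.yaml", package = "pmsalt")`): a
#' `scenarios` list of entries with `id`, `kind`, `param` (scalar or a
#' mapping keyed by `sex.group`) and `label`.
#'
#' @param path Path to a YAML file; defaults to the shipped scenario set.
#' @return Named list of [scenario()] objects.
#' @export
read_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                              package = "pmsalt")) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read scenario files")
  }
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$scenarios, function(e) {
    par <- e$param
    if (is.list(par)) par <- unlist(par)
    scenario(e$id, e$kind, par, e$label %||% e$id)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The null (business-as-usual) scenario
#' @return A zero-delta [scenario()].
#' @export
null_scenario <- function() {
  scenario("S0", "absolute_delta", 0, "Baseline (no intervention)")
}

#' Apply a scenario to DRI-group sodium intakes
#'
#' Interventions are one-sided: a target level never raises an intake, a
#' delta never drives it negative.
#'
#' @param intakes Data frame from [generate_sodium_intakes()].
#' @param scn A [scenario()].
#' @return The intakes data frame with counterfactual `mean_mg_day` and an
#'   added `delta_mg_day` column.
#' @export
apply_scenario <- function(intakes, scn) {
  stopifnot(inherits(scn, "sodium_scenario"))
  key <- paste(intakes$sex, intakes$group, sep = ".")
  par <- if (length(scn$param) == 1L) {
    rep(scn$param, nrow(intakes))
  } else {
    as.numeric(scn$param[key])
  }
  if (anyNA(par)) stop("scenario parameters missing for some DRI groups")
  old <- intakes$mean_mg_day
  new <- switch(scn$kind,
    target_level = pmin(old, par),
    absolute_delta = pmax(0, old - par),
    proportional = old * (1 - par),
    stop("unknown scenario kind")
  )
  out <- intakes
  out$mean_mg_day <- new
  out$delta_mg_day <- old - new
  out
}

#' SBP change from a sodium change
#'
#' Linear dose-response: `dSBP = -slope * delta_sodium / 1000` mmHg, with
#' `slope` in mmHg per 1,000 mg/day sodium.
#'
#' @param delta_sodium Sodium reduction, mg/day (>= 0).
#' @param slope Dose-response slope, mmHg per 1,000 mg/day (>= 0).
#' @return SBP change in mmHg (<= 0).
#' @export
sbp_shift <- function(delta_sodium, slope) {
  if (any(delta_sodium < 0)) stop("delta must be non-negative")
  if (any(slope < 0)) stop("slope must be non-negative")
  -slope * delta_sodium / 1000
}

#' Incidence rate ratio from an SBP change
#'
#' Log-linear risk: `rr20^(dSBP / 20)`, below 1 for SBP reductions.
#'
#' @param delta_sbp SBP change, mmHg.
#' @param rr20 Relative risk per 20 mmHg SBP (>= 1).
#' @return Rate ratio.
#' @export
rr_multiplier <- function(delta_sbp, rr20) {
  if (any(rr20 < 1)) stop("rr20 must be >= 1")
  rr20^(delta_sbp / 20)
}

#' Potential impact fraction
#'
#' Mean-shift mode (default): `1 - rr20^(dSBP/20)` for the mean SBP change
#' implied by the mean intake change. Distributional mode evaluates
#' `1 - sum(w * RR(x')) / sum(w * RR(x))` over a discretised intake
#' distribution with weights `w` summing to 1; under the log-linear RR a
#' uniform shift of every support point reduces exactly to the mean-shift
#' form.
#'
#' @param delta_sodium Mean sodium reduction, mg/day (mean-shift mode).
#' @param slope SBP slope, mmHg per 1,000 mg/day.
#' @param rr20 Relative risk per 20 mmHg (>= 1).
#' @param x,x_cf,w Optional intake support points, counterfactual support
#'   and weights for distributional mode.
#' @return PIF in `(-Inf, 1]`.
#' @export
pif <- function(delta_sodium = NULL, slope, rr20,
                x = NULL, x_cf = NULL, w = NULL) {
  if (!is.null(x)) {
    stopifnot(!is.null(x_cf), !is.null(w), length(x) == length(x_cf),
              length(x) == length(w))
    if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
    # log-linear RR relative to an arbitrary reference cancels in the ratio
    rr_base <- rr20^((slope * x / 1000) / 20)
    rr_cf <- rr20^((slope * x_cf / 1000) / 20)
    return(1 - sum(w * rr_cf) / sum(w * rr_base))
  }
  1 - rr_multiplier(sbp_shift(delta_sodium, slope), rr20)
}

#' Default sodium-effect model
#'
#' Illustrative, non-authoritative defaults: a linear sodium-to-SBP slope
#' by age band (mmHg per 1,000 mg/day, both sexes) and relative risks per
#' 20 mmHg SBP by age band and disease, declining with age as in the
#' blood-pressure meta-analytic literature.
#'
#' @return List with `slope_bands` (age_lo, age_hi, value), `rr20_bands`
#'   (per-disease data frames) and `salt_factor` (2.5).
#' @export
default_effect_model <- function() {
  list(
    slope_bands = data.frame(
      age_lo = c(0L, 40L, 60L), age_hi = c(39L, 59L, 100L),
      value = c(1.0, 1.5, 2.0)
    ),
    rr20_bands = list(
      ihd = data.frame(
        age_lo = c(0L, 50L, 60L, 70L, 80L),
        age_hi = c(49L, 59L, 69L, 79L, 100L),
        value = c(1.90, 1.70, 1.50, 1.35, 1.20)
      ),
      stroke = data.frame(
        age_lo = c(0L, 50L, 60L, 70L, 80L),
        age_hi = c(49L, 59L, 69L, 79L, 100L),
        value = c(2.50, 2.00, 1.70, 1.45, 1.25)
      )
    ),
    salt_factor = 2.5
  )
}

#' Potential impact fractions by age, sex and disease
#'
#' Applies a scenario to the DRI-group intakes, maps each group's mean
#' sodium reduction to an SBP change with the age-banded slope, and
#' converts it to a PIF per disease with the age-banded RR per 20 mmHg.
#' Ages below 19 receive no intervention (PIF 0).
#'
#' @param intakes DRI-group intakes from [generate_sodium_intakes()].
#' @param scn A [scenario()].
#' @param effect Effect model from [default_effect_model()].
#' @return List of 101 x 2 PIF grids, one per disease.
#' @export
pif_table <- function(intakes, scn, effect = default_effect_model()) {
  cf <- apply_scenario(intakes, scn)
  ages <- model_ages()
  slope <- expand_bands(effect$slope_bands, ages)
  delta <- age_sex_grid(0)
  for (k in seq_len(nrow(cf))) {
    sel <- ages >= cf$age_lo[k] & ages <= cf$age_hi[k]
    delta[sel, cf$sex[k]] <- cf$delta_mg_day[k]
  }
  out <- list()
  for (d in names(effect$rr20_bands)) {
    rr20 <- expand_bands(effect$rr20_bands[[d]], ages)
    g <- age_sex_grid(0)
    for (s in model_sexes()) {
      g[, s] <- 1 - rr_multiplier(sbp_shift(delta[, s], slope), rr20)
    }
    out[[d]] <- g
  }
  out
}
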