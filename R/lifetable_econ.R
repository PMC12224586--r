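# Proportional multi-state lifetable and economics: disease-model outputs
# are combined into survivorship, life-years, QALYs and discounted
# healthcare costs. The counterfactual lifetable subtracts the change in
# disease-specific mortality from all-cause mortality; QALYs weight
# life-years by a background utility and multiplicative prevalence-weighted
# disease decrements; costs accrue per prevalent case-year.

#' Present-value discount factor
#'
#' @param t Years from the reference time (>= 0).
#' @param rate Annual discount rate (>= 0; default 0.015).
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(t, rate = 0.015) {
  if (any(t < 0)) stop("t must be non-negative")
  if (any(rate < 0)) stop("rate must be non-negative")
  (1 + rate)^(-t)
}

#' Economic settings
#'
#' @param discount_rate Annual discount rate (default 0.015; sensitivity
#'   values 0 and 0.03).
#' @param horizon Simulation horizon in years: a number (e.g. 10, 50) or
#'   `"lifetime"`.
#' @param currency_year Currency reference year (2019).
#' @return List of settings.
#' @export
econ_settings <- function(discount_rate = 0.015, horizon = "lifetime",
                          currency_year = 2019) {
  if (discount_rate < 0) stop("discount rate must be non-negative")
  if (!identical(horizon, "lifetime")) {
    horizon <- as.numeric(horizon)
    if (horizon <= 0) stop("horizon must be positive")
  }
  list(discount_rate = discount_rate, horizon = horizon,
       currency_year = currency_year)
}

#' Adjust all-cause mortality for changed disease mortality
#'
#' `m'(a) = max(0, m(a) - sum_d [mx_base_d(a) - mx_scen_d(a)])`; the
#' baseline lifetable uses `m` unchanged.
#'
#' @param m All-cause mortality rate vector.
#' @param mx_base,mx_scen Lists (per disease) of baseline and scenario
#'   disease-specific mortality rate vectors on the same grid.
#' @return Adjusted mortality vector, clamped at 0.
#' @export
adjusted_mortality <- function(m, mx_base, mx_scen) {
  stopifnot(identical(names(mx_base), names(mx_scen)))
  red <- 0
  for (d in names(mx_base)) red <- red + (mx_base[[d]] - mx_scen[[d]])
  pmax(0, m - red)
}

#' Build a cohort lifetable
#'
#' `l(a+1) = l(a) * (1 - q(a))` with `q = 1 - exp(-m)`; life-years by the
#' trapezoid rule, `L(a) = (l(a) + l(a+1)) / 2`.
#'
#' @param n0 Cohort size at the starting age (> 0).
#' @param m Mortality rate vector, one value per simulated year.
#' @return List with `l` (survivors at the start of each year, length
#'   `length(m) + 1`) and `L` (life-years lived in each year).
#' @export
build_lifetable <- function(n0, m) {
  if (n0 <= 0) stop("cohort size must be positive")
  q <- 1 - exp(-m)
  l <- n0 * cumprod(c(1, 1 - q))
  L <- (l[-length(l)] + l[-1L]) / 2
  list(l = l, L = L)
}

#' Combined QALY weight for a year of life
#'
#' Background utility times multiplicative prevalence-weighted disease
#' decrements: `w = w_bg * prod_d (1 - prev_d * dec_d)` (additive variant
#' available).
#'
#' @param w_bg Background utility (in `[0, 1]`).
#' @param prev List or vector of disease prevalence proportions.
#' @param dec Matching disease utility decrements (in `[0, 1]`).
#' @param combine `"multiplicative"` (default) or `"additive"`.
#' @return QALY weight(s).
#' @export
qaly_weight <- function(w_bg, prev, dec, combine = c("multiplicative",
                                                     "additive")) {
  combine <- match.arg(combine)
  if (any(unlist(dec) > 1) || any(unlist(dec) < 0)) {
    stop("decrements must lie in [0, 1]")
  }
  prev <- as.list(prev)
  if (combine == "multiplicative") {
    w <- w_bg
    for (k in seq_along(prev)) w <- w * (1 - prev[[k]] * dec[[k]])
    w
  } else {
    loss <- 0
    for (k in seq_along(prev)) loss <- loss + prev[[k]] * dec[[k]]
    pmax(0, w_bg - loss)
  }
}

#' Cost per prevalent case
#'
#' @param total_cost Total direct cost (CAD/year) per stratum.
#' @param prevalent_cases Prevalent cases per stratum (> 0 where costs are
#'   nonzero).
#' @return Elementwise `total_cost / prevalent_cases` (0 where both are 0).
#' @export
cost_per_case <- function(total_cost, prevalent_cases) {
  if (any(prevalent_cases == 0 & total_cost > 0)) {
    stop("nonzero cost with zero prevalent cases")
  }
  ifelse(prevalent_cases > 0, total_cost / prevalent_cases, 0)
}

#' Allocate unattributable costs across diseases
#'
#' Each disease receives a share of the unattributable total proportional
#' to its share of attributable costs within the stratum; the allocation
#' conserves the total exactly.
#'
#' @param attributable Named list or data frame column set of attributable
#'   costs per disease (same strata).
#' @param unattributable_total Unattributable total per stratum.
#' @return Named list of additions per disease.
#' @export
allocate_unattributable <- function(attributable, unattributable_total) {
  attributable <- as.list(attributable)
  tot <- Reduce(`+`, attributable)
  if (any(tot == 0 & unattributable_total > 0)) {
    stop("all-zero attributable costs with nonzero unattributable total")
  }
  lapply(attributable, function(a) {
    ifelse(tot > 0, a / tot, 0) * unattributable_total
  })
}

#' Inflate costs to the reference currency year
#'
#' @param cost Cost in source-year currency.
#' @param cpi_factor Inflation factor (> 0).
#' @return `cost * cpi_factor`.
#' @export
inflate <- function(cost, cpi_factor) {
  if (any(cpi_factor <= 0)) stop("cpi factor must be positive")
  cost * cpi_factor
}

#' Discounted healthcare savings from reduced prevalence
#'
#' `sum_t disc(t) * cost_per_case(a_t) * (cases_base(t) - cases_scen(t))`,
#' with the year-`t` stream valued at the year-end factor
#' `(1 + r)^-(t + 1)` (`t` 0-based).
#'
#' @param cases_base,cases_scen Aligned prevalent-case-year vectors by
#'   simulation year.
#' @param cost Per-case annual cost vector aligned with the years.
#' @param rate Discount rate.
#' @return Discounted savings (positive when the scenario has fewer cases).
#' @export
healthcare_savings <- function(cases_base, cases_scen, cost, rate = 0.015) {
  if (length(cases_base) != length(cases_scen)) {
    stop("trajectories are not aligned")
  }
  t <- seq_along(cases_base) - 1L
  sum(discount_factor(t + 1L, rate) * cost * (cases_base - cases_scen))
}
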