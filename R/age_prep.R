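# Conversion of source-granularity tables (5-year age groups, coarse
# survey/cost bands) to the 1-year 0-100 grid the lifetable requires.
#
# Counts are disaggregated by monotone cubic interpolation of the cumulative
# sum (Hyman-filtered spline), which guarantees non-negative 1-year values
# and exact preservation of every group total. Rates beyond the last
# observed group (90+) are extrapolated with a polynomial trend fitted to
# the oldest group midpoints.

#' Validate a grouped age series
#'
#' A grouped series is a data frame with columns `age_lo`, `age_hi`
#' (inclusive integer bounds) and `value`. Groups must be contiguous,
#' non-overlapping, ascending, with non-negative values.
#'
#' @param groups Data frame with columns `age_lo`, `age_hi`, `value`.
#' @return The validated data frame (invisibly usable).
#' @export
grouped_series <- function(groups) {
  stopifnot(all(c("age_lo", "age_hi", "value") %in% names(groups)))
  groups <- groups[order(groups$age_lo), , drop = FALSE]
  if (any(groups$age_hi < groups$age_lo)) {
    stop("group with age_hi < age_lo")
  }
  if (nrow(groups) > 1L) {
    gap <- groups$age_lo[-1L] - groups$age_hi[-nrow(groups)]
    if (any(gap != 1L)) stop("groups must be contiguous and non-overlapping")
  }
  if (any(groups$value < 0)) stop("group values must be non-negative")
  groups
}

#' Disaggregate grouped counts to 1-year values
#'
#' Interpolates the cumulative count at group boundaries with a monotone
#' cubic spline (`stats::splinefun(method = "hyman")`) and differences it at
#' integer ages. Monotonicity of the cumulative guarantees non-negative
#' 1-year counts; interpolation through the knots preserves each group
#' total exactly.
#'
#' @param groups A grouped series of counts (see [grouped_series()]).
#' @return Data frame with columns `age`, `value`, one row per 1-year age
#'   spanned by the groups.
#' @export
disaggregate_counts <- function(groups) {
  groups <- grouped_series(groups)
  # boundaries between integer ages: group (lo, hi) spans [lo, hi + 1)
  knots_x <- c(groups$age_lo[1L], groups$age_hi + 1L)
  knots_y <- c(0, cumsum(groups$value))
  ages <- seq.int(groups$age_lo[1L], groups$age_hi[nrow(groups)])
  if (nrow(groups) < 3L) {
    # too few knots for a cubic: linear interpolation (uniform within group)
    cum <- stats::approx(knots_x, knots_y, xout = c(ages, max(ages) + 1L))$y
  } else {
    fn <- stats::splinefun(knots_x, knots_y, method = "hyman")
    cum <- fn(c(ages, max(ages) + 1L))
  }
  vals <- diff(cum)
  vals[vals < 0 & vals > -1e-12] <- 0  # guard tiny negative round-off
  data.frame(age = ages, value = vals)
}

#' Disaggregate grouped rates to 1-year values
#'
#' Rates are converted to counts with a 1-year population grid, the counts
#' disaggregated with [disaggregate_counts()], and the result divided by the
#' 1-year population, so that smooth disaggregated counts (not rates) are
#' what is conserved within each group.
#'
#' @param groups Grouped series of rates.
#' @param pop_1y Numeric vector of population counts indexed by age 0..100.
#' @param rate_cap Upper clamp for the resulting rates (default 1).
#' @return Data frame with columns `age`, `value`.
#' @export
disaggregate_rates <- function(groups, pop_1y, rate_cap = 1) {
  groups <- grouped_series(groups)
  ages_all <- model_ages()
  grp_pop <- vapply(seq_len(nrow(groups)), function(k) {
    sum(pop_1y[ages_all >= groups$age_lo[k] & ages_all <= groups$age_hi[k]])
  }, numeric(1))
  counts <- groups
  counts$value <- groups$value * grp_pop
  dis <- disaggregate_counts(counts)
  denom <- pop_1y[match(dis$age, ages_all)]
  dis$value <- ifelse(denom > 0, dis$value / denom, 0)
  dis$value <- pmin(pmax(dis$value, 0), rate_cap)
  dis
}

#' Extrapolate rates beyond the last observed age group
#'
#' Fits a polynomial trend of order `poly_order` to the rate at the oldest
#' `n_fit` group midpoints and evaluates it at ages `from` to `max_age`.
#' Open-ended terminal groups are assigned midpoint `age_lo + 2.5`.
#' Predictions are clamped to `[0, rate_cap]`.
#'
#' @param groups Grouped series of rates (the source, e.g. 5-year groups to
#'   90+).
#' @param from First age to extrapolate (default 91).
#' @param max_age Last age (default 100).
#' @param poly_order Polynomial order, one of 1, 2, 3 (default 2).
#' @param n_fit Number of oldest groups used for the fit (default 6).
#' @param rate_cap Upper clamp (default 1).
#' @return Data frame with columns `age`, `value` for ages `from..max_age`.
#' @export
extrapolate_rates <- function(groups, from = 91, max_age = 100,
                              poly_order = 2, n_fit = 6, rate_cap = 1) {
  groups <- grouped_series(groups)
  stopifnot(poly_order %in% 1:3)
  n <- nrow(groups)
  use <- groups[seq.int(max(1L, n - n_fit + 1L), n), , drop = FALSE]
  if (nrow(use) < poly_order + 1L) {
    stop("insufficient groups for polynomial order ", poly_order)
  }
  mid <- ifelse(
    use$age_hi - use$age_lo >= 10,       # open-ended terminal group
    use$age_lo + 2.5,
    (use$age_lo + use$age_hi) / 2
  )
  fit <- stats::lm(value ~ stats::poly(mid, poly_order, raw = TRUE),
                   data = data.frame(mid = mid, value = use$value))
  ages <- seq.int(from, max_age)
  pred <- stats::predict(fit, newdata = data.frame(mid = ages))
  data.frame(age = ages, value = pmin(pmax(as.numeric(pred), 0), rate_cap))
}

#' Expand banded values to 1-year ages (piecewise constant)
#'
#' Each 1-year age receives the value of the band containing it; the lower
#' band edge is inclusive. Errors if any requested age is uncovered.
#'
#' @param bands Data frame with columns `age_lo`, `age_hi`, `value`.
#' @param ages Integer ages to fill (default 0..100).
#' @return Numeric vector of `length(ages)` values.
#' @export
expand_bands <- function(bands, ages = model_ages()) {
  stopifnot(all(c("age_lo", "age_hi", "value") %in% names(bands)))
  out <- rep(NA_real_, length(ages))
  for (k in seq_len(nrow(bands))) {
    sel <- ages >= bands$age_lo[k] & ages <= bands$age_hi[k]
    out[sel] <- bands$value[k]
  }
  if (anyNA(out)) {
    stop("ages not covered by bands: ",
         paste(ages[is.na(out)], collapse = ", "))
  }
  out
}

#' Build a full 1-year rate grid from source-granularity epidemiology
#'
#' Combines rate disaggregation over the observed groups with polynomial
#' extrapolation to `max_age`, and fills ages below the first group with
#' zero (diseases of adulthood).
#'
#' @inheritParams disaggregate_rates
#' @inheritParams extrapolate_rates
#' @return Numeric vector indexed by age 0..100.
#' @export
rates_to_1y <- function(groups, pop_1y, poly_order = 2, n_fit = 6,
                        rate_cap = 1) {
  groups <- grouped_series(groups)
  out <- numeric(101L)
  n <- nrow(groups)
  open_last <- (groups$age_hi[n] - groups$age_lo[n]) > 10
  closed <- if (open_last) groups[-n, , drop = FALSE] else groups
  dis <- disaggregate_rates(closed, pop_1y, rate_cap = rate_cap)
  out[dis$age + 1L] <- dis$value
  last <- closed$age_hi[nrow(closed)]
  if (last < 100) {
    ext <- extrapolate_rates(groups, from = last + 1L, max_age = 100,
                             poly_order = poly_order, n_fit = n_fit,
                             rate_cap = rate_cap)
    out[ext$age + 1L] <- ext$value
  }
  out
}
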