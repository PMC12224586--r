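# Age-grid preparation: counts-conserving disaggregation, exact polynomial
# extrapolation, piecewise-constant band expansion.

test_that("count disaggregation conserves every group total exactly", {
  groups <- data.frame(age_lo = seq(0L, 85L, 5L), age_hi = seq(4L, 89L, 5L),
                       value = c(500, 480, 510, 530, 560, 540, 520, 490,
                                 460, 430, 390, 340, 280, 210, 150, 90,
                                 40, 12))
  dis <- disaggregate_counts(groups)
  expect_true(all(dis$value >= 0))
  for (k in seq_len(nrow(groups))) {
    sel <- dis$age >= groups$age_lo[k] & dis$age <= groups$age_hi[k]
    expect_lt(abs(sum(dis$value[sel]) - groups$value[k]), 1e-9)
  }
})

test_that("uniform grouped counts disaggregate to the uniform value", {
  groups <- data.frame(age_lo = seq(0L, 20L, 5L), age_hi = seq(4L, 24L, 5L),
                       value = 500)
  dis <- disaggregate_counts(groups)
  expect_equal(dis$value, rep(100, 25), tolerance = 1e-9)
})

test_that("increasing group totals give increasing 1-year values", {
  groups <- data.frame(age_lo = c(0L, 5L, 10L), age_hi = c(4L, 9L, 14L),
                       value = c(100, 200, 300))
  dis <- disaggregate_counts(groups)
  expect_true(all(diff(dis$value) > 0))
  expect_equal(sum(dis$value[dis$age <= 4]), 100, tolerance = 1e-9)
  expect_equal(sum(dis$value[dis$age >= 10]), 300, tolerance = 1e-9)
})

test_that("malformed group series are rejected", {
  expect_error(grouped_series(data.frame(age_lo = c(0L, 4L),
                                         age_hi = c(4L, 9L),
                                         value = c(1, 1))),
               "contiguous")
  expect_error(grouped_series(data.frame(age_lo = c(0L, 6L),
                                         age_hi = c(4L, 9L),
                                         value = c(1, 1))),
               "contiguous")
  expect_error(grouped_series(data.frame(age_lo = 0L, age_hi = 4L,
                                         value = -1)),
               "non-negative")
})

test_that("rate extrapolation is exact for polynomial inputs", {
  lo <- seq(60L, 85L, 5L)
  groups <- function(f) data.frame(age_lo = lo, age_hi = lo + 4L,
                                   value = f((lo + lo + 4) / 2))
  # constant
  ext <- extrapolate_rates(groups(function(a) rep(0.05, length(a))),
                           poly_order = 2)
  expect_equal(ext$value, rep(0.05, 10), tolerance = 1e-9)
  # linear, order 1: r(a) = 0.001 a -> r(100) = 0.1
  ext <- extrapolate_rates(groups(function(a) 0.001 * a), poly_order = 1)
  expect_equal(ext$value[ext$age == 100], 0.1, tolerance = 1e-9)
  # quadratic, order 2: r(a) = 1e-5 a^2 -> r(95) = 0.09025
  ext <- extrapolate_rates(groups(function(a) 1e-5 * a^2), poly_order = 2)
  expect_equal(ext$value[ext$age == 95], 0.09025, tolerance = 1e-9)
  expect_error(extrapolate_rates(groups(function(a) a)[1:2, ],
                                 poly_order = 3),
               "insufficient")
})

test_that("open-ended terminal groups use the lo + 2.5 midpoint", {
  lo <- c(seq(60L, 85L, 5L), 90L)
  hi <- c(seq(64L, 89L, 5L), 100L)
  # linear rate in the midpoint convention: closed groups at (lo+hi)/2,
  # open group at 92.5
  mids <- c((seq(60L, 85L, 5L) + seq(64L, 89L, 5L)) / 2, 92.5)
  groups <- data.frame(age_lo = lo, age_hi = hi, value = 0.002 * mids)
  ext <- extrapolate_rates(groups, poly_order = 1)
  expect_equal(ext$value, 0.002 * (91:100), tolerance = 1e-9)
})

test_that("band expansion is piecewise constant with inclusive lower edges", {
  bands <- data.frame(age_lo = c(0L, 50L), age_hi = c(49L, 100L),
                      value = c(1, 2))
  v <- expand_bands(bands)
  expect_equal(v[50], 1)   # age 49
  expect_equal(v[51], 2)   # age 50
  one <- data.frame(age_lo = 0L, age_hi = 100L, value = 7)
  expect_equal(expand_bands(one), rep(7, 101))
  cost <- data.frame(age_lo = 65L, age_hi = 74L, value = 5000)
  expect_equal(expand_bands(cost, ages = 70L), 5000)
  expect_error(expand_bands(bands[2, , drop = FALSE]), "not covered")
})

test_that("rate disaggregation conserves counts and clamps to [0, cap]", {
  pop <- rep(1000, 101)
  groups <- data.frame(age_lo = c(20L, 25L), age_hi = c(24L, 29L),
                       value = c(0.01, 0.02))
  dis <- disaggregate_rates(groups, pop)
  expect_equal(sum(dis$value[dis$age <= 24] * 1000), 0.01 * 5000,
               tolerance = 1e-9)
  expect_true(all(dis$value >= 0 & dis$value <= 1))
})
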