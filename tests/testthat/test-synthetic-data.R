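# Synthetic-data generators: determinism, conservation, hazard shape,
# calibration and the consistency of forward-generated epidemiology with
# the three-state recursion.

test_that("population generation conserves the total and is seeded", {
  p1 <- generate_population(seed = 3L, total_size = 1e5)
  p2 <- generate_population(seed = 3L, total_size = 1e5)
  p3 <- generate_population(seed = 4L, total_size = 1e5)
  expect_identical(p1, p2)
  expect_false(identical(p1$population, p3$population))
  expect_equal(sum(p1$population), 1e5)
  expect_true(all(p1$population >= 0))
  expect_true(all(p1$all_cause_mortality >= 0 &
                    p1$all_cause_mortality <= 1))
})

test_that("Gompertz-Makeham hazard has the stated form", {
  # degenerate: beta = 0 gives a flat hazard alpha
  flat <- generate_population(seed = 1L, total_size = 1e4,
                              gompertz = list(alpha = 0.001, beta = 0,
                                              gamma = 0.1))
  expect_true(all(flat$all_cause_mortality == 0.001))
  # pure Gompertz: m(80)/m(40) = exp(gamma * 40)
  g <- generate_population(seed = 1L, total_size = 1e4,
                           gompertz = list(alpha = 0, beta = 1e-5,
                                           gamma = 0.09))
  m <- g$all_cause_mortality[, "male"]
  expect_equal(unname(m[81] / m[41]), exp(0.09 * 40), tolerance = 1e-12)
  expect_error(generate_population(total_size = 0), "positive")
})

test_that("degenerate disease parameters give degenerate epidemiology", {
  pars <- default_epi_params()
  pars$ihd$f35 <- 0          # no case fatality -> no cause deaths
  pars$stroke$i35 <- 0       # no incidence -> no prevalence
  epi <- generate_disease_epi(seed = 1L, params = pars)
  expect_true(all(epi$ihd$cause_mortality == 0))
  expect_true(all(epi$stroke$prevalence == 0))
})

test_that("forward-generated epidemiology matches a brute-force recursion", {
  # constant i = 0.01, f = 0.2 from age 0; hand recursion independent of
  # the package step function
  pars <- list(dz = list(i35 = 0.01, i_growth = 0, onset_age = 0L,
                         f35 = 0.2, f_growth = 0,
                         sex_mult = c(male = 1, female = 1), remission = 0))
  epi <- generate_disease_epi(seed = 1L, params = pars)
  qi <- 1 - exp(-0.01); qf <- 1 - exp(-0.2)
  S <- 1; C <- 0; prev_hand <- numeric(101)
  for (a in 0:99) {
    prev_hand[a + 1] <- C / (S + C)
    new <- S * qi; dd <- C * qf
    S <- S - new; C <- C + new - dd
  }
  prev_hand[101] <- C / (S + C)
  expect_equal(epi$dz$prevalence[, "male"], unname(prev_hand),
               tolerance = 1e-12, ignore_attr = TRUE)
  # long-run level approaches the discrete steady state q_i / q_f (the
  # fixed point of x' = (x(1-q_f) + q_i) / (1-q_i) for x = C/S)
  expect_equal(prev_hand[101], qi / qf, tolerance = 0.01)
})

test_that("generated triples satisfy the three-state recursion with true f", {
  raw <- test_raw()
  for (d in raw$epi$diseases) {
    for (s in model_sexes()) {
      fwd <- run_disease_cohort(raw$epi[[d]]$incidence[, s],
                                raw$epi[[d]]$case_fatality_true[, s], 0, 0)
      alive <- fwd$S + fwd$C
      expect_lt(max(abs(fwd$C / alive - raw$epi[[d]]$prevalence[, s])),
                1e-9)
    }
  }
})

test_that("sodium intakes are calibrated to the configured baseline mean", {
  raw <- test_raw()
  expect_equal(attr(raw$sodium, "weighted_mean"), 2758, tolerance = 1e-9)
  expect_equal(sum(raw$sodium$weight), 1, tolerance = 1e-12)
  expect_true(all(raw$sodium$mean_mg_day > 0))
  # explicit weights: weighted mean is sum(w * mean) without calibration
  w <- rep(1 / 8, 8)
  names(w) <- paste(dri_groups()$sex, dri_groups()$group, sep = ".")
  cfg <- default_sodium_config()
  cfg$target_mean <- NULL
  intk <- generate_sodium_intakes(seed = 1L, config = cfg, weights = w)
  expect_equal(attr(intk, "weighted_mean"), mean(cfg$means))
  bad <- w; bad[1] <- bad[1] + 0.1
  expect_error(generate_sodium_intakes(seed = 1L, config = cfg,
                                       weights = bad), "sum to 1")
})

test_that("SBP 80+ band carries the 60-79 value forward per sex", {
  sbp <- generate_sbp(seed = 1L)
  for (s in c("male", "female")) {
    v60 <- sbp$value[sbp$sex == s & sbp$age_lo == 60]
    v80 <- sbp$value[sbp$sex == s & sbp$age_lo == 80]
    expect_equal(v80, v60)
  }
  # missing 60-79 band errors
  bands <- default_sbp_bands()
  expect_error(generate_sbp(bands = bands[bands$age_lo != 60, ]),
               "missing 60-79 band")
  expect_identical(generate_sbp(seed = 5L), generate_sbp(seed = 5L))
})

test_that("cost and utility generation respects bounds and seeding", {
  raw <- test_raw()
  cu <- raw$costs
  expect_true(all(cu$attributable$value >= 0))
  expect_true(all(cu$unattributable$value >= 0))
  expect_true(all(cu$background_utility$value >= 0 &
                    cu$background_utility$value <= 1))
  expect_true(all(cu$disease_utility_decrement >= 0 &
                    cu$disease_utility_decrement <= 1))
  cfg <- default_cost_utility_config()
  cfg$background_utility[1] <- 1.2
  expect_error(generate_costs_utilities(1L, cfg, raw$population, raw$epi),
               "\\[0, 1\\]")
  cu2 <- generate_costs_utilities(raw$seed,
                                  population = raw$population,
                                  epi = raw$epi)
  expect_identical(cu, cu2)
})

test_that("input CSV round-trip writes every table", {
  dir <- withr::local_tempdir()
  files <- write_inputs_csv(test_raw(), dir)
  expect_true(all(file.exists(files)))
  pop <- utils::read.csv(file.path(dir, "population.csv"))
  expect_equal(sum(pop$value), sum(test_raw()$population$population))
  expect_setequal(names(pop), c("age", "sex", "value"))
})
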