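# Scenario arithmetic, the sodium -> SBP -> RR pathway and PIF properties.

test_that("required reductions and salt equivalents match the scenario set", {
  expect_equal(required_reduction(2758, 1500), 1258)
  expect_equal(required_reduction(2758, 2000), 758)
  expect_equal(required_reduction(1400, 1500), 0)
  expect_equal(sodium_to_salt(1258), 3.14)
  expect_equal(sodium_to_salt(212), 0.53)
  expect_equal(sodium_to_salt(0), 0)
  expect_equal(percent_reduction(459, 2758), 16.64, tolerance = 1e-3)
  expect_equal(round(percent_reduction(459, 2758)), 17)
  expect_equal(percent_reduction(0, 2758), 0)
  expect_equal(percent_reduction(1379, 2758), 50)
})

test_that("every default scenario reproduces its printed salt equivalent", {
  deltas <- c(S1 = 1258, S2 = 758, S3 = 459, S4 = 128, S5 = 174, S6 = 212,
              S7 = 73, S8 = 131, S9 = 182, S10 = 259)
  salts <- c(S1 = 3.14, S2 = 1.89, S3 = 1.15, S4 = 0.32, S5 = 0.44,
             S6 = 0.53, S7 = 0.18, S8 = 0.33, S9 = 0.45, S10 = 0.65)
  # published salt columns round exact .5 boundaries down (S2, S9), so
  # compare the unrounded conversion to half a reporting unit
  expect_true(all(abs(deltas * 2.5 / 1000 - salts) <= 0.005 + 1e-12))
  expect_equal(sodium_to_salt(deltas[["S1"]]), 3.14)
  expect_equal(sodium_to_salt(deltas[["S6"]]), 0.53)
  expect_equal(sodium_to_salt(deltas[["S4"]]), 0.32)
})

test_that("scenario application is one-sided per kind", {
  intakes <- test_raw()$sodium
  # proportional 4.7% on a 3000 mg/day group -> 2859
  intk <- intakes
  intk$mean_mg_day <- rep(3000, nrow(intk))
  prop <- apply_scenario(intk, scenario("X", "proportional", 0.047))
  expect_equal(prop$mean_mg_day, rep(2859, nrow(intk)))
  # zero delta leaves intakes unchanged
  nul <- apply_scenario(intakes, null_scenario())
  expect_equal(nul$mean_mg_day, intakes$mean_mg_day)
  expect_true(all(nul$delta_mg_day == 0))
  # target above the group mean never raises intake
  intk$mean_mg_day <- rep(2100, nrow(intk))
  tgt <- apply_scenario(intk, scenario("X", "target_level", 2300))
  expect_equal(tgt$mean_mg_day, rep(2100, nrow(intk)))
  expect_error(scenario("X", "proportional", 1.2), "\\[0, 1\\]")
})

test_that("SBP shift and RR multiplier follow their unit definitions", {
  expect_equal(sbp_shift(1000, 2.0), -2.0)
  expect_equal(sbp_shift(0, 2.0), 0)
  expect_equal(sbp_shift(500, 1.2), -0.6)
  expect_equal(rr_multiplier(-20, 2.0), 0.5)
  expect_equal(rr_multiplier(0, 1.7), 1.0)
  expect_equal(rr_multiplier(-10, 2.0), 2^(-0.5))
  expect_error(rr_multiplier(-10, 0.9), ">= 1")
})

test_that("PIF reduces to the mean-shift form and is null at baseline", {
  # rr20 = 1 -> PIF 0 regardless of shift
  expect_equal(pif(delta_sodium = 1000, slope = 2, rr20 = 1), 0)
  # dSBP = -20 at rr20 = 2 -> PIF 0.5
  expect_equal(pif(delta_sodium = 10000, slope = 2, rr20 = 2), 0.5)
  # distributional mode with a uniform shift equals mean-shift exactly
  x <- c(2000, 2800, 3600); w <- c(0.3, 0.4, 0.3)
  shift <- 459
  p_dist <- pif(slope = 1.5, rr20 = 1.8, x = x, x_cf = x - shift, w = w)
  p_mean <- pif(delta_sodium = shift, slope = 1.5, rr20 = 1.8)
  expect_equal(p_dist, p_mean, tolerance = 1e-12)
  expect_error(pif(slope = 1, rr20 = 1.5, x = x, x_cf = x, w = c(1, 1, 1)),
               "sum to 1")
})

test_that("PIF tables are zero below 19, bounded by 1 and monotone", {
  raw <- test_raw()
  eff <- default_effect_model()
  tabs <- lapply(default_scenarios(), function(s)
    pif_table(raw$sodium, s, eff))
  for (tab in tabs) {
    for (g in tab) {
      expect_true(all(g[model_ages() < 19, ] == 0))
      expect_true(all(g <= 1))
    }
  }
  # a uniformly larger reduction gives a pointwise no-smaller PIF
  for (delta in list(c(100, 459), c(459, 758), c(758, 1258))) {
    lo <- pif_table(raw$sodium,
                    scenario("lo", "absolute_delta", delta[1]), eff)$ihd
    hi <- pif_table(raw$sodium,
                    scenario("hi", "absolute_delta", delta[2]), eff)$ihd
    expect_true(all(hi - lo >= 0))
    adult <- model_ages() >= 19
    expect_true(all(hi[adult, ] - lo[adult, ] > 0))
  }
  # scenario ordering by overall delta (S7 < S4 < S8 < S5 < S9 < S6 <
  # S10 < S3 < S2 < S1) induces the same ordering of population-mean PIF
  adult <- model_ages() >= 19
  ord <- c("S7", "S4", "S8", "S5", "S9", "S6", "S10", "S3", "S2", "S1")
  pop <- raw$population$population[adult, ]
  means <- vapply(ord, function(id)
    sum(tabs[[id]]$ihd[adult, ] * pop) / sum(pop), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("scenario YAML round-trip matches the built-in defaults", {
  skip_if_not_installed("yaml")
  scns <- read_scenarios()
  expect_named(scns, paste0("S", 1:10))
  expect_equal(scns$S1$kind, "target_level")
  expect_equal(scns$S4$param, 0.047)
  defs <- default_scenarios()
  for (id in names(defs)) {
    expect_equal(scns[[id]]$kind, defs[[id]]$kind)
    expect_equal(scns[[id]]$param, defs[[id]]$param)
  }
})
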