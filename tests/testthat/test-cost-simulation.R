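test_that("episode cost charges prorated tablets at the strength-year unit cost", {
  rec <- make_records(patient = "PTa", month = "2010-06",
                      statin = "simvastatin", strength = 40,
                      tablets = 28L, days = 28L)
  pr <- data.frame(year = 2010L, statin = "simvastatin", strength_mg = 40,
                   total_quantity = 100, total_spend_gbp = 50)  # 0.50/tablet
  defl <- flat_deflators(2010)
  expect_equal(episode_cost(rec, pr, defl, cap_days = 28), 14.00)
  # no cap equals cap at days_supplied
  expect_equal(episode_cost(rec, pr, defl, cap_days = NULL),
               episode_cost(rec, pr, defl, cap_days = 28))
  # 56 tablets over 56 days capped at 28 charges half
  long <- rec; long$tablets <- 56L; long$days_supplied <- 56L
  expect_equal(episode_cost(long, pr, defl, cap_days = 28),
               episode_cost(long, pr, defl, cap_days = NULL) / 2)
  # deflation applies to the money amount
  expect_equal(episode_cost(rec, pr, data.frame(year = 2010, index = 80), 28),
               14 * 100 / 80)
  expect_error(episode_cost(make_records("PTb", month = "2011-01",
                                         statin = "simvastatin", strength = 40),
                            pr, defl),
               "no price data for simvastatin 40 mg in 2011")
})

test_that("counterfactual cost substitutes the comparator at the equivalent dose", {
  eq <- toy_equivalence()
  pol <- comparator_policy()
  defl <- flat_deflators(c(2010, 2015))
  pr <- data.frame(
    year = c(2010L, 2010L, 2015L, 2015L),
    statin = c("atorvastatin", "simvastatin", "rosuvastatin", "atorvastatin"),
    strength_mg = c(10, 20, 10, 20),
    total_quantity = c(100, 100, 100, 100),
    total_spend_gbp = c(100, 10, 200, 30))
  # pre-cutover atorvastatin 10 (35%, medium) -> simvastatin 20 (36%, medium)
  rec <- make_records("PTa", month = "2010-03", statin = "atorvastatin",
                      strength = 10)
  expect_equal(episode_cost(rec, pr, defl, 28), 28.00)
  expect_equal(hypothetical_episode_cost(rec, pr, eq, pol, defl, 28), 2.80)
  # records already on the comparator are a fixed point
  on_comp <- make_records("PTb", month = "2010-03", statin = "simvastatin",
                          strength = 20)
  expect_equal(hypothetical_episode_cost(on_comp, pr, eq, pol, defl, 28),
               episode_cost(on_comp, pr, defl, 28))
  # post-cutover rosuvastatin is substituted to atorvastatin
  eq2 <- default_equivalence_table()
  rosu <- make_records("PTc", month = "2015-02", statin = "rosuvastatin",
                       strength = 10)
  expect_equal(hypothetical_episode_cost(rosu, pr, eq2, pol, defl, NULL),
               28 * 30 / 100)  # priced as atorvastatin 20 mg
})

test_that("scenarios are fixed points for comparator-only cohorts", {
  months <- c("2010-01", "2011-06", "2012-08", "2013-03")
  rec <- make_records(patient = sprintf("PT%d", 1:4), month = months,
                      statin = comparator_for(months, comparator_policy()),
                      strength = ifelse(comparator_for(months, comparator_policy())
                                        == "simvastatin", 40, 20))
  fix <- random_fixture(1)
  for (fun in list(scenario_first_episode, scenario_all_patients)) {
    out <- fun(rec, fix$prices, fix$equivalence, fix$policy, fix$deflators)
    expect_equal(out$savings_abs, rep(0, nrow(out)))
  }
})

test_that("scenario rows match the brute-force oracle on toy fixtures", {
  for (seed in c(2, 7, 13)) {
    fix <- random_fixture(seed)
    expect_matches_oracle(fix, "first")
    expect_matches_oracle(fix, "all")
  }
})

test_that("savings rows conserve cost and scale linearly in tablets", {
  fix <- random_fixture(5)
  for (fun in list(scenario_first_episode, scenario_all_patients)) {
    out <- fun(fix$records, fix$prices, fix$equivalence, fix$policy,
               fix$deflators)
    expect_equal(out$actual_cost, out$hypothetical_cost + out$savings_abs,
                 tolerance = 1e-9)
    doubled <- fix$records; doubled$tablets <- doubled$tablets * 2L
    out2 <- fun(doubled, fix$prices, fix$equivalence, fix$policy,
                fix$deflators)
    expect_equal(out2$actual_cost, 2 * out$actual_cost, tolerance = 1e-9)
    expect_equal(out2$savings_abs, 2 * out$savings_abs, tolerance = 1e-9)
  }
})

test_that("restricting scenario 2 to short first episodes reproduces scenario 1", {
  fix <- random_fixture(9)
  sub <- fix$records[fix$records$first_episode, ]
  sub$days_supplied <- pmin(sub$days_supplied, 28L)  # 28-day first episodes
  expect_gt(nrow(sub), 0L)
  s1 <- scenario_first_episode(sub, fix$prices, fix$equivalence, fix$policy,
                               fix$deflators)
  s2 <- scenario_all_patients(sub, fix$prices, fix$equivalence, fix$policy,
                              fix$deflators)
  expect_equal(s1, s2)
})

test_that("savings weakly decrease when the comparator's price rises", {
  fix <- random_fixture(11)
  base <- scenario_all_patients(fix$records, fix$prices, fix$equivalence,
                                fix$policy, fix$deflators)
  dearer <- fix$prices
  comp <- dearer$statin %in% c("simvastatin", "atorvastatin")
  dearer$total_spend_gbp[comp] <- dearer$total_spend_gbp[comp] * 3
  up <- scenario_all_patients(fix$records, dearer, fix$equivalence,
                              fix$policy, fix$deflators)
  expect_true(all(up$savings_abs <= base$savings_abs + 1e-9))
})

test_that("savings are non-negative when the comparator is cheapest in band", {
  years <- 2010:2013
  cheap <- make_price_grid(years, unit_costs = list(
    atorvastatin = 0.01, simvastatin = 0.01, rosuvastatin = 1,
    pravastatin = 1, fluvastatin = 1))
  for (seed in 1:5) {
    fix <- random_fixture(seed)
    out <- scenario_all_patients(fix$records, cheap, fix$equivalence,
                                 fix$policy, flat_deflators(years))
    expect_true(all(out$savings_abs >= -1e-9))
  }
})

test_that("empty years inside the range appear with zero counts", {
  rec <- make_records(patient = c("PTa", "PTb"),
                      month = c("2010-05", "2012-08"),
                      statin = "rosuvastatin", strength = 10)
  fix <- random_fixture(1)
  out <- scenario_first_episode(rec, fix$prices, fix$equivalence, fix$policy,
                                fix$deflators)
  r2011 <- out[out$year == "2011", ]
  expect_equal(r2011$n_patients, 0)
  expect_equal(r2011$actual_cost, 0)
  expect_true(is.na(r2011$savings_pct))
})

test_that("national scaling is a simple ratio with a division guard", {
  expect_equal(scale_to_national(400, 4e6, 4e4), 40000)
  expect_equal(scale_to_national(7, 100, 100), 7)
  expect_error(scale_to_national(1, 10, 0), "sample_total")
  fix <- random_fixture(4)
  s <- scenario_first_episode(fix$records, fix$prices, fix$equivalence,
                              fix$policy, fix$deflators, scale = 1000)
  u <- scenario_first_episode(fix$records, fix$prices, fix$equivalence,
                              fix$policy, fix$deflators)
  expect_equal(s$n_patients, u$n_patients * 1000)
  expect_equal(s$actual_cost, u$actual_cost)
})
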