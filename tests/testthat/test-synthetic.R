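test_that("logit choice probabilities are a stable shift-invariant softmax", {
  expect_equal(logit_choice_probabilities(rep(2.5, 5)), rep(0.2, 5))
  expect_equal(logit_choice_probabilities(c(0, log(3))), c(0.25, 0.75))
  u <- c(-1.2, 0.4, 3.3, 0)
  expect_equal(logit_choice_probabilities(u),
               logit_choice_probabilities(u + 17.5), tolerance = 1e-12)
  expect_equal(sum(logit_choice_probabilities(c(1000, 1001, 999))), 1)
  expect_error(logit_choice_probabilities(c(1, NA)), "finite")
  expect_error(logit_choice_probabilities(numeric(0)), "non-empty")
})

test_that("the quarterly price path decays geometrically to the floor", {
  cfg <- price_dynamics_config(
    branded_ddd_price = c(atorvastatin = 1, fluvastatin = 1, pravastatin = 1,
                          rosuvastatin = 1, simvastatin = 1),
    patent_expiry = c(simvastatin = "2010-01"),
    decay_per_quarter = stats::setNames(rep(0.5, 5), statin_codes()),
    floor_frac = stats::setNames(rep(0.05, 5), statin_codes()))
  q0 <- 2010L * 4L
  path <- ddd_price_path(cfg, "simvastatin", q0 + 0:8)
  expect_equal(path, pmax(0.5^(0:8), 0.05))  # halves each quarter, floors at 5%
  # no expiry (or decay factor 1) means a flat branded price forever
  expect_equal(ddd_price_path(cfg, "rosuvastatin", q0 + 0:8), rep(1, 9))
  flat <- price_dynamics_config(decay_per_quarter =
                                  stats::setNames(rep(1, 5), statin_codes()))
  expect_equal(ddd_price_path(flat, "simvastatin", q0 + 0:8),
               rep(0.85, 9))
})

test_that("the generated price series is seeded, covered and valid", {
  cfg <- price_dynamics_config()
  a <- generate_price_series(cfg, c("2010-01", "2012-12"), seed = 7)
  b <- generate_price_series(cfg, c("2010-01", "2012-12"), seed = 7)
  expect_identical(a, b)
  c2 <- generate_price_series(cfg, c("2010-01", "2012-12"), seed = 8)
  expect_false(identical(a, c2))
  expect_setequal(unique(a$year), 2010:2012)
  expect_setequal(unique(a$statin), statin_codes())
  expect_silent(validate_prices(a))
  expect_error(generate_price_series(cfg, c("2012-12", "2010-01")), "empty window")
})

test_that("generated cohorts are deterministic, valid prescription tables", {
  prices <- generate_price_series(price_dynamics_config(),
                                  c("2010-01", "2011-12"), seed = 1)
  cc <- cohort_config(seed = 5, n_practices = 6L,
                      window = c("2010-01", "2011-12"), sample_frac = 1 / 5000)
  a <- generate_cohort(cc, prices)
  b <- generate_cohort(cc, prices)
  expect_identical(a, b)
  expect_silent(validate_prescriptions(a))
  # one first episode per patient, dated at the patient's earliest record
  firsts <- tapply(a$first_episode, a$patient_id, sum)
  expect_true(all(firsts == 1L))
  mins <- tapply(month_index(a$issue_month), a$patient_id, min)
  fe <- a[a$first_episode, ]
  expect_equal(as.integer(mins[fe$patient_id]), month_index(fe$issue_month))
  # a coverage gap in the price series is a named error
  expect_error(generate_cohort(cc, prices[prices$year != 2011, ]),
               "does not cover .* 2011")
})

test_that("with no price, guideline or practice effects, initiation is uniform", {
  prices <- generate_price_series(price_dynamics_config(),
                                  c("2010-01", "2011-12"), seed = 2)
  cc <- cohort_config(seed = 6, beta = 0, gamma = 0, sigma = 0,
                      n_practices = 10L, window = c("2010-01", "2011-12"),
                      sample_frac = 1 / 150, discontinuation_hazard = 1)
  rec <- generate_cohort(cc, prices)
  n <- sum(rec$first_episode)
  shares <- table(rec$statin[rec$first_episode]) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(shares - 0.2) < 3 * se))
})

test_that("a strictly cheapest statin under strong price sensitivity dominates", {
  cfg <- price_dynamics_config(
    branded_ddd_price = c(atorvastatin = 2, fluvastatin = 2, pravastatin = 2,
                          rosuvastatin = 2, simvastatin = 0.05),
    patent_expiry = character(0))
  prices <- generate_price_series(cfg, c("2010-01", "2010-12"), seed = 3)
  cc <- cohort_config(seed = 7, beta = 20, gamma = 0, sigma = 0,
                      n_practices = 5L, window = c("2010-01", "2010-12"),
                      sample_frac = 1 / 300, discontinuation_hazard = 1)
  rec <- generate_cohort(cc, prices)
  share <- mean(rec$statin[rec$first_episode] == "simvastatin")
  expect_gt(share, 0.99)
})

test_that("ongoing patients switch only onto the current comparator", {
  prices <- generate_price_series(price_dynamics_config(),
                                  c("2011-01", "2013-12"), seed = 4)
  cc <- cohort_config(seed = 8, n_practices = 5L,
                      window = c("2011-01", "2013-12"), sample_frac = 1 / 2000,
                      discontinuation_hazard = 0.02, switch_prob = 0.5)
  rec <- generate_cohort(cc, prices)
  ord <- order(rec$patient_id, month_index(rec$issue_month))
  r <- rec[ord, ]
  changed <- which(!r$first_episode &
                     r$statin != c("", r$statin[-nrow(r)]) &
                     r$patient_id == c("", r$patient_id[-nrow(r)]))
  expect_gt(length(changed), 0L)
  expect_true(all(r$statin[changed] ==
                    comparator_for(r$issue_month[changed], comparator_policy())))
})

test_that("the conditional-logit refit recovers the generator coefficients", {
  prices <- generate_price_series(price_dynamics_config(),
                                  c("2003-07", "2018-12"), seed = 1)
  cc <- cohort_config(seed = 9, sigma = 0, beta = 5, gamma = 1,
                      sample_frac = 1 / 2000, discontinuation_hazard = 1)
  rec <- generate_cohort(cc, prices)
  fit <- fit_initiation_logit(rec, prices)
  expect_equal(fit$convergence, 0)
  expect_lt(abs(fit$beta - 5) / 5, 0.15)
  expect_gt(fit$gamma, 0)
})
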