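test_that("market shares are first-episode proportions per period", {
  rec <- make_records(patient = sprintf("PT%02d", 1:10), month = "2010-06",
                      statin = "simvastatin", strength = 40)
  sh <- market_shares(rec)
  expect_equal(sh$share[sh$statin == "simvastatin"], 1)
  expect_equal(sh$share[sh$statin != "simvastatin"], rep(0, 4))

  rec2 <- make_records(patient = sprintf("PT%02d", 1:4), month = "2010-06",
                       statin = c(rep("simvastatin", 3), "atorvastatin"),
                       strength = c(40, 40, 40, 20))
  sh2 <- market_shares(rec2)
  expect_equal(sh2$share[sh2$statin == "simvastatin"], 0.75)
  expect_equal(sh2$share[sh2$statin == "atorvastatin"], 0.25)
})

test_that("periods without new patients carry an explicit empty marker", {
  rec <- make_records(patient = c("PTa", "PTa", "PTb"),
                      month = c("2010-01", "2010-02", "2010-03"),
                      statin = "simvastatin", strength = 40,
                      first = c(TRUE, FALSE, FALSE))
  sh <- market_shares(rec)
  expect_setequal(unique(sh$period), c("2010-01", "2010-02", "2010-03"))
  feb <- sh[sh$period == "2010-02", ]
  expect_true(all(is.na(feb$share)))
  expect_true(all(feb$n_new == 0L))
  # only ongoing records: every period is an empty marker
  none <- rec; none$first_episode <- FALSE
  expect_true(all(is.na(market_shares(none)$share)))
})

test_that("shares sum to one in every non-empty period on random cohorts", {
  for (seed in 1:10) {
    fix <- random_fixture(seed)
    sh <- market_shares(fix$records)
    sums <- tapply(sh$share, sh$period, sum)
    nonempty <- tapply(sh$n_new, sh$period, sum) > 0
    expect_equal(as.numeric(sums[nonempty]), rep(1, sum(nonempty)),
                 tolerance = 1e-9)
    expect_true(all(is.na(sums[!nonempty])))
  }
})

# practices whose focal share is exactly `shares[k]`, 10 new patients each
quintile_fixture <- function(shares, month = "2010-06") {
  rows <- list()
  for (k in seq_along(shares)) {
    n_focal <- round(10 * shares[k])
    statin <- c(rep("simvastatin", n_focal), rep("atorvastatin", 10 - n_focal))
    rows[[k]] <- make_records(
      patient = sprintf("PT%s_%02d_%02d", month, k, 1:10),
      practice = sprintf("GP%02d", k), month = month,
      statin = statin, strength = ifelse(statin == "simvastatin", 40, 20))
  }
  do.call(rbind, rows)
}

test_that("dynamic quintile means recover hand-partitioned practice shares", {
  one_each <- quintile_fixture(c(0.1, 0.3, 0.5, 0.7, 0.9))
  q <- quintile_means_dynamic(one_each)
  expect_equal(q$mean_share, c(0.1, 0.3, 0.5, 0.7, 0.9))

  ten <- quintile_fixture(seq(0, 0.9, by = 0.1))
  q10 <- quintile_means_dynamic(ten)
  expect_equal(q10$mean_share, c(0.05, 0.25, 0.45, 0.65, 0.85))
  expect_equal(q10$n_practices, rep(2L, 5))

  flat <- quintile_fixture(rep(0.6, 8))
  qf <- quintile_means_dynamic(flat)
  expect_equal(qf$mean_share, rep(0.6, 5))
})

test_that("dynamic quintile means are monotone across groups and skip sparse periods", {
  for (seed in 1:5) {
    fix <- random_fixture(seed, max_records = 20L)
    q <- suppressMessages(quintile_means_dynamic(fix$records))
    if (is.null(q) || nrow(q) == 0L) next
    for (p in unique(q$period)) {
      expect_false(is.unsorted(q$mean_share[q$period == p]))
    }
  }
  sparse <- quintile_fixture(c(0.2, 0.8))  # 2 practices < 5
  expect_message(out <- quintile_means_dynamic(sparse), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("fixed-baseline quintiles coincide with dynamic at the baseline", {
  rec <- quintile_fixture(seq(0, 0.9, by = 0.1), month = "2003-08")
  dyn <- quintile_means_dynamic(rec, granularity = "quarter")
  fix <- quintile_means_fixed(rec, baseline_period = "2003-Q3")
  expect_equal(fix$mean_share, dyn$mean_share)
  expect_identical(attr(fix, "mode"), "fixed_baseline")
})

test_that("fixed mode keeps membership frozen while dynamic re-ranks", {
  base <- quintile_fixture(seq(0, 0.9, by = 0.1), month = "2003-08")
  # in the next quarter the baseline-bottom practice (GP01, share 0) jumps to 1.0
  later <- quintile_fixture(c(1.0, seq(0.1, 0.9, by = 0.1)), month = "2003-11")
  rec <- rbind(base, later)
  fx <- quintile_means_fixed(rec, baseline_period = "2003-Q3")
  q4 <- fx[fx$period == "2003-Q4", ]
  # bottom group mean: GP01 now 1.0, GP02 0.1 -> 0.55; the rest shift by one
  expect_equal(q4$mean_share, c(0.55, 0.25, 0.45, 0.65, 0.85))
  # baseline under-population is an error
  expect_error(quintile_means_fixed(rec, baseline_period = "2004-Q1"),
               "need >= 5")
})

test_that("switch-away rate counts switchers and close follow-up", {
  one <- make_records(patient = "PTa", month = c("2010-01", "2010-02", "2010-04"),
                      statin = c("atorvastatin", "simvastatin", "atorvastatin"),
                      strength = c(20, 40, 20))
  expect_equal(as.numeric(switch_away_rate(one, "simvastatin", 4)), 100)

  # switched on, never prescribed again: denominator only
  censored <- make_records(patient = "PTb", month = c("2010-01", "2010-02"),
                           statin = c("atorvastatin", "simvastatin"),
                           strength = c(20, 40))
  r <- switch_away_rate(rbind(one, censored), "simvastatin", 4)
  expect_equal(as.numeric(r), 50)
  expect_equal(attr(r, "n_switchers"), 2L)

  # 10 patients switch on; 3 leave within the window
  mk <- function(id, back) {
    statin3 <- if (back) "rosuvastatin" else "simvastatin"
    make_records(patient = id, month = c("2011-01", "2011-03", "2011-06"),
                 statin = c("pravastatin", "simvastatin", statin3),
                 strength = c(20, 40, ifelse(statin3 == "simvastatin", 40, 10)))
  }
  ten <- do.call(rbind, lapply(1:10, function(i) mk(sprintf("PT%02d", i), i <= 3)))
  expect_equal(as.numeric(switch_away_rate(ten, "simvastatin", 4)), 30)
  # beyond the window the switch-back is not counted
  expect_equal(as.numeric(switch_away_rate(ten, "simvastatin", 2)), 0)
  # no switch events: undefined, not zero
  expect_true(is.na(switch_away_rate(one[1, ], "simvastatin", 4)))
})
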