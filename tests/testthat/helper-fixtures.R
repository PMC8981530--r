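# Shared fixture builders and the independent brute-force savings oracle.
# The oracle deliberately re-implements banding, substitution and costing with
# plain loops and arithmetic so it shares no code path with the package.

flat_deflators <- function(years = 2003:2018) {
  data.frame(year = years, index = 100)
}

# terse record constructor; one first episode per patient by default
make_records <- function(patient, practice = "GP1", month, statin, strength,
                         tablets = 28L, days = 28L, first = NULL) {
  n <- max(length(patient), length(month), length(statin), length(strength))
  df <- data.frame(
    patient_id = rep_len(patient, n),
    practice_id = rep_len(practice, n),
    issue_month = rep_len(month, n),
    statin = rep_len(statin, n),
    strength_mg = rep_len(strength, n),
    tablets = rep_len(as.integer(tablets), n),
    days_supplied = rep_len(as.integer(days), n),
    stringsAsFactors = FALSE
  )
  if (is.null(first)) {
    ord <- order(df$patient_id, statincost::month_index(df$issue_month))
    first <- logical(n)
    first[ord[!duplicated(df$patient_id[ord])]] <- TRUE
  }
  df$first_episode <- rep_len(first, n)
  df
}

# full price grid over the catalogue so any substitution can be priced
make_price_grid <- function(years, unit_costs = NULL, quantity = 1000) {
  cat <- default_strength_catalogue()
  rows <- list()
  for (y in years) for (s in names(cat)) for (m in cat[[s]]) {
    u <- if (is.null(unit_costs)) 1 else unit_costs[[s]]
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, statin = s, strength_mg = m,
      total_quantity = quantity, total_spend_gbp = u * quantity,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# spec toy equivalence table: A 10->35, 20->42; B 10->30, 20->36, 40->43
toy_equivalence <- function() {
  data.frame(
    statin = c("atorvastatin", "atorvastatin",
               "simvastatin", "simvastatin", "simvastatin"),
    dose_mg = c(10, 20, 10, 20, 40),
    ldl_reduction_pct = c(35, 42, 30, 36, 43),
    stringsAsFactors = FALSE
  )
}

# random small fixture: <= 20 records plus covering prices and deflators
random_fixture <- function(seed, max_records = 20L) {
  set.seed(seed)
  years <- 2010:2013
  cat <- default_strength_catalogue()
  n <- sample.int(max_records, 1L)
  statin <- sample(names(cat), n, replace = TRUE)
  strength <- vapply(statin, function(s) sample(cat[[s]], 1L), 0)
  months <- sprintf("%d-%02d", sample(years, n, TRUE), sample.int(12L, n, TRUE))
  patient <- sprintf("PT%02d", sample.int(max(3L, n %/% 2L), n, replace = TRUE))
  records <- make_records(
    patient = patient, practice = sprintf("GP%d", sample.int(4L, n, TRUE)),
    month = months, statin = statin, strength = strength,
    tablets = sample(7:56, n, TRUE), days = sample(7:84, n, TRUE))
  prices <- make_price_grid(years)
  prices$total_quantity <- round(runif(nrow(prices), 100, 2000))
  prices$total_spend_gbp <- round(runif(nrow(prices), 10, 3000), 2)
  deflators <- data.frame(year = c(years, 2018),
                          index = c(round(runif(length(years), 70, 110), 1), 100))
  list(records = records, prices = prices, deflators = deflators,
       equivalence = default_equivalence_table(), policy = comparator_policy())
}

# ---- independent oracle ----------------------------------------------------

oracle_band <- function(pct) {
  stopifnot(pct >= 20)
  if (pct <= 30) "low" else if (pct <= 40) "medium" else "high"
}

oracle_equiv_dose <- function(statin, dose, target, eq) {
  if (statin == target) return(dose)
  red <- NA_real_
  for (i in seq_len(nrow(eq))) {
    if (eq$statin[i] == statin && eq$dose_mg[i] == dose) red <- eq$ldl_reduction_pct[i]
  }
  stopifnot(!is.na(red))
  band <- oracle_band(red)
  best_same <- Inf; best_ge <- Inf; biggest <- -Inf
  for (i in seq_len(nrow(eq))) {
    if (eq$statin[i] != target) next
    d <- eq$dose_mg[i]; r <- eq$ldl_reduction_pct[i]
    if (oracle_band(r) == band && d < best_same) best_same <- d
    if (r >= red && d < best_ge) best_ge <- d
    if (d > biggest) biggest <- d
  }
  if (is.finite(best_same)) best_same
  else if (is.finite(best_ge)) best_ge
  else biggest
}

oracle_record_cost <- function(statin, strength, month, tablets, days, cap,
                               prices, deflators) {
  year <- as.integer(substr(month, 1, 4))
  u <- NA_real_
  for (i in seq_len(nrow(prices))) {
    if (prices$statin[i] == statin && prices$strength_mg[i] == strength &&
        prices$year[i] == year) {
      u <- prices$total_spend_gbp[i] / prices$total_quantity[i]
    }
  }
  stopifnot(!is.na(u))
  idx <- NA_real_
  for (i in seq_len(nrow(deflators))) {
    if (deflators$year[i] == year) idx <- deflators$index[i]
  }
  tablets * min(days, cap) / days * u * 100 / idx
}

# per-record summation, no grouping machinery: returns yearly rows
oracle_scenario <- function(records, prices, eq, policy, deflators,
                            scenario = c("first", "all")) {
  scenario <- match.arg(scenario)
  cutover <- 12 * as.integer(substr(policy$cutover_month, 1, 4)) +
    as.integer(substr(policy$cutover_month, 6, 7)) - 1
  actual <- numeric(0); hyp <- numeric(0); patients <- list()
  for (i in seq_len(nrow(records))) {
    if (scenario == "first" && !records$first_episode[i]) next
    cap <- if (scenario == "first") 28 else Inf
    mo <- records$issue_month[i]
    y <- substr(mo, 1, 4)
    mi <- 12 * as.integer(y) + as.integer(substr(mo, 6, 7)) - 1
    comp <- if (mi >= cutover) policy$post_comparator else policy$pre_comparator
    a <- oracle_record_cost(records$statin[i], records$strength_mg[i], mo,
                            records$tablets[i], records$days_supplied[i], cap,
                            prices, deflators)
    if (records$statin[i] == comp) {
      h <- a
    } else {
      d <- oracle_equiv_dose(records$statin[i], records$strength_mg[i], comp, eq)
      h <- oracle_record_cost(comp, d, mo, records$tablets[i],
                              records$days_supplied[i], cap, prices, deflators)
    }
    if (is.na(actual[y])) { actual[y] <- 0; hyp[y] <- 0; patients[[y]] <- character(0) }
    actual[y] <- actual[y] + a
    hyp[y] <- hyp[y] + h
    patients[[y]] <- union(patients[[y]], records$patient_id[i])
  }
  years <- sort(names(actual))
  data.frame(year = years,
             n_patients = vapply(patients[years], length, 0L),
             actual_cost = unname(actual[years]),
             hypothetical_cost = unname(hyp[years]),
             stringsAsFactors = FALSE)
}

# compare package scenario yearly rows against the oracle, 1e-9 relative
expect_matches_oracle <- function(fix, scenario) {
  fun <- if (scenario == "first") scenario_first_episode else scenario_all_patients
  got <- fun(fix$records, fix$prices, fix$equivalence, fix$policy, fix$deflators)
  ora <- oracle_scenario(fix$records, fix$prices, fix$equivalence, fix$policy,
                         fix$deflators, scenario)
  got <- got[got$year %in% ora$year, ]
  expect_equal(got$actual_cost, ora$actual_cost, tolerance = 1e-9)
  expect_equal(got$hypothetical_cost, ora$hypothetical_cost, tolerance = 1e-9)
  expect_equal(got$savings_abs, ora$actual_cost - ora$hypothetical_cost,
               tolerance = 1e-9)
  if (scenario == "all") expect_equal(got$n_patients, as.numeric(ora$n_patients))
}
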