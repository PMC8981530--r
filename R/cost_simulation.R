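# map each record to the unit tablet cost of its (statin, strength, year);
# missing price cells are an error naming the pair, never silently zero
record_unit_costs <- function(records, prices, what = "episode_cost") {
  year <- month_year(records$issue_month)
  key <- paste(records$statin, records$strength_mg, year, sep = "|")
  pkey <- paste(prices$statin, prices$strength_mg, prices$year, sep = "|")
  i <- match(key, pkey)
  if (anyNA(i)) {
    miss <- unique(paste0(records$statin[is.na(i)], " ",
                          records$strength_mg[is.na(i)], " mg in ",
                          year[is.na(i)]))
    stop(what, ": no price data for ", paste(miss, collapse = "; "),
         call. = FALSE)
  }
  prices$total_spend_gbp[i] / prices$total_quantity[i]
}

#' Cost of a prescription episode in constant 2018 GBP
#'
#' Charges `tablets * min(days_supplied, cap_days) / days_supplied` tablets at
#' the average acquisition cost of the record's (statin, strength) in the
#' record's issue year, then deflates to 2018 purchasing power.  Capping
#' prorates tablets by the day fraction, so the result is neutral to pack-size
#' conventions; `cap_days = NULL` charges all tablets.
#'
#' @param records one or more prescription records.
#' @param prices annual price table.
#' @param deflators GDP deflator series.
#' @param cap_days maximum days of treatment to cost, or `NULL` for no cap.
#' @return numeric vector of constant-2018 GBP, one element per record.
#' @export
episode_cost <- function(records, prices, deflators, cap_days = NULL) {
  u <- record_unit_costs(records, prices)
  frac <- if (is.null(cap_days)) 1 else {
    pmin(records$days_supplied, cap_days) / records$days_supplied
  }
  year <- month_year(records$issue_month)
  deflate(records$tablets * frac * u, year, deflators)
}

#' Counterfactual episode cost under the comparator policy
#'
#' Re-prices each record as if the policy comparator for its issue month had
#' been prescribed instead, at the dose therapeutically equivalent to the
#' original treatment (same LDL-reduction intensity band, smallest adequate
#' dose; see [equivalent_dose()]).  Tablet count and duration are kept;
#' only agent and strength change.  Records already on the comparator are
#' costed unchanged.
#'
#' @inheritParams episode_cost
#' @param equivalence LDL-reduction equivalence table.
#' @param policy a [comparator_policy()].
#' @return numeric vector of constant-2018 GBP, one element per record.
#' @export
hypothetical_episode_cost <- function(records, prices, equivalence, policy,
                                      deflators, cap_days = NULL) {
  comp <- comparator_for(records$issue_month, policy)
  sub <- records
  needs <- sub$statin != comp
  if (any(needs)) {
    pairs <- unique(data.frame(statin = sub$statin[needs],
                               strength_mg = sub$strength_mg[needs],
                               target = comp[needs],
                               stringsAsFactors = FALSE))
    pairs$dose <- mapply(function(s, d, t) {
      as.numeric(equivalent_dose(s, d, t, equivalence))
    }, pairs$statin, pairs$strength_mg, pairs$target)
    i <- match(paste(sub$statin[needs], sub$strength_mg[needs], comp[needs]),
               paste(pairs$statin, pairs$strength_mg, pairs$target))
    sub$strength_mg[needs] <- pairs$dose[i]
    sub$statin[needs] <- comp[needs]
  }
  u <- record_unit_costs(sub, prices, "hypothetical_episode_cost")
  frac <- if (is.null(cap_days)) 1 else {
    pmin(sub$days_supplied, cap_days) / sub$days_supplied
  }
  deflate(sub$tablets * frac * u, month_year(sub$issue_month), deflators)
}

build_savings_rows <- function(year, n_patients, actual, hypothetical,
                               total_n = sum(n_patients)) {
  savings <- actual - hypothetical
  pct <- ifelse(actual > 0, 100 * savings / actual, NA_real_)
  yearly <- data.frame(
    year = as.character(year), n_patients = n_patients,
    actual_cost = actual, hypothetical_cost = hypothetical,
    savings_abs = savings, savings_pct = pct, stringsAsFactors = FALSE
  )
  tot_a <- sum(actual); tot_h <- sum(hypothetical)
  total <- data.frame(
    year = "Total", n_patients = total_n,
    actual_cost = tot_a, hypothetical_cost = tot_h,
    savings_abs = tot_a - tot_h,
    savings_pct = if (tot_a > 0) 100 * (tot_a - tot_h) / tot_a else NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(yearly, total)
}

#' Scenario 1: savings on the first 28 days of new treatment episodes
#'
#' Restricts the cohort to first prescription episodes and costs only the
#' first `cap_days` days of each, comparing the actual treatment with the
#' comparator-policy counterfactual.  Per calendar year: the number of new
#' patients, actual cost, hypothetical cost, and absolute and relative
#' savings, all in constant 2018 GBP, plus a cumulative `"Total"` row.
#'
#' @param records prescription table (first episodes identified by flag).
#' @param prices annual price table.
#' @param equivalence LDL-reduction equivalence table.
#' @param policy a [comparator_policy()].
#' @param deflators GDP deflator series.
#' @param scale optional multiplicative factor applied to patient counts
#'   (e.g. a sample-to-national factor from [scale_to_national()]); `NULL`
#'   reports sample-level counts.
#' @param cap_days days of treatment costed per episode (default 28).
#' @return savings data.frame (see [write_savings_table()]).  Years inside the
#'   data range with no first episodes appear with zero counts and costs and
#'   `savings_pct = NA`.
#' @export
scenario_first_episode <- function(records, prices, equivalence,
                                   policy = comparator_policy(),
                                   deflators = default_deflator_series(),
                                   scale = NULL, cap_days = 28L) {
  fe <- records[records$first_episode, , drop = FALSE]
  if (nrow(fe) == 0L) stop("scenario_first_episode: no first-episode records",
                           call. = FALSE)
  years <- seq(min(month_year(records$issue_month)),
               max(month_year(records$issue_month)))
  fy <- factor(month_year(fe$issue_month), levels = years)
  actual <- as.numeric(tapply(episode_cost(fe, prices, deflators, cap_days),
                              fy, sum, default = 0))
  hyp <- as.numeric(tapply(
    hypothetical_episode_cost(fe, prices, equivalence, policy, deflators, cap_days),
    fy, sum, default = 0))
  n <- as.numeric(table(fy))
  if (!is.null(scale)) n <- n * scale
  build_savings_rows(years, n, actual, hyp)
}

#' Scenario 2: savings on all prescription-days for all patients
#'
#' Costs every prescription record in full (no day cap) for both the actual
#' treatments and the comparator-policy counterfactual.  Substitution is
#' evaluated record by record at each record's own issue month, so a patient
#' whose records straddle the policy cutover is substituted to simvastatin
#' before it and atorvastatin after it.  `n_patients` counts distinct patients
#' with at least one record in the year; the `"Total"` row counts distinct
#' patients over the whole window.
#'
#' @inheritParams scenario_first_episode
#' @return savings data.frame (see [write_savings_table()]).
#' @export
scenario_all_patients <- function(records, prices, equivalence,
                                  policy = comparator_policy(),
                                  deflators = default_deflator_series(),
                                  scale = NULL) {
  if (nrow(records) == 0L) stop("scenario_all_patients: no records", call. = FALSE)
  years <- seq(min(month_year(records$issue_month)),
               max(month_year(records$issue_month)))
  fy <- factor(month_year(records$issue_month), levels = years)
  actual <- as.numeric(tapply(episode_cost(records, prices, deflators, NULL),
                              fy, sum, default = 0))
  hyp <- as.numeric(tapply(
    hypothetical_episode_cost(records, prices, equivalence, policy, deflators, NULL),
    fy, sum, default = 0))
  n <- as.numeric(tapply(records$patient_id, fy,
                         function(p) length(unique(p)), default = 0))
  total_n <- length(unique(records$patient_id))
  if (!is.null(scale)) {
    n <- n * scale
    total_n <- total_n * scale
  }
  build_savings_rows(years, n, actual, hyp, total_n = total_n)
}

#' Scale a sample count to a national estimate
#'
#' Single multiplicative scaling: `sample_count * national_total /
#' sample_total`, the ratio estimator used to present sample-level patient
#' counts as national ones when the sample's total volume and the national
#' total volume are both known.
#'
#' @param sample_count count observed in the sample.
#' @param national_total national total of the scaling basis (e.g. tablets).
#' @param sample_total sample total of the same basis; must be positive.
#' @return scaled count.
#' @export
scale_to_national <- function(sample_count, national_total, sample_total) {
  if (!length(sample_total) || is.na(sample_total) || sample_total <= 0) {
    stop("scale_to_national: sample_total must be > 0", call. = FALSE)
  }
  sample_count * national_total / sample_total
}
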