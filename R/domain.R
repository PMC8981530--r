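#' The five statins available in the British National Formulary
#'
#' All functions in this package restrict the drug universe to the five statins
#' prescribable in English primary care over the study window; any other agent
#' is rejected at validation time.
#'
#' @return character vector of the five statin names (lower case).
#' @export
statin_codes <- function() {
  c("atorvastatin", "fluvastatin", "pravastatin", "rosuvastatin", "simvastatin")
}

#' WHO defined daily doses for statins
#'
#' The defined daily dose (DDD) is the WHO's assumed average maintenance dose
#' per day for a drug's main indication; dividing acquisition cost by the
#' number of DDDs dispensed makes costs comparable across drugs and strengths.
#'
#' @return named numeric vector, DDD in milligrams per statin.
#' @export
default_ddd_table <- function() {
  c(atorvastatin = 20, fluvastatin = 60, pravastatin = 30,
    rosuvastatin = 10, simvastatin = 30)
}

#' Default tablet-strength catalogue
#'
#' Strengths (mg per tablet) marketed for each statin.  Fully overridable:
#' every reader and generator takes a `strength_catalogue` argument.
#'
#' @return named list, one numeric vector of strengths per statin.
#' @export
default_strength_catalogue <- function() {
  list(atorvastatin = c(10, 20, 40, 80),
       fluvastatin  = c(20, 40, 80),
       pravastatin  = c(10, 20, 40),
       rosuvastatin = c(5, 10, 20, 40),
       simvastatin  = c(10, 20, 40, 80))
}

#' Default LDL-reduction equivalence table
#'
#' Percentage reduction in low-density lipoprotein (LDL) cholesterol achieved
#' by each statin dose, following the standard NICE intensity groupings.
#' Reductions of 20--30% are classed low intensity, 31--40% medium and above
#' 40% high; therapeutic substitution between statins is performed within
#' these bands (see [equivalent_dose()]).
#'
#' @return data.frame with columns `statin`, `dose_mg`, `ldl_reduction_pct`.
#' @export
default_equivalence_table <- function() {
  data.frame(
    statin = rep(c("fluvastatin", "pravastatin", "simvastatin",
                   "atorvastatin", "rosuvastatin"),
                 times = c(3L, 3L, 4L, 4L, 4L)),
    dose_mg = c(20, 40, 80,
                10, 20, 40,
                10, 20, 40, 80,
                10, 20, 40, 80,
                5, 10, 20, 40),
    ldl_reduction_pct = c(21, 27, 33,
                          20, 24, 29,
                          27, 32, 37, 42,
                          37, 43, 49, 55,
                          38, 43, 48, 53),
    stringsAsFactors = FALSE
  )
}

#' Default GDP deflator series (base 2018 = 100)
#'
#' Approximate UK calendar-year GDP deflator index values used to express
#' money amounts in constant 2018 GBP.  Approximate: suitable for synthetic
#' analyses and examples; supply your own series via [read_deflator_series()]
#' for work against real price data.
#'
#' @return data.frame with columns `year`, `index`.
#' @export
default_deflator_series <- function() {
  validate_deflators(data.frame(
    year = 2003:2018,
    index = c(74.0, 75.9, 77.6, 79.9, 82.3, 84.7, 85.9, 87.2,
              88.8, 90.2, 92.0, 93.3, 93.8, 95.7, 97.6, 100.0)
  ))
}

#' Comparator policy: the cost-effective statin over time
#'
#' The cost-minimisation counterfactual substitutes every prescription with a
#' therapeutically similar dose of the policy comparator: simvastatin before
#' the cutover month and atorvastatin from the cutover month onwards.  The
#' default cutover is May 2012, the month atorvastatin lost patent protection.
#'
#' @param cutover_month `"YYYY-MM"`; first month the post comparator applies.
#' @param pre_comparator,post_comparator statin names, must differ.
#' @return an object of class `"comparator_policy"`.
#' @seealso [comparator_for()]
#' @export
comparator_policy <- function(cutover_month = "2012-05",
                              pre_comparator = "simvastatin",
                              post_comparator = "atorvastatin") {
  month_index(cutover_month)
  pre_comparator <- match.arg(pre_comparator, statin_codes())
  post_comparator <- match.arg(post_comparator, statin_codes())
  if (pre_comparator == post_comparator) {
    stop("pre_comparator and post_comparator must differ", call. = FALSE)
  }
  structure(list(cutover_month = cutover_month,
                 pre_comparator = pre_comparator,
                 post_comparator = post_comparator),
            class = "comparator_policy")
}

#' @export
print.comparator_policy <- function(x, ...) {
  cat("Comparator policy: ", x$pre_comparator, " before ", x$cutover_month,
      ", ", x$post_comparator, " from ", x$cutover_month, " onwards\n", sep = "")
  invisible(x)
}

# ---- validators ------------------------------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

fail_rows <- function(bad, msg) {
  if (any(bad)) {
    stop(sprintf("%s (row %s)", msg,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
}

#' Validate a prescription-record table
#'
#' Checks the invariants of a prescription-event table: known statin, strength
#' on the catalogue for that statin, positive tablet count, at least one day
#' supplied, valid issue month, and at most one first-episode record per
#' patient.  Errors report 1-based data-row numbers (header excluded).
#'
#' @param records data.frame with columns `patient_id`, `practice_id`,
#'   `issue_month`, `statin`, `strength_mg`, `tablets`, `days_supplied`,
#'   `first_episode`.
#' @param strength_catalogue named list of allowed strengths per statin.
#' @return the validated data.frame, invisibly, with normalised column types.
#' @export
validate_prescriptions <- function(records,
                                   strength_catalogue = default_strength_catalogue()) {
  require_columns(records,
                  c("patient_id", "practice_id", "issue_month", "statin",
                    "strength_mg", "tablets", "days_supplied", "first_episode"),
                  "prescriptions")
  records$patient_id <- as.character(records$patient_id)
  records$practice_id <- as.character(records$practice_id)
  records$issue_month <- as.character(records$issue_month)
  records$statin <- as.character(records$statin)
  records$strength_mg <- as.numeric(records$strength_mg)
  records$tablets <- as.integer(records$tablets)
  records$days_supplied <- as.integer(records$days_supplied)
  records$first_episode <- as.logical(records$first_episode)

  ok_month <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", records$issue_month)
  fail_rows(!ok_month, "prescriptions: invalid issue_month")
  bad_statin <- !(records$statin %in% statin_codes())
  fail_rows(bad_statin, sprintf(
    "prescriptions: unknown statin [%s]",
    paste(unique(records$statin[bad_statin]), collapse = ", ")))
  on_catalogue <- mapply(function(s, m) {
    m %in% strength_catalogue[[s]]
  }, records$statin, records$strength_mg, USE.NAMES = FALSE)
  fail_rows(!on_catalogue, "prescriptions: strength_mg not on catalogue for statin")
  fail_rows(is.na(records$tablets) | records$tablets <= 0L,
            "prescriptions: tablets must be a positive integer")
  fail_rows(is.na(records$days_supplied) | records$days_supplied < 1L,
            "prescriptions: days_supplied must be >= 1")
  fail_rows(is.na(records$first_episode), "prescriptions: first_episode must be TRUE/FALSE")

  n_first <- tapply(records$first_episode, records$patient_id, sum)
  dup <- names(n_first)[n_first > 1L]
  if (length(dup)) {
    rows <- which(records$first_episode &
                    records$patient_id %in% dup)
    stop(sprintf(
      "prescriptions: more than one first_episode record for patient(s) %s (row %s)",
      paste(dup, collapse = ", "), paste(rows, collapse = ", ")), call. = FALSE)
  }
  invisible(records)
}

#' Validate an annual price/quantity table
#'
#' One row per (year, statin, strength): total tablets dispensed and total
#' nominal net-ingredient-cost spend.  Quantity must be positive, spend
#' non-negative, and the (year, statin, strength) key unique.
#'
#' @param prices data.frame with columns `year`, `statin`, `strength_mg`,
#'   `total_quantity`, `total_spend_gbp`.
#' @return the validated data.frame, invisibly.
#' @export
validate_prices <- function(prices) {
  require_columns(prices,
                  c("year", "statin", "strength_mg", "total_quantity",
                    "total_spend_gbp"), "prices")
  prices$year <- as.integer(prices$year)
  prices$statin <- as.character(prices$statin)
  prices$strength_mg <- as.numeric(prices$strength_mg)
  prices$total_quantity <- as.numeric(prices$total_quantity)
  prices$total_spend_gbp <- as.numeric(prices$total_spend_gbp)

  bad_statin <- !(prices$statin %in% statin_codes())
  fail_rows(bad_statin, sprintf(
    "prices: unknown statin [%s]",
    paste(unique(prices$statin[bad_statin]), collapse = ", ")))
  fail_rows(is.na(prices$total_quantity) | prices$total_quantity <= 0,
            "prices: total_quantity must be > 0")
  fail_rows(is.na(prices$total_spend_gbp) | prices$total_spend_gbp < 0,
            "prices: total_spend_gbp must be >= 0")
  key <- paste(prices$year, prices$statin, prices$strength_mg, sep = "|")
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    stop("prices: duplicated (year, statin, strength_mg) key(s): ",
         paste(gsub("\\|", ", ", d), collapse = "; "), call. = FALSE)
  }
  invisible(prices)
}

#' Validate a DDD table
#' @param ddd named numeric vector or data.frame with columns `statin`, `ddd_mg`.
#' @return a named numeric vector over all five statins, invisibly.
#' @export
validate_ddd <- function(ddd) {
  if (is.data.frame(ddd)) {
    require_columns(ddd, c("statin", "ddd_mg"), "ddd")
    ddd <- stats::setNames(as.numeric(ddd$ddd_mg), as.character(ddd$statin))
  }
  missing <- setdiff(statin_codes(), names(ddd))
  if (length(missing)) {
    stop("ddd: missing statin(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(ddd) | ddd <= 0)) stop("ddd: DDDs must be positive", call. = FALSE)
  invisible(ddd[statin_codes()])
}

#' Validate a GDP deflator series
#' @param deflators data.frame with columns `year`, `index`; all indices
#'   positive and, when 2018 is present, `index == 100` there.
#' @return the validated data.frame, invisibly.
#' @export
validate_deflators <- function(deflators) {
  require_columns(deflators, c("year", "index"), "deflators")
  deflators$year <- as.integer(deflators$year)
  deflators$index <- as.numeric(deflators$index)
  fail_rows(is.na(deflators$index) | deflators$index <= 0,
            "deflators: index must be > 0")
  if (anyDuplicated(deflators$year)) stop("deflators: duplicated year", call. = FALSE)
  base <- deflators$index[deflators$year == 2018L]
  if (length(base) && abs(base - 100) > 1e-9) {
    stop("deflators: index must be 100 in the base year 2018", call. = FALSE)
  }
  invisible(deflators)
}

#' Validate an LDL-reduction equivalence table
#'
#' Within each statin the LDL reduction must be non-decreasing in dose, and
#' every reduction must fall in a defined intensity band (>= 20%).
#'
#' @param table data.frame with columns `statin`, `dose_mg`, `ldl_reduction_pct`.
#' @return the validated data.frame, invisibly.
#' @export
validate_equivalence <- function(table) {
  require_columns(table, c("statin", "dose_mg", "ldl_reduction_pct"), "equivalence")
  table$statin <- as.character(table$statin)
  table$dose_mg <- as.numeric(table$dose_mg)
  table$ldl_reduction_pct <- as.numeric(table$ldl_reduction_pct)
  bad_statin <- !(table$statin %in% statin_codes())
  fail_rows(bad_statin, "equivalence: unknown statin")
  fail_rows(is.na(table$ldl_reduction_pct) | table$ldl_reduction_pct < 20,
            "equivalence: ldl_reduction_pct below the lowest band (20%)")
  key <- paste(table$statin, table$dose_mg)
  if (anyDuplicated(key)) stop("equivalence: duplicated (statin, dose) row", call. = FALSE)
  for (s in unique(table$statin)) {
    sub <- table[table$statin == s, ]
    sub <- sub[order(sub$dose_mg), ]
    if (is.unsorted(sub$ldl_reduction_pct)) {
      stop("equivalence: ldl_reduction_pct must be non-decreasing in dose for ",
           s, call. = FALSE)
    }
  }
  invisible(table)
}
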