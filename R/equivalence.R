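#' Tabulated LDL-cholesterol reduction for a statin dose
#'
#' @param statin statin name.
#' @param dose_mg dose in milligrams per day.
#' @param table equivalence table (see [default_equivalence_table()]).
#' @return the tabulated percentage LDL reduction.  A (statin, dose) pair
#'   absent from the table is a lookup error naming both.
#' @export
ldl_reduction <- function(statin, dose_mg, table = default_equivalence_table()) {
  i <- which(table$statin == statin & table$dose_mg == dose_mg)
  if (length(i) != 1L) {
    stop(sprintf("equivalence: no entry for %s %g mg", statin, dose_mg),
         call. = FALSE)
  }
  table$ldl_reduction_pct[i]
}

#' Intensity band of an LDL reduction
#'
#' Statin doses are classed by the percentage LDL-cholesterol reduction they
#' achieve: 20--30% low intensity, above 30% up to 40% medium, above 40% high.
#' The bands partition `[20, Inf)`; a reduction below 20% falls below the
#' lowest band and is an error.
#'
#' @param reduction_pct numeric vector of percentage LDL reductions.
#' @return character vector over `"low"`, `"medium"`, `"high"`.
#' @export
intensity_band <- function(reduction_pct) {
  if (any(is.na(reduction_pct)) || any(reduction_pct < 20)) {
    stop("intensity_band: reduction below the lowest band (20%)", call. = FALSE)
  }
  ifelse(reduction_pct <= 30, "low",
         ifelse(reduction_pct <= 40, "medium", "high"))
}

#' Therapeutically equivalent dose of another statin
#'
#' Maps a (statin, dose) to a dose of the `target` statin with similar
#' LDL-lowering intensity: the smallest target dose in the same intensity
#' band.  If the target has no dose in that band, the smallest target dose
#' achieving at least the source's LDL reduction is used; if none exists, the
#' largest catalogued target dose is returned with attribute
#' `band_unmatched = TRUE`.  Substituting a statin onto itself returns the
#' dose unchanged.
#'
#' The smallest-adequate-dose tie-break is cost-minimising whenever price is
#' monotone in dose.
#'
#' @param statin,dose_mg source treatment (must be in `table`).
#' @param target target statin (must have at least one catalogued dose).
#' @param table equivalence table.
#' @return target dose in milligrams.
#' @export
equivalent_dose <- function(statin, dose_mg, target,
                            table = default_equivalence_table()) {
  if (statin == target) return(dose_mg)
  red <- ldl_reduction(statin, dose_mg, table)
  band <- intensity_band(red)
  tgt <- table[table$statin == target, , drop = FALSE]
  if (nrow(tgt) == 0L) {
    stop(sprintf("equivalence: no catalogued dose for target %s", target),
         call. = FALSE)
  }
  tgt_band <- intensity_band(tgt$ldl_reduction_pct)
  same_band <- tgt$dose_mg[tgt_band == band]
  if (length(same_band)) return(min(same_band))
  at_least <- tgt$dose_mg[tgt$ldl_reduction_pct >= red]
  if (length(at_least)) return(min(at_least))
  structure(max(tgt$dose_mg), band_unmatched = TRUE)
}

#' Policy comparator in force at a given month
#'
#' A step function with a single discontinuity at the cutover month: months
#' strictly before the cutover map to the pre comparator, the cutover month
#' and every later month to the post comparator.
#'
#' @param month character vector of `"YYYY-MM"` months.
#' @param policy a [comparator_policy()].
#' @return character vector of statin names.
#' @examples
#' comparator_for(c("2012-04", "2012-05"), comparator_policy())
#' @export
comparator_for <- function(month, policy = comparator_policy()) {
  stopifnot(inherits(policy, "comparator_policy"))
  ifelse(month_index(month) >= month_index(policy$cutover_month),
         policy$post_comparator, policy$pre_comparator)
}
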