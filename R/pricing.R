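#' Average acquisition cost per tablet
#'
#' The annual price table gives, per (year, statin, strength), the total
#' tablets dispensed nationally and the corresponding total spend at net
#' ingredient cost.  The average acquisition cost per tablet is simply
#' spend / quantity.
#'
#' @param cells one or more price rows (data.frame with `total_spend_gbp`,
#'   `total_quantity`).
#' @return numeric vector, nominal GBP per tablet, one element per row.
#' @export
unit_cost <- function(cells) {
  require_columns(cells, c("total_spend_gbp", "total_quantity"), "prices")
  if (any(cells$total_quantity <= 0)) stop("prices: total_quantity must be > 0",
                                           call. = FALSE)
  cells$total_spend_gbp / cells$total_quantity
}

#' Acquisition cost per defined daily dose
#'
#' Pools all strengths of one statin in one year into a cost per milligram
#' (total spend over total milligrams dispensed) and multiplies by the statin's
#' DDD.  This milligram-weighted pooling yields a single cost-per-DDD curve per
#' drug without arbitrary strength weights.
#'
#' @param statin statin name.
#' @param year calendar year.
#' @param prices price table (see [read_prices()]).
#' @param ddd named DDD vector (mg), default [default_ddd_table()].
#' @return nominal GBP per DDD (scalar).  Errors if no price cell exists for
#'   the (statin, year) pair — missing data is never treated as zero cost.
#' @export
cost_per_ddd <- function(statin, year, prices, ddd = default_ddd_table()) {
  ddd <- validate_ddd(ddd)
  sub <- prices[prices$statin == statin & prices$year == year, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no price data for %s in %d", statin, as.integer(year)),
         call. = FALSE)
  }
  unname(ddd[[statin]]) * sum(sub$total_spend_gbp) /
    sum(sub$total_quantity * sub$strength_mg)
}

#' Cost-per-DDD series for every statin-year in a price table
#'
#' @param prices price table.
#' @param ddd named DDD vector.
#' @param deflators optional deflator series; when supplied, costs are
#'   expressed in constant 2018 GBP.
#' @return data.frame `(year, statin, cost_per_ddd)`, one row per statin-year
#'   present in `prices`, ordered by year then statin.
#' @export
cost_per_ddd_series <- function(prices, ddd = default_ddd_table(),
                                deflators = NULL) {
  keys <- unique(prices[, c("year", "statin")])
  keys <- keys[order(keys$year, keys$statin), , drop = FALSE]
  cost <- mapply(function(s, y) cost_per_ddd(s, y, prices, ddd),
                 keys$statin, keys$year, USE.NAMES = FALSE)
  if (!is.null(deflators)) cost <- deflate(cost, keys$year, deflators)
  data.frame(year = keys$year, statin = keys$statin, cost_per_ddd = cost,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert nominal GBP to constant 2018 GBP
#'
#' Multiplies each amount by `100 / index(year)`, the GDP-deflator adjustment
#' to base-2018 purchasing power.  Years absent from the series are an error;
#' the series is never extrapolated.  Deflation applies to money amounts only,
#' never to quantities.
#'
#' @param amount numeric vector of nominal GBP.
#' @param year calendar year(s), recycled against `amount`.
#' @param deflators deflator series data.frame (`year`, `index`, 2018 = 100).
#' @return numeric vector of constant-2018 GBP.
#' @export
deflate <- function(amount, year, deflators) {
  deflators <- validate_deflators(deflators)
  idx <- deflators$index[match(as.integer(year), deflators$year)]
  if (anyNA(idx)) {
    missing <- unique(as.integer(year)[is.na(idx)])
    stop("deflators: no index for year(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  amount * 100 / idx
}
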