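#' Delimited-text readers and writers
#'
#' All tables are exchanged as comma-separated UTF-8 text with a header row and
#' ISO `"YYYY-MM"` month strings.  Writers serialise doubles with 17 significant
#' digits so that a write/read round trip is the identity to full stored
#' precision.
#'
#' @name statincost-io
NULL

write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
}

read_csv_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write prescription-event tables
#'
#' @param path file path.
#' @param strength_catalogue named list of allowed strengths per statin; rows
#'   with off-catalogue strengths are rejected with their row number.
#' @return `read_prescriptions()` returns a validated data.frame of
#'   prescription records in file order.
#' @export
read_prescriptions <- function(path, strength_catalogue = default_strength_catalogue()) {
  df <- read_csv_checked(path, "prescriptions")
  v <- validate_prescriptions(df, strength_catalogue)
  v
}

#' @rdname read_prescriptions
#' @param records validated prescription data.frame.
#' @export
write_prescriptions <- function(records, path,
                                strength_catalogue = default_strength_catalogue()) {
  records <- validate_prescriptions(records, strength_catalogue)
  write_csv_precise(records, path)
  invisible(path)
}

#' Read and write annual price/quantity tables
#'
#' One row per (year, statin, strength_mg) with the total tablets dispensed and
#' total nominal spend (net ingredient cost, GBP).  Duplicate keys and
#' non-positive quantities are rejected.
#'
#' @param path file path.
#' @return `read_prices()` returns a validated data.frame of price cells.
#' @export
read_prices <- function(path) {
  validate_prices(read_csv_checked(path, "prices"))
}

#' @rdname read_prices
#' @param prices validated price data.frame.
#' @export
write_prices <- function(prices, path) {
  prices <- validate_prices(prices)
  write_csv_precise(prices, path)
  invisible(path)
}

#' Read and write DDD tables
#' @param path file path to a CSV with columns `statin`, `ddd_mg`.
#' @return `read_ddd_table()` returns a named numeric vector of DDDs (mg).
#' @export
read_ddd_table <- function(path) {
  validate_ddd(read_csv_checked(path, "ddd"))
}

#' @rdname read_ddd_table
#' @param ddd named numeric vector of DDDs.
#' @export
write_ddd_table <- function(ddd, path) {
  ddd <- validate_ddd(ddd)
  write_csv_precise(data.frame(statin = names(ddd), ddd_mg = as.numeric(ddd)), path)
  invisible(path)
}

#' Read and write GDP deflator series
#' @param path file path to a CSV with columns `year`, `index` (2018 = 100).
#' @return `read_deflator_series()` returns a validated data.frame.
#' @export
read_deflator_series <- function(path) {
  validate_deflators(read_csv_checked(path, "deflators"))
}

#' @rdname read_deflator_series
#' @param deflators validated deflator data.frame.
#' @export
write_deflator_series <- function(deflators, path) {
  deflators <- validate_deflators(deflators)
  write_csv_precise(deflators, path)
  invisible(path)
}

#' Read and write LDL-reduction equivalence tables
#' @param path file path to a CSV with columns `statin`, `dose_mg`,
#'   `ldl_reduction_pct`.
#' @return `read_equivalence_table()` returns a validated data.frame.
#' @export
read_equivalence_table <- function(path) {
  validate_equivalence(read_csv_checked(path, "equivalence"))
}

#' @rdname read_equivalence_table
#' @param table validated equivalence data.frame.
#' @export
write_equivalence_table <- function(table, path) {
  table <- validate_equivalence(table)
  write_csv_precise(table, path)
  invisible(path)
}

#' Write and read a savings table
#'
#' Serialises the output of [scenario_first_episode()] or
#' [scenario_all_patients()]: one row per calendar year plus a cumulative
#' `"Total"` row.  If the input lacks a `"Total"` row one is appended before
#' writing.  Writing an empty table is an error and produces no file.
#'
#' @param rows savings data.frame with columns `year` (character, years plus
#'   optionally `"Total"`), `n_patients`, `actual_cost`, `hypothetical_cost`,
#'   `savings_abs`, `savings_pct`.
#' @param path file path.
#' @export
write_savings_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("savings: refusing to write an empty table", call. = FALSE)
  }
  require_columns(rows, c("year", "n_patients", "actual_cost",
                          "hypothetical_cost", "savings_abs", "savings_pct"),
                  "savings")
  rows$year <- as.character(rows$year)
  if (!any(rows$year == "Total")) {
    yearly <- rows
    total <- data.frame(
      year = "Total",
      n_patients = sum(yearly$n_patients),
      actual_cost = sum(yearly$actual_cost),
      hypothetical_cost = sum(yearly$hypothetical_cost),
      savings_abs = sum(yearly$savings_abs),
      savings_pct = if (sum(yearly$actual_cost) > 0) {
        100 * sum(yearly$savings_abs) / sum(yearly$actual_cost)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
    rows <- rbind(yearly, total)
  }
  write_csv_precise(rows, path)
  invisible(path)
}

#' @rdname write_savings_table
#' @return `read_savings_table()` returns the savings data.frame with `year`
#'   as character (the final row is `"Total"`).
#' @export
read_savings_table <- function(path) {
  df <- read_csv_checked(path, "savings")
  require_columns(df, c("year", "n_patients", "actual_cost",
                        "hypothetical_cost", "savings_abs", "savings_pct"),
                  "savings")
  df$year <- as.character(df$year)
  df
}
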