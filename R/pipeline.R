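#' Pipeline configuration
#'
#' Bundles the inputs of a full analysis run.  Either synthetic mode (the
#' price and cohort generators supply the data) or file mode (paths to the
#' five input tables).  Validation is fail-fast: missing input files are
#' rejected before any computation starts.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param paths named list of input paths (file mode): `prescriptions`,
#'   `prices`, and optionally `ddd`, `deflators`, `equivalence` (package
#'   defaults fill any omitted).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param price_dynamics a [price_dynamics_config()] (synthetic mode).
#' @param policy a [comparator_policy()].
#' @param scenarios which savings scenarios to run: `"first"`, `"all"`, or
#'   `"both"`.
#' @param granularity period granularity for the share series.
#' @param scale optional national scaling factor for patient counts.
#' @param plots draw figure files (requires ggplot2)?
#' @param out_dir output directory, created if absent.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            paths = list(),
                            cohort = cohort_config(),
                            price_dynamics = price_dynamics_config(),
                            policy = comparator_policy(),
                            scenarios = c("both", "first", "all"),
                            granularity = c("month", "quarter"),
                            scale = NULL,
                            plots = FALSE,
                            out_dir = "statincost-output") {
  mode <- match.arg(mode)
  scenarios <- match.arg(scenarios)
  granularity <- match.arg(granularity)
  if (mode == "files") {
    needed <- c("prescriptions", "prices")
    missing <- setdiff(needed, names(paths))
    if (length(missing)) {
      stop("pipeline_config: file mode needs path(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("pipeline_config: input file not found: ", p,
                                call. = FALSE)
    }
  }
  structure(list(mode = mode, paths = paths, cohort = cohort,
                 price_dynamics = price_dynamics, policy = policy,
                 scenarios = scenarios, granularity = granularity,
                 scale = scale, plots = plots, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments; the
#' `cohort`, `price_dynamics` and `policy` blocks are passed as argument
#' lists to their constructors.
#'
#' @param path YAML file path.
#' @return a `"pipeline_config"` object.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("mode", "paths", "scenarios", "granularity", "scale",
              "plots", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$price_dynamics)) {
    args$price_dynamics <- do.call(price_dynamics_config, y$price_dynamics)
  }
  if (!is.null(y$policy)) args$policy <- do.call(comparator_policy, y$policy)
  do.call(pipeline_config, args)
}

write_stage <- function(df, path, written) {
  write_csv_precise(df, path)
  c(written, path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage over one input set: cost-per-DDD series, initiation
#' market shares, dynamic and baseline-fixed practice quintiles, and the
#' selected savings scenarios; writes each result as CSV under the output
#' directory and returns a manifest of produced files with MD5 content
#' hashes.  Identical config and seed give identical hashes.  If any stage
#' fails, files already written by this run are removed before the error (
#' tagged with the stage name) propagates.
#'
#' @param config a [pipeline_config()].
#' @param seed optional integer overriding the cohort config's seed
#'   (synthetic mode).
#' @return data.frame `(file, md5)`, one row per artifact.
#' @export
run_pipeline <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "load-inputs"
  result <- tryCatch({
    if (config$mode == "synthetic") {
      cc <- config$cohort
      if (!is.null(seed)) cc$seed <- as.integer(seed)
      stage <- "simulate-data"
      prices <- generate_price_series(config$price_dynamics,
                                      window = cc$window, seed = cc$seed)
      records <- generate_cohort(cc, prices, policy = config$policy)
      ddd <- default_ddd_table()
      deflators <- data.frame(year = sort(unique(prices$year)), index = 100)
      equivalence <- default_equivalence_table()
    } else {
      records <- read_prescriptions(config$paths$prescriptions)
      prices <- read_prices(config$paths$prices)
      ddd <- if (is.null(config$paths$ddd)) default_ddd_table() else {
        read_ddd_table(config$paths$ddd)
      }
      deflators <- if (is.null(config$paths$deflators)) {
        default_deflator_series()
      } else read_deflator_series(config$paths$deflators)
      equivalence <- if (is.null(config$paths$equivalence)) {
        default_equivalence_table()
      } else read_equivalence_table(config$paths$equivalence)
    }

    out <- function(f) file.path(config$out_dir, f)

    stage <- "cost-per-ddd"
    cpd <- cost_per_ddd_series(prices, ddd, deflators)
    written <- write_stage(cpd, out("cost_per_ddd.csv"), written)

    stage <- "market-shares"
    shares <- market_shares(records, config$granularity)
    written <- write_stage(shares, out("market_shares.csv"), written)

    stage <- "quintiles"
    qd <- suppressMessages(
      quintile_means_dynamic(records, granularity = "quarter"))
    qd$mode <- "dynamic"
    written <- write_stage(qd, out("quintiles_dynamic.csv"), written)
    baseline <- unique(quarter_label(records$issue_month[
      order(month_index(records$issue_month))]))[1L]
    qf <- quintile_means_fixed(records, baseline_period = baseline)
    qf$mode <- "fixed_baseline"
    written <- write_stage(qf, out("quintiles_fixed.csv"), written)

    first_rows <- all_rows <- NULL
    if (config$scenarios %in% c("first", "both")) {
      stage <- "savings-first-episode"
      first_rows <- scenario_first_episode(records, prices, equivalence,
                                           config$policy, deflators,
                                           scale = config$scale)
      written <- write_stage(first_rows, out("savings_first_episode.csv"),
                             written)
    }
    if (config$scenarios %in% c("all", "both")) {
      stage <- "savings-all-patients"
      all_rows <- scenario_all_patients(records, prices, equivalence,
                                        config$policy, deflators,
                                        scale = config$scale)
      written <- write_stage(all_rows, out("savings_all_patients.csv"),
                             written)
    }

    if (isTRUE(config$plots)) {
      stage <- "plots"
      written <- c(written, pipeline_plots(shares, cpd, qd, qf, config$out_dir))
    }

    data.frame(file = written, md5 = unname(tools::md5sum(written)),
               stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage [%s] failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

# figure files mirroring the share, cost-per-DDD and quintile panels
pipeline_plots <- function(shares, cpd, qd, qf, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("plots requested but ggplot2 is not installed; skipping")
    return(character(0))
  }
  g <- ggplot2::ggplot
  aes <- ggplot2::aes
  files <- character(0)
  save_plot <- function(p, f) {
    path <- file.path(out_dir, f)
    ggplot2::ggsave(path, p, width = 8, height = 5)
    c(files, path)
  }
  sh <- shares[!is.na(shares$share), ]
  files <- save_plot(
    g(sh, aes(x = .ordinal(sh$period), y = share, colour = statin,
              group = statin)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "period", y = "share of new patients"),
    "fig_shares.pdf")
  files <- save_plot(
    g(cpd, aes(x = year, y = cost_per_ddd, colour = statin)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "GBP per DDD (constant 2018)"),
    "fig_cost_per_ddd.pdf")
  for (nm in c("dynamic", "fixed")) {
    q <- if (nm == "dynamic") qd else qf
    files <- save_plot(
      g(q, aes(x = .ordinal(q$period), y = mean_share,
               colour = factor(quintile), group = factor(quintile))) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "period", y = "mean share", colour = "quintile"),
      paste0("fig_quintiles_", nm, ".pdf"))
  }
  files
}

# map period labels to plot positions preserving calendar order
.ordinal <- function(labels) match(labels, sort(unique(labels)))

#' Render the two-panel savings table
#'
#' Formats the two savings scenarios side by side — first-episode scenario on
#' the left, all-patients scenario on the right — one row per year plus the
#' cumulative `Total` row, money in constant 2018 GBP.  Both inputs must
#' cover the same years.
#'
#' @param first_rows,all_rows savings data.frames from
#'   [scenario_first_episode()] and [scenario_all_patients()].
#' @return character vector of table lines, invisibly; printed to the
#'   console.
#' @export
render_table1 <- function(first_rows, all_rows) {
  if (is.null(first_rows) || is.null(all_rows) ||
      nrow(first_rows) == 0L || nrow(all_rows) == 0L) {
    stop("render_table1: both scenarios required", call. = FALSE)
  }
  if (!identical(as.character(first_rows$year), as.character(all_rows$year))) {
    stop("render_table1: scenario year sets differ", call. = FALSE)
  }
  money <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
  pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))
  num <- function(x) formatC(round(x), format = "d", big.mark = ",")
  body <- data.frame(
    Year = first_rows$year,
    `New patients` = num(first_rows$n_patients),
    `Actual (GBP)` = money(first_rows$actual_cost),
    `Counterfactual (GBP)` = money(first_rows$hypothetical_cost),
    `Savings (GBP)` = money(first_rows$savings_abs),
    `Savings (%)` = pct(first_rows$savings_pct),
    `All patients` = num(all_rows$n_patients),
    `Actual (GBP) ` = money(all_rows$actual_cost),
    `Counterfactual (GBP) ` = money(all_rows$hypothetical_cost),
    `Savings (GBP) ` = money(all_rows$savings_abs),
    `Savings (%) ` = pct(all_rows$savings_pct),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  widths <- pmax(nchar(names(body)),
                 vapply(body, function(col) max(nchar(col)), 0L))
  pad <- function(v, w) formatC(v, width = w)
  header <- paste(mapply(pad, names(body), widths), collapse = "  ")
  rule1 <- paste(c("First 28 days, new patients  |  All prescriptions, all patients"),
                 collapse = "")
  lines <- c(rule1,
             header,
             strrep("-", nchar(header)),
             vapply(seq_len(nrow(body)), function(i) {
               paste(mapply(function(col, w) pad(body[[col]][i], w),
                            names(body), widths), collapse = "  ")
             }, ""))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write the small deterministic fixture set
#'
#' Emits a coherent miniature input set (prescriptions, prices, DDDs,
#' deflators, equivalence table) used across the test suite and examples:
#' a 3-practice synthetic cohort over 2010--2013 with the default two-expiry
#' price dynamics.  Deterministic given `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the five file paths, invisibly.
#' @export
write_test_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  window <- c("2010-01", "2013-12")
  prices <- generate_price_series(price_dynamics_config(), window, seed = seed)
  cohort <- cohort_config(seed = seed, n_practices = 3L, window = window,
                          sample_frac = 1 / 20000)
  records <- generate_cohort(cohort, prices)
  paths <- c(
    prescriptions = file.path(dir, "prescriptions.csv"),
    prices = file.path(dir, "prices.csv"),
    ddd = file.path(dir, "ddd.csv"),
    deflators = file.path(dir, "deflators.csv"),
    equivalence = file.path(dir, "equivalence.csv")
  )
  write_prescriptions(records, paths[["prescriptions"]])
  write_prices(prices, paths[["prices"]])
  write_ddd_table(default_ddd_table(), paths[["ddd"]])
  write_deflator_series(default_deflator_series(), paths[["deflators"]])
  write_equivalence_table(default_equivalence_table(), paths[["equivalence"]])
  invisible(paths)
}
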