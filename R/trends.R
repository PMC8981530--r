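#' Initiation market shares per period
#'
#' For each period (calendar month or quarter) spanned by the data, the share
#' of new patients (records flagged `first_episode`) initiated on each statin.
#' Shares within a non-empty period sum to one; periods with no new patients
#' are kept in the output with `n_new = 0` and `share = NA` as an explicit
#' empty marker.
#'
#' @param records prescription table; non-first-episode rows are ignored.
#' @param granularity `"month"` or `"quarter"`.
#' @return data.frame `(period, statin, n_new, share)` with five rows per
#'   period (one per statin), periods in calendar order.
#' @export
market_shares <- function(records, granularity = c("month", "quarter")) {
  granularity <- match.arg(granularity)
  if (nrow(records) == 0L) stop("market_shares: no records", call. = FALSE)
  levels <- period_levels(month_label(min(month_index(records$issue_month))),
                          month_label(max(month_index(records$issue_month))),
                          granularity)
  fe <- records[records$first_episode, , drop = FALSE]
  tab <- table(factor(period_of(fe$issue_month, granularity), levels = levels),
               factor(fe$statin, levels = statin_codes()))
  totals <- rowSums(tab)
  share <- sweep(tab, 1, totals, "/")          # 0/0 -> NaN for empty periods
  share[totals == 0, ] <- NA_real_
  data.frame(
    period = rep(levels, times = length(statin_codes())),
    statin = rep(statin_codes(), each = length(levels)),
    n_new = as.vector(unclass(tab)),
    share = as.vector(unclass(share)),
    stringsAsFactors = FALSE
  )
}

# per (period, practice): share of new patients on the focal statin
practice_focal_shares <- function(records, focal, granularity) {
  fe <- records[records$first_episode, , drop = FALSE]
  if (nrow(fe) == 0L) return(NULL)
  period <- period_of(fe$issue_month, granularity)
  sep <- "\x1f"  # unit separator: cannot occur in period labels or sane ids
  key <- factor(paste(period, fe$practice_id, sep = sep))
  total <- tapply(rep(1L, nrow(fe)), key, sum)
  focal_n <- tapply(fe$statin == focal, key, sum)
  parts <- strsplit(names(total), sep, fixed = TRUE)
  data.frame(
    period = vapply(parts, `[`, "", 1L),
    practice_id = vapply(parts, `[`, "", 2L),
    n_new = as.integer(total),
    share = as.numeric(focal_n / total),
    stringsAsFactors = FALSE
  )
}

# rank-based quintile assignment; ties broken by identifier
assign_quintiles <- function(share, id) {
  n <- length(share)
  o <- order(share, id)
  cuts <- ceiling(seq_len(5L) * n / 5L)
  g <- integer(n)
  g[o] <- rep.int(1:5, diff(c(0L, cuts)))
  g
}

#' Practice-heterogeneity quintiles, recomputed each period
#'
#' For every period, each practice's share of new patients initiated on the
#' focal statin is computed among its own new patients; practices are ranked
#' on that share and split into quintiles (cut points at ranks
#' `ceiling(k * N / 5)`, ties broken by practice identifier), and the
#' unweighted mean share within each quintile is reported.  Periods with fewer
#' than five practices seeing a new patient are skipped with a message.
#'
#' @param records prescription table.
#' @param focal statin whose prescribing share ranks the practices.
#' @param granularity `"month"` (the default, ranking practices every month)
#'   or `"quarter"`.
#' @return data.frame `(period, quintile, mean_share, n_practices)` with
#'   attribute `mode = "dynamic"`; within each period `mean_share` is
#'   non-decreasing from quintile 1 (bottom) to 5 (top).
#' @export
quintile_means_dynamic <- function(records, focal = "simvastatin",
                                   granularity = c("month", "quarter")) {
  granularity <- match.arg(granularity)
  ps <- practice_focal_shares(records, focal, granularity)
  if (is.null(ps)) stop("quintile_means_dynamic: no first-episode records",
                        call. = FALSE)
  out <- lapply(split(ps, ps$period), function(d) {
    if (nrow(d) < 5L) return(NULL)
    g <- assign_quintiles(d$share, d$practice_id)
    data.frame(
      period = d$period[1L],
      quintile = 1:5,
      mean_share = as.numeric(tapply(d$share, factor(g, levels = 1:5), mean)),
      n_practices = as.integer(table(factor(g, levels = 1:5))),
      stringsAsFactors = FALSE
    )
  })
  skipped <- names(out)[vapply(out, is.null, TRUE)]
  if (length(skipped)) {
    message("quintile_means_dynamic: skipped ", length(skipped),
            " period(s) with fewer than 5 active practices")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(period = character(0), quintile = integer(0),
                      mean_share = numeric(0), n_practices = integer(0),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$period, res$quintile), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "mode") <- "dynamic"
  res
}

#' Practice-heterogeneity quintiles with membership fixed at a baseline
#'
#' Quintile membership is computed once, from practice shares over the
#' baseline period, and then held fixed: each later period reports the
#' unweighted mean focal share among the member practices that saw at least
#' one new patient in that period.  Separating this from the dynamic ranking
#' distinguishes persistent practice-level differences from period-by-period
#' churn in who prescribes the focal statin.
#'
#' @param records prescription table.
#' @param focal statin whose share ranks the practices.
#' @param baseline_period period label at the series granularity (default
#'   `"2003-Q3"`, the first study quarter).
#' @param granularity `"quarter"` (default) or `"month"`.
#' @return data.frame `(period, quintile, mean_share, n_practices)` with
#'   attributes `mode = "fixed_baseline"` and `baseline_period`.  Quintiles
#'   with no member practice active in a period have `mean_share = NA`.
#' @export
quintile_means_fixed <- function(records, focal = "simvastatin",
                                 baseline_period = "2003-Q3",
                                 granularity = c("quarter", "month")) {
  granularity <- match.arg(granularity)
  ps <- practice_focal_shares(records, focal, granularity)
  if (is.null(ps)) stop("quintile_means_fixed: no first-episode records",
                        call. = FALSE)
  base <- ps[ps$period == baseline_period, , drop = FALSE]
  if (nrow(base) < 5L) {
    stop(sprintf(
      "quintile_means_fixed: baseline period %s has %d practice(s) with new patients; need >= 5",
      baseline_period, nrow(base)), call. = FALSE)
  }
  membership <- stats::setNames(assign_quintiles(base$share, base$practice_id),
                                base$practice_id)
  ps <- ps[ps$practice_id %in% names(membership), , drop = FALSE]
  ps$quintile <- membership[ps$practice_id]
  out <- lapply(split(ps, ps$period), function(d) {
    q <- factor(d$quintile, levels = 1:5)
    data.frame(
      period = d$period[1L],
      quintile = 1:5,
      mean_share = as.numeric(tapply(d$share, q, mean)),
      n_practices = as.integer(table(q)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$period, res$quintile), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "mode") <- "fixed_baseline"
  attr(res, "baseline_period") <- baseline_period
  res
}

#' Switch-away rate from a target statin
#'
#' Among patients who were switched onto the target statin (a prescription of
#' the target immediately preceded by a prescription of a different statin),
#' the percentage who then received a non-target statin within
#' `window_months` months of the switch.  A patient's first switch onto the
#' target defines their event; patients never prescribed again after the
#' switch stay in the denominator.
#'
#' @param records prescription table (all records, not only first episodes).
#' @param target statin switched onto (default the pre-2012 comparator,
#'   simvastatin).
#' @param window_months follow-up window in months after the switch month.
#' @return percentage in `[0, 100]`, with attributes `n_switchers` and
#'   `n_switched_away`; `NA` (with both attributes 0) when no patient ever
#'   switched onto the target.
#' @export
switch_away_rate <- function(records, target = "simvastatin", window_months = 4L) {
  ord <- order(records$patient_id, month_index(records$issue_month))
  r <- records[ord, , drop = FALSE]
  m <- month_index(r$issue_month)
  n_switch <- 0L
  n_away <- 0L
  for (d in split(seq_len(nrow(r)), r$patient_id)) {
    s <- r$statin[d]
    if (length(s) < 2L) next
    ev <- which(s[-1L] == target & s[-length(s)] != target) + 1L
    if (!length(ev)) next
    e <- ev[1L]
    n_switch <- n_switch + 1L
    t0 <- m[d][e]
    later <- seq_along(s) > e & m[d] > t0 & m[d] <= t0 + window_months
    if (any(s[later] != target)) n_away <- n_away + 1L
  }
  if (n_switch == 0L) {
    return(structure(NA_real_, n_switchers = 0L, n_switched_away = 0L))
  }
  structure(100 * n_away / n_switch,
            n_switchers = n_switch, n_switched_away = n_away)
}
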