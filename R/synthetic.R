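# run expr with a local RNG seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Multinomial-logit choice probabilities
#'
#' Numerically stable softmax: the choice kernel of the synthetic prescriber
#' model.  Invariant to adding a constant to all utilities.
#'
#' @param utilities non-empty finite numeric vector.
#' @return probability vector of the same length, summing to 1.
#' @examples
#' logit_choice_probabilities(c(0, log(3)))  # 0.25, 0.75
#' @export
logit_choice_probabilities <- function(utilities) {
  if (!length(utilities) || !all(is.finite(utilities))) {
    stop("logit_choice_probabilities: utilities must be non-empty and finite",
         call. = FALSE)
  }
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

#' Price-dynamics configuration for the synthetic price series
#'
#' Each statin has a branded real price per DDD that stays constant until its
#' patent expires (if ever); from the quarter after expiry the price is
#' multiplied by a per-quarter decay factor until it reaches a floor fraction
#' of the branded price — the generic-entry price collapse seen for
#' simvastatin (Zocor, May 2003) and atorvastatin (Lipitor, May 2012).
#'
#' @param branded_ddd_price named numeric, branded real GBP per DDD.
#' @param patent_expiry named character of `"YYYY-MM"` expiry months; statins
#'   absent from the vector never go generic.
#' @param decay_per_quarter named numeric in (0, 1], per-quarter multiplier
#'   after expiry.
#' @param floor_frac named numeric in (0, 1], floor as a fraction of the
#'   branded price.
#' @param strength_exponent exponent of the sublinear strength-price relation:
#'   a tablet of `m` mg costs `ddd_price * (m / DDD)^strength_exponent`.
#' @param annual_tablets named numeric, mean tablets dispensed per statin-year
#'   (split equally across strengths; quantities are drawn log-normally around
#'   these with `quantity_sdlog`).
#' @param quantity_sdlog log-scale s.d. of dispensed quantities.
#' @param strength_catalogue strengths marketed per statin.
#' @return a list of class `"price_dynamics_config"`.
#' @export
price_dynamics_config <- function(
    branded_ddd_price = c(atorvastatin = 0.90, fluvastatin = 0.60,
                          pravastatin = 0.75, rosuvastatin = 0.80,
                          simvastatin = 0.85),
    patent_expiry = c(simvastatin = "2003-05", atorvastatin = "2012-05"),
    decay_per_quarter = c(atorvastatin = 0.70, fluvastatin = 0.70,
                          pravastatin = 0.70, rosuvastatin = 0.70,
                          simvastatin = 0.70),
    floor_frac = c(atorvastatin = 0.05, fluvastatin = 0.05, pravastatin = 0.05,
                   rosuvastatin = 0.05, simvastatin = 0.05),
    strength_exponent = 0.8,
    annual_tablets = c(atorvastatin = 2e5, fluvastatin = 2e5, pravastatin = 2e5,
                       rosuvastatin = 2e5, simvastatin = 2e5),
    quantity_sdlog = 0.1,
    strength_catalogue = default_strength_catalogue()) {
  stopifnot(all(statin_codes() %in% names(branded_ddd_price)),
            all(branded_ddd_price > 0),
            all(decay_per_quarter > 0), all(decay_per_quarter <= 1),
            all(floor_frac > 0), all(floor_frac <= 1))
  if (length(patent_expiry)) month_index(patent_expiry)
  structure(list(branded_ddd_price = branded_ddd_price,
                 patent_expiry = patent_expiry,
                 decay_per_quarter = decay_per_quarter,
                 floor_frac = floor_frac,
                 strength_exponent = strength_exponent,
                 annual_tablets = annual_tablets,
                 quantity_sdlog = quantity_sdlog,
                 strength_catalogue = strength_catalogue),
            class = "price_dynamics_config")
}

# quarter index helpers (year * 4 + quarter - 1)
qindex_of_month <- function(month) {
  i <- month_index(month)
  (i %/% 12L) * 4L + (i %% 12L) %/% 3L
}

#' Quarterly real price path per DDD for one statin
#'
#' Deterministic skeleton of the synthetic price series: the branded price up
#' to and including the expiry quarter, then geometric decay each quarter
#' down to the floor.
#'
#' @param config a [price_dynamics_config()].
#' @param statin statin name.
#' @param quarters integer vector of quarter indices (`year * 4 + q - 1`), or
#'   a character vector of `"YYYY-MM"` months identifying their quarters.
#' @return numeric vector of real GBP per DDD.
#' @export
ddd_price_path <- function(config, statin, quarters) {
  stopifnot(inherits(config, "price_dynamics_config"))
  if (is.character(quarters)) quarters <- qindex_of_month(quarters)
  branded <- config$branded_ddd_price[[statin]]
  expiry <- config$patent_expiry[statin]
  if (is.na(expiry)) return(rep(branded, length(quarters)))
  qe <- qindex_of_month(unname(expiry))
  k <- pmax(0L, quarters - qe)
  branded * pmax(config$decay_per_quarter[[statin]]^k,
                 config$floor_frac[[statin]])
}

#' Generate a synthetic annual price/quantity table
#'
#' For every year overlapping the window and every statin-strength on the
#' catalogue: the real per-DDD price is the mean of the four quarterly values
#' from [ddd_price_path()]; a tablet of strength `m` costs
#' `price_per_ddd * (m / DDD)^strength_exponent`; dispensed quantities are
#' drawn log-normally around the configured volumes; total spend is quantity
#' times unit price, converted to nominal GBP with the supplied deflators
#' (`NULL` means prices are already nominal-2018, i.e. a flat index of 100).
#' Deterministic given `seed`.
#'
#' @param config a [price_dynamics_config()].
#' @param window character length-2, first and last `"YYYY-MM"` month.
#' @param seed integer seed.
#' @param ddd named DDD vector.
#' @param deflators optional deflator series used to express spend in nominal
#'   terms of each year.
#' @return validated price data.frame (see [read_prices()]).
#' @export
generate_price_series <- function(config, window = c("2003-01", "2018-12"),
                                  seed = 1L, ddd = default_ddd_table(),
                                  deflators = NULL) {
  stopifnot(inherits(config, "price_dynamics_config"))
  if (length(window) != 2L) stop("window must be c(first_month, last_month)",
                                 call. = FALSE)
  if (month_index(window[2L]) < month_index(window[1L])) {
    stop("generate_price_series: empty window", call. = FALSE)
  }
  ddd <- validate_ddd(ddd)
  years <- seq(month_year(window[1L]), month_year(window[2L]))
  with_local_seed(seed, {
    rows <- list()
    for (s in statin_codes()) {
      strengths <- config$strength_catalogue[[s]]
      yearly_ddd_price <- vapply(years, function(y) {
        mean(ddd_price_path(config, s, y * 4L + 0:3))
      }, 0)
      for (k in seq_along(years)) {
        unit <- yearly_ddd_price[k] *
          (strengths / ddd[[s]])^config$strength_exponent
        qty <- stats::rlnorm(length(strengths),
                             meanlog = log(config$annual_tablets[[s]] /
                                             length(strengths)),
                             sdlog = config$quantity_sdlog)
        spend <- unit * qty
        if (!is.null(deflators)) {
          spend <- spend * validate_deflators(deflators)$index[
            match(years[k], deflators$year)] / 100
        }
        rows[[length(rows) + 1L]] <- data.frame(
          year = years[k], statin = s, strength_mg = strengths,
          total_quantity = qty, total_spend_gbp = spend,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_prices(out)
    out
  })
}

#' Default yearly new-patient volume schedule
#'
#' Linear interpolation of annual statin-initiation volumes from 1.15 million
#' (2004) down to 782,000 (2018), the national trend over the study window;
#' 2003 reuses the 2004 value (only its second half falls inside the default
#' window).  Cohort generation multiplies these by `sample_frac`.
#'
#' @param years integer vector of calendar years.
#' @return named numeric vector of new patients per year.
#' @export
default_volume_schedule <- function(years = 2003:2018) {
  v <- stats::approx(x = c(2004, 2018), y = c(1.15e6, 7.82e5),
                     xout = pmax(years, 2004), rule = 2)$y
  stats::setNames(v, years)
}

#' Guideline recommendation history
#'
#' Default national-guidance timeline for initial statin choice: simvastatin
#' recommended from January 2006 (TA-94, reinforced by CG-67 in 2008),
#' atorvastatin from May 2014 (CG-181).  Before January 2006 no statin
#' carries the guideline utility boost.
#'
#' @return data.frame `(from_month, statin)`, rows in chronological order;
#'   each recommendation holds until the next row's month.
#' @export
default_guideline_history <- function() {
  data.frame(from_month = c("2006-01", "2014-05"),
             statin = c("simvastatin", "atorvastatin"),
             stringsAsFactors = FALSE)
}

# 0/1 matrix [statin x month_index] of "recommended at that month"
recommended_matrix <- function(guidelines, month_idx) {
  rec <- matrix(0, nrow = length(statin_codes()), ncol = length(month_idx),
                dimnames = list(statin_codes(), NULL))
  if (is.null(guidelines) || nrow(guidelines) == 0L) return(rec)
  from <- month_index(guidelines$from_month)
  o <- order(from)
  from <- from[o]; who <- guidelines$statin[o]
  for (j in seq_along(month_idx)) {
    k <- findInterval(month_idx[j], from)
    if (k >= 1L) rec[who[k], j] <- 1
  }
  rec
}

#' Cohort-generation configuration
#'
#' Parameters of the synthetic prescribing cohort.  Practices carry normally
#' distributed statin preferences (s.d. `sigma`); new patients arrive as a
#' Poisson stream spreading the yearly volume schedule evenly over months and
#' practices; the initial statin is a multinomial-logit draw with utility
#' `alpha(practice, statin) - beta * real_price_per_DDD + gamma *
#' recommended`; patients then receive one prescription per month (28 tablets
#' of the statin's modal strength) until discontinuation (geometric with the
#' monthly hazard), and in each month after the first are switched to the
#' current policy comparator with probability `switch_prob`.
#'
#' @param seed integer seed driving all draws.
#' @param n_practices number of general practices.
#' @param window character length-2 month range (default the study window
#'   July 2003 -- December 2018).
#' @param yearly_volumes named numeric, national new patients per year.
#' @param sample_frac fraction of the national volume to simulate (default
#'   1/1000, keeping desk-scale runtimes).
#' @param beta price sensitivity, utility per real GBP per DDD (> 0 means
#'   cheaper statins are preferred).
#' @param gamma guideline boost, utility added to the currently recommended
#'   statin.
#' @param sigma s.d. of practice-level preference intercepts (0 = homogeneous
#'   practices).
#' @param discontinuation_hazard monthly probability a patient stops
#'   treatment.
#' @param switch_prob monthly probability an ongoing patient is switched to
#'   the current policy comparator.
#' @param tablets_per_month tablets per monthly prescription.
#' @param modal_strengths named numeric, the single strength (mg) dispensed
#'   per statin.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed = 1L, n_practices = 25L,
                          window = c("2003-07", "2018-12"),
                          yearly_volumes = default_volume_schedule(),
                          sample_frac = 1 / 1000,
                          beta = 5, gamma = 1, sigma = 1,
                          discontinuation_hazard = 0.05,
                          switch_prob = 0.02,
                          tablets_per_month = 28L,
                          modal_strengths = c(atorvastatin = 20,
                                              fluvastatin = 80,
                                              pravastatin = 40,
                                              rosuvastatin = 10,
                                              simvastatin = 40)) {
  stopifnot(n_practices >= 1L, length(window) == 2L,
            discontinuation_hazard >= 0, discontinuation_hazard <= 1,
            switch_prob >= 0, switch_prob <= 1,
            sigma >= 0, beta >= 0, sample_frac > 0,
            all(yearly_volumes >= 0),
            all(statin_codes() %in% names(modal_strengths)))
  month_index(window)
  structure(list(seed = seed, n_practices = as.integer(n_practices),
                 window = window, yearly_volumes = yearly_volumes,
                 sample_frac = sample_frac, beta = beta, gamma = gamma,
                 sigma = sigma,
                 discontinuation_hazard = discontinuation_hazard,
                 switch_prob = switch_prob,
                 tablets_per_month = as.integer(tablets_per_month),
                 modal_strengths = modal_strengths),
            class = "cohort_config")
}

#' Generate a synthetic prescription cohort
#'
#' Simulates the prescribing process described in [cohort_config()] and
#' returns a validated prescription table: one record per patient-month on
#' treatment, the first flagged `first_episode`.  Deterministic given the
#' config seed.  The supplied price series must cover every (statin, year) in
#' the window; a gap is an error naming the year.
#'
#' @param config a [cohort_config()].
#' @param prices price table used both for choice utilities (as real GBP per
#'   DDD) and coverage checking.
#' @param guidelines recommendation history (see
#'   [default_guideline_history()]).
#' @param policy comparator policy driving ongoing-patient switching.
#' @param ddd named DDD vector.
#' @param deflators optional deflator series to express prices in real terms
#'   before they enter the choice model.
#' @return prescription data.frame ordered by issue month.
#' @export
generate_cohort <- function(config, prices,
                            guidelines = default_guideline_history(),
                            policy = comparator_policy(),
                            ddd = default_ddd_table(),
                            deflators = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ddd <- validate_ddd(ddd)
  months <- month_seq(config$window[1L], config$window[2L])
  midx <- month_index(months)
  years <- sort(unique(midx %/% 12L))
  statins <- statin_codes()

  # real price per DDD, [statin x year]
  price_mat <- matrix(NA_real_, nrow = length(statins), ncol = length(years),
                      dimnames = list(statins, as.character(years)))
  for (s in statins) for (k in seq_along(years)) {
    y <- years[k]
    if (!any(prices$statin == s & prices$year == y)) {
      stop(sprintf("generate_cohort: price series does not cover %s in %d",
                   s, y), call. = FALSE)
    }
    p <- cost_per_ddd(s, y, prices, ddd)
    if (!is.null(deflators)) p <- deflate(p, y, deflators)
    price_mat[s, k] <- p
  }
  rec <- recommended_matrix(guidelines, midx)
  yr_col <- match(midx %/% 12L, years)
  vols <- config$yearly_volumes[as.character(years)]
  if (anyNA(vols)) {
    stop("generate_cohort: yearly_volumes missing year(s) ",
         paste(years[is.na(vols)], collapse = ", "), call. = FALSE)
  }
  P <- config$n_practices
  practice_ids <- sprintf("GP%03d", seq_len(P))

  with_local_seed(config$seed, {
    alpha <- matrix(stats::rnorm(P * length(statins), 0, config$sigma),
                    nrow = P, dimnames = list(practice_ids, statins))

    # --- initiations ------------------------------------------------------
    t0 <- integer(0); prac <- integer(0); s0 <- character(0)
    for (j in seq_along(midx)) {
      lambda <- vols[yr_col[j]] * config$sample_frac / 12 / P
      n_new <- stats::rpois(P, lambda)
      if (sum(n_new) == 0L) next
      base_u <- -config$beta * price_mat[, yr_col[j]] + config$gamma * rec[, j]
      for (p in which(n_new > 0L)) {
        pr <- logit_choice_probabilities(alpha[p, ] + base_u)
        draw <- sample(statins, n_new[p], replace = TRUE, prob = pr)
        t0 <- c(t0, rep(midx[j], n_new[p]))
        prac <- c(prac, rep(p, n_new[p]))
        s0 <- c(s0, draw)
      }
    }
    n_pat <- length(t0)
    if (n_pat == 0L) {
      stop("generate_cohort: no patients generated; increase sample_frac",
           call. = FALSE)
    }
    # treatment duration in months (>= 1), truncated at the window end
    dur <- 1L + stats::rgeom(n_pat, max(config$discontinuation_hazard, 1e-12))
    dur <- pmin(dur, midx[length(midx)] - t0 + 1L)
    t_end <- t0 + dur - 1L

    # --- monthly follow-up ------------------------------------------------
    patient_ids <- sprintf("PT%06d", seq_len(n_pat))
    cur <- s0
    out <- vector("list", length(midx))
    for (j in seq_along(midx)) {
      m <- midx[j]
      active <- which(t0 <= m & m <= t_end)
      if (!length(active)) next
      ongoing <- active[t0[active] < m]
      if (length(ongoing) && config$switch_prob > 0) {
        flip <- stats::runif(length(ongoing)) < config$switch_prob
        if (any(flip)) {
          cur[ongoing[flip]] <- comparator_for(months[j], policy)
        }
      }
      out[[j]] <- data.frame(
        patient_id = patient_ids[active],
        practice_id = practice_ids[prac[active]],
        issue_month = months[j],
        statin = cur[active],
        strength_mg = unname(config$modal_strengths[cur[active]]),
        tablets = config$tablets_per_month,
        days_supplied = 28L,
        first_episode = t0[active] == m,
        stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, out)
    rownames(records) <- NULL
    validate_prescriptions(records)
    records
  })
}

#' Fit the initiation choice model to a cohort
#'
#' Maximum-likelihood conditional logit for first-episode statin choice with
#' two coefficients: price sensitivity `beta` on the real acquisition cost
#' per DDD, and guideline boost `gamma` on the recommended-statin indicator.
#' Observations are aggregated to (month, statin) counts, so the fit is fast
#' at any cohort size.  Intended for generator validation at `sigma = 0`
#' (homogeneous practices), where these are the only utility terms.
#'
#' @param records prescription table; only first episodes are used.
#' @param prices,guidelines,ddd,deflators as in [generate_cohort()].
#' @return list with elements `beta`, `gamma`, `logLik`, `convergence`
#'   (0 = converged).
#' @export
fit_initiation_logit <- function(records, prices,
                                 guidelines = default_guideline_history(),
                                 ddd = default_ddd_table(),
                                 deflators = NULL) {
  fe <- records[records$first_episode, , drop = FALSE]
  if (nrow(fe) == 0L) stop("fit_initiation_logit: no first episodes", call. = FALSE)
  statins <- statin_codes()
  midx <- sort(unique(month_index(fe$issue_month)))
  years <- sort(unique(midx %/% 12L))
  price_mat <- matrix(NA_real_, length(statins), length(years),
                      dimnames = list(statins, as.character(years)))
  for (s in statins) for (k in seq_along(years)) {
    p <- cost_per_ddd(s, years[k], prices, ddd)
    if (!is.null(deflators)) p <- deflate(p, years[k], deflators)
    price_mat[s, k] <- p
  }
  rec <- recommended_matrix(guidelines, midx)
  yr_col <- match(midx %/% 12L, years)
  counts <- table(factor(month_index(fe$issue_month), levels = midx),
                  factor(fe$statin, levels = statins))
  counts <- t(unclass(counts))  # [statin x month]

  nll <- function(par) {
    ll <- 0
    for (j in seq_along(midx)) {
      u <- -par[1L] * price_mat[, yr_col[j]] + par[2L] * rec[, j]
      u <- u - max(u)
      ll <- ll + sum(counts[, j] * (u - log(sum(exp(u)))))
    }
    -ll
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS")
  list(beta = fit$par[1L], gamma = fit$par[2L], logLik = -fit$value,
       convergence = fit$convergence)
}
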