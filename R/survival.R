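#' Apply registry-style cohort exclusions and the age-99 cap
#'
#' Removes records known only from autopsy or death certificate (DCO),
#' records with no follow-up (zero survival time), and - when
#' \code{single_primary_only} is set - patients with more than one primary
#' tumor.  Follow-up is additionally truncated at the month a patient's
#' attained age reaches 99: later deaths are recoded as censored at that
#' point.
#'
#' @param cohort patient cohort (see [generate_cohort()] for the columns).
#' @param single_primary_only drop patients with \code{n_primaries > 1}.
#' @return the filtered cohort.
#' @export
apply_cohort_filters <- function(cohort, single_primary_only = FALSE) {
  d <- cohort[!(cohort$source %in% c("autopsy", "DCO")), , drop = FALSE]
  d <- d[d$surv_months > 0, , drop = FALSE]
  if (single_primary_only) d <- d[d$n_primaries == 1L, , drop = FALSE]
  cap <- 12 * (99 - d$diag_age)
  over <- d$surv_months > cap
  d$surv_months[over] <- cap[over]
  d$status[over] <- "alive"
  d$cause[over] <- NA_character_
  rownames(d) <- NULL
  d
}

# Fast life-table lookup: returns q for (stratum, year, age) triples, with
# calendar years clamped to the library span (last year carried forward)
# and ages capped at the library maximum (never beyond 99).
lt_lookup <- function(lt_library, stratum, year, age) {
  strat_lev <- unique(lt_library$stratum)
  si <- match(lt_library$stratum, strat_lev)
  key_lib <- (si * 200L + (lt_library$year - 1800L)) * 200L + lt_library$age
  yr <- pmax(pmin(year, max(lt_library$year)), min(lt_library$year))
  max_age <- max(lt_library$age)
  si_q <- match(stratum, strat_lev)
  if (anyNA(si_q)) stop("patient stratum not found in life-table library")
  key_q <- (si_q * 200L + (yr - 1800L)) * 200L + pmin(age, max_age)
  q <- lt_library$qx[match(key_q, key_lib)]
  if (anyNA(q)) stop("life-table library does not cover some attained age/year")
  q
}

new_survival_curve <- function(kind, interval_months, interval, n_risk,
                               events, estimate, se = NA_real_) {
  data.frame(kind = kind, interval = interval,
             start_months = (interval - 1) * interval_months,
             end_months = interval * interval_months,
             n_risk = n_risk, events = events,
             estimate = estimate, se = se)
}

#' Ederer II expected survival
#'
#' For each follow-up interval \code{k}, the conditional expected survival
#' is the mean - over patients still under follow-up at the start of the
#' interval - of their individual probability of surviving the interval,
#' read from their matched life table at current attained age (diagnosis
#' age plus elapsed whole years, capped at 99) and calendar year
#' (similarly advanced, with the library's last year carried forward).
#' Cumulative expected survival is the product of the conditional terms.
#' If the risk set empties before \code{n_intervals} the curve truncates
#' with a warning.
#'
#' @param cohort filtered patient cohort with a \code{stratum} column
#'   matching the library.
#' @param lt_library data frame with columns \code{stratum}, \code{year},
#'   \code{age}, \code{qx}.
#' @param n_intervals number of follow-up intervals.
#' @param interval_months interval length in months (12 = annual).
#' @return a survival-curve data frame (\code{kind = "expected"}).
#' @export
expected_survival_ederer2 <- function(cohort, lt_library, n_intervals,
                                      interval_months = 12) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  max_year <- max(lt_library$year)
  p_cond <- n_risk <- numeric(0)
  for (k in seq_len(n_intervals)) {
    start <- (k - 1) * interval_months
    at <- cohort$surv_months > start
    if (!any(at)) {
      warning("risk set empty at interval ", k, "; expected curve truncated")
      break
    }
    elapsed <- start %/% 12
    age_k <- pmin(cohort$diag_age[at] + elapsed, 99L)
    year_k <- cohort$diag_year[at] + elapsed
    q <- lt_lookup(lt_library, cohort$stratum[at], year_k, age_k)
    p_cond <- c(p_cond, mean((1 - q)^(interval_months / 12)))
    n_risk <- c(n_risk, sum(at))
  }
  ks <- seq_along(p_cond)
  new_survival_curve("expected", interval_months, ks, n_risk,
                     events = NA_real_, estimate = cumprod(p_cond))
}

#' Observed all-cause survival by the actuarial (life-table) method
#'
#' Classic actuarial estimator on fixed intervals: within interval
#' \code{k} with \code{n_k} patients entering, \code{d_k} deaths and
#' \code{c_k} censorings, the conditional survival is
#' \code{1 - d_k / (n_k - c_k/2)} (censored patients credited half an
#' interval at risk), multiplied cumulatively.  Standard errors follow
#' Greenwood's formula on the effective denominators.
#'
#' @inheritParams expected_survival_ederer2
#' @return a survival-curve data frame (\code{kind = "observed"}).
#' @export
observed_survival_actuarial <- function(cohort, n_intervals,
                                        interval_months = 12) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  dead <- cohort$status == "dead"
  t <- cohort$surv_months
  p <- varsum <- n_risk <- d_k <- numeric(n_intervals)
  cumvar <- 0
  for (k in seq_len(n_intervals)) {
    start <- (k - 1) * interval_months
    end <- k * interval_months
    at <- t > start
    n_k <- sum(at)
    d <- sum(at & dead & t <= end)
    cns <- sum(at & !dead & t <= end)
    n_eff <- n_k - cns / 2
    if (n_eff <= 0) {
      n_intervals <- k - 1L
      warning("effective risk set empty at interval ", k,
              "; observed curve truncated")
      break
    }
    p[k] <- 1 - d / n_eff
    n_risk[k] <- n_k
    d_k[k] <- d
    if (n_eff > d) cumvar <- cumvar + d / (n_eff * (n_eff - d))
    varsum[k] <- cumvar
  }
  ks <- seq_len(n_intervals)
  est <- cumprod(p[ks])
  new_survival_curve("observed", interval_months, ks, n_risk[ks], d_k[ks],
                     est, se = est * sqrt(varsum[ks]))
}

#' Relative survival as the ratio of observed to expected survival
#'
#' @param observed,expected survival curves on identical interval grids
#'   (from [observed_survival_actuarial()] and
#'   [expected_survival_ederer2()]).
#' @return a survival-curve data frame (\code{kind = "relative"}); values
#'   may exceed 1.  The expected curve is treated as fixed, so the
#'   standard error is the observed one scaled by the expected survival.
#' @export
relative_survival <- function(observed, expected) {
  n <- min(nrow(observed), nrow(expected))
  o <- observed[seq_len(n), ]; e <- expected[seq_len(n), ]
  if (!isTRUE(all.equal(o$end_months, e$end_months)))
    stop("observed and expected curves are on different interval grids")
  if (any(e$estimate <= 0)) stop("expected survival is zero")
  new_survival_curve("relative", o$end_months[1] - o$start_months[1],
                     o$interval, o$n_risk, o$events,
                     o$estimate / e$estimate, se = o$se / e$estimate)
}

#' Cause-specific survival (Kaplan-Meier)
#'
#' Kaplan-Meier estimator with death from the cancer as the event; deaths
#' from other causes, end of study, and the age-99 cap count as
#' censorings.  Estimation is delegated to \code{survival::survfit}
#' (Greenwood standard errors, log-log 95% intervals) and the curve is
#' read off at the interval endpoints.
#'
#' @inheritParams expected_survival_ederer2
#' @param unknown_as_cancer treat an unknown cause of death as a cancer
#'   death (default \code{FALSE}: unknown counts as other-cause, i.e. a
#'   censoring).
#' @return a survival-curve data frame (\code{kind = "cause_specific"})
#'   with \code{lower}/\code{upper} 95% confidence columns.
#' @export
cause_specific_survival <- function(cohort, n_intervals, interval_months = 12,
                                    unknown_as_cancer = FALSE) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  is_cancer <- cohort$status == "dead" &
    (cohort$cause %in% "cancer" |
       (unknown_as_cancer & (is.na(cohort$cause) | cohort$cause == "unknown")))
  fit <- survival::survfit(
    survival::Surv(cohort$surv_months, is_cancer) ~ 1,
    conf.type = "log-log")
  times <- seq_len(n_intervals) * interval_months
  sm <- summary(fit, times = times, extend = TRUE)
  out <- new_survival_curve("cause_specific", interval_months,
                            seq_len(n_intervals), sm$n.risk, sm$n.event,
                            sm$surv, se = sm$std.err)
  out$lower <- sm$lower
  out$upper <- sm$upper
  out
}

#' Suppress survival estimates for small groups
#'
#' Registry reporting convention: groups with fewer than \code{min_n}
#' patients at diagnosis report no survival statistics.
#'
#' @param curves named list of survival-curve data frames, one per group.
#' @param group_sizes named numeric vector of patients at diagnosis, with
#'   the same names as \code{curves}.
#' @param min_n minimum reportable group size (default 50; groups of
#'   exactly \code{min_n} are reported).
#' @return the list with suppressed groups' \code{estimate}, \code{se}
#'   (and interval columns, if present) set to \code{NA} and a logical
#'   \code{suppressed} column added throughout.
#' @export
suppress_small_groups <- function(curves, group_sizes, min_n = 50) {
  if (!all(names(curves) %in% names(group_sizes)))
    stop("group_sizes must cover every curve")
  lapply(stats::setNames(names(curves), names(curves)), function(g) {
    cv <- curves[[g]]
    cv$suppressed <- group_sizes[[g]] < min_n
    if (group_sizes[[g]] < min_n)
      cv[intersect(c("estimate", "se", "lower", "upper"), names(cv))] <- NA_real_
    cv
  })
}
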