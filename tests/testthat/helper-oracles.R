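# Shared fixtures and independent oracles, built in code.

# A life table with the same death probability at every age 0-99.
const_lt <- function(q) data.frame(age = 0:99, qx = rep(q, 100))

# Three-stratum toy life-table library with Gompertz-like mortality,
# distinct levels per stratum and a mild calendar trend.
toy_lt_library <- function(years = 2000:2005) {
  shifts <- c(A = 0, B = 0.35, C = -0.4)
  do.call(rbind, lapply(names(shifts), function(s) {
    do.call(rbind, lapply(years, function(y) {
      m <- exp(-9 + 0.085 * (0:99) + shifts[[s]] - 0.01 * (y - 2000))
      data.frame(stratum = s, year = y, age = 0:99, qx = 1 - exp(-m))
    }))
  }))
}

# Brute-force Ederer II: per-interval loop over patients, averaging each
# at-risk patient's expected interval survival from their matched table
# (attained age = diagnosis age + elapsed whole years capped at the table
# maximum; calendar year clamped to the library span), then multiplying.
oracle_ederer2 <- function(cohort, lib, n_intervals, interval_months = 12) {
  out <- numeric(0)
  run <- 1
  for (k in seq_len(n_intervals)) {
    start <- (k - 1) * interval_months
    ps <- numeric(0)
    for (i in seq_len(nrow(cohort))) {
      if (cohort$surv_months[i] > start) {
        el <- start %/% 12
        a <- min(cohort$diag_age[i] + el, max(lib$age))
        y <- min(max(cohort$diag_year[i] + el, min(lib$year)), max(lib$year))
        q <- lib$qx[lib$stratum == cohort$stratum[i] & lib$year == y &
                      lib$age == a]
        ps <- c(ps, (1 - q)^(interval_months / 12))
      }
    }
    if (length(ps) == 0L) break
    run <- run * mean(ps)
    out <- c(out, run)
  }
  out
}

# Random small cohort over the toy library's strata.
random_small_cohort <- function(n, seed) {
  set.seed(seed)
  dead <- stats::runif(n) < 0.6
  data.frame(id = seq_len(n),
             diag_year = sample(1999:2007, n, replace = TRUE),
             diag_age = sample(40:97, n, replace = TRUE),
             sex = "f", race = "all", county = 1L,
             stratum = sample(c("A", "B", "C"), n, replace = TRUE),
             surv_months = stats::runif(n, 0.5, 130),
             status = ifelse(dead, "dead", "alive"),
             cause = ifelse(dead, sample(c("cancer", "other"), n, TRUE), NA),
             source = "other", n_primaries = 1L)
}

# A flat mortality surface: every age, year and quintile at constant rate m.
flat_surface <- function(m, ...) {
  true_surface(age_knot_values = rep(log(m), 6), year_slope = 0,
               ses_effects = c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0, Q5 = 0),
               ses_age_slopes = c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0, Q5 = 0),
               ...)
}
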