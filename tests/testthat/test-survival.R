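mk_cohort <- function(surv_months, status, cause = NULL, diag_age = 60,
                      diag_year = 2000, source = "other", n_primaries = 1L,
                      stratum = "A") {
  n <- length(surv_months)
  data.frame(id = seq_len(n), diag_year = diag_year, diag_age = diag_age,
             sex = "f", race = "all", county = 1L, stratum = stratum,
             surv_months = surv_months, status = status,
             cause = if (is.null(cause)) ifelse(status == "dead", "other", NA)
                     else cause,
             source = source, n_primaries = n_primaries)
}

test_that("registry exclusions and the age-99 cap are applied", {
  co <- mk_cohort(c(10, 20, 0, 30, 40, 50),
                  c("dead", "dead", "dead", "dead", "dead", "alive"),
                  source = c("other", "DCO", "other", "autopsy", "other", "other"),
                  diag_age = c(60, 60, 60, 60, 97, 60),
                  n_primaries = c(1L, 1L, 1L, 1L, 1L, 3L))
  f <- apply_cohort_filters(co)
  expect_identical(f$id, c(1L, 5L, 6L))          # DCO, autopsy, zero-time gone
  # the 97-year-old dead at 40 months is censored when attained age hits 99
  expect_equal(f$surv_months[f$id == 5L], 24)
  expect_identical(f$status[f$id == 5L], "alive")
  f2 <- apply_cohort_filters(co, single_primary_only = TRUE)
  expect_false(3L %in% f2$n_primaries)
})

test_that("Ederer II reproduces closed-form expected survival", {
  lib <- data.frame(stratum = "A", year = 2000, age = 0:99, qx = 0.1)
  one <- mk_cohort(200, "alive")
  e <- expected_survival_ederer2(one, lib, 5, 12)
  expect_equal(e$estimate, 0.9^(1:5), tolerance = 1e-12)

  lib0 <- data.frame(stratum = "A", year = 2000, age = 0:99, qx = 0)
  many <- mk_cohort(c(5, 40, 200), c("dead", "dead", "alive"))
  e0 <- expected_survival_ederer2(many, lib0, 10, 12)
  expect_true(all(e0$estimate == 1))
})

test_that("Ederer II equals the brute-force oracle on staggered small cohorts", {
  lib <- toy_lt_library()
  st <- mk_cohort(c(8, 30, 70), c("dead", "dead", "alive"),
                  diag_age = c(72, 55, 90), diag_year = c(2000, 2003, 2005),
                  stratum = c("A", "B", "C"))
  got <- expected_survival_ederer2(st, lib, 6, 12)
  expect_equal(got$estimate, oracle_ederer2(st, lib, 6, 12), tolerance = 1e-12)

  # monthly intervals too
  gotm <- expected_survival_ederer2(st, lib, 24, 1)
  expect_equal(gotm$estimate, oracle_ederer2(st, lib, 24, 1), tolerance = 1e-12)
})

test_that("the actuarial estimator applies half-interval censoring credit", {
  none <- mk_cohort(rep(130, 10), rep("alive", 10))
  expect_true(all(observed_survival_actuarial(none, 10, 12)$estimate == 1))

  two <- mk_cohort(c(3, 9, rep(130, 8)), c("dead", "dead", rep("alive", 8)))
  expect_equal(observed_survival_actuarial(two, 1, 12)$estimate, 0.8)

  mixed <- mk_cohort(c(3, 5, 9, rep(130, 7)),
                     c("dead", "alive", "alive", rep("alive", 7)))
  expect_equal(observed_survival_actuarial(mixed, 1, 12)$estimate,
               1 - 1 / (10 - 2 / 2))
})

test_that("relative survival is the pointwise observed/expected ratio", {
  obs <- observed_survival_actuarial(
    mk_cohort(c(6, rep(130, 9)), c("dead", rep("alive", 9))), 10, 12)
  lib0 <- data.frame(stratum = "A", year = 2000, age = 0:99, qx = 0)
  exp0 <- expected_survival_ederer2(
    mk_cohort(c(6, rep(130, 9)), c("dead", rep("alive", 9))), lib0, 10, 12)
  rs <- relative_survival(obs, exp0)
  expect_equal(rs$estimate, obs$estimate)      # expected = 1 passes observed through

  scaled <- exp0; scaled$estimate <- rep(0.8, 10)
  expect_equal(relative_survival(obs, scaled)$estimate[10],
               obs$estimate[10] / 0.8)
  expect_equal(0.5 / 0.8, 0.625)               # the 10-year headline arithmetic
  zero <- exp0; zero$estimate[3] <- 0
  expect_error(relative_survival(obs, zero), "zero")
})

test_that("cause-specific survival censors other-cause deaths", {
  noc <- mk_cohort(c(10, 50, 130), c("dead", "dead", "alive"),
                   cause = c("other", "other", NA))
  expect_true(all(cause_specific_survival(noc, 10, 12)$estimate == 1))

  km <- mk_cohort(c(5, 17, rep(130, 8)), c("dead", "dead", rep("alive", 8)),
                  cause = c("cancer", "cancer", rep(NA, 8)))
  cs <- cause_specific_survival(km, 2, 12)
  expect_equal(cs$estimate, c(0.9, 0.8))

  # an other-cause death shrinks the risk set without registering an event
  mix <- mk_cohort(c(6, 18, 60), c("dead", "dead", "alive"),
                   cause = c("other", "cancer", NA))
  cs2 <- cause_specific_survival(mix, 2, 12)
  expect_equal(cs2$estimate[2], 0.5)           # 1 event among 2 still at risk

  # unknown causes count as cancer only when asked to
  unk <- mk_cohort(c(12, 130), c("dead", "alive"), cause = c("unknown", NA))
  expect_equal(cause_specific_survival(unk, 1, 12)$estimate, 1)
  expect_equal(cause_specific_survival(unk, 1, 12,
                                       unknown_as_cancer = TRUE)$estimate, 0.5)
})

test_that("groups under the reporting minimum are suppressed", {
  cv <- observed_survival_actuarial(mk_cohort(rep(130, 49), rep("alive", 49)), 5, 12)
  out <- suppress_small_groups(list(small = cv, large = cv),
                               c(small = 49, large = 50))
  expect_true(all(is.na(out$small$estimate)))
  expect_true(all(out$small$suppressed))
  expect_equal(out$large$estimate, cv$estimate)   # exactly 50 is reported
  none <- suppress_small_groups(list(small = cv), c(small = 49), min_n = 0)
  expect_false(any(none$small$suppressed))
})
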