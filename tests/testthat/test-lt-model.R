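panel_3yr <- data.frame(county = 1L, state = "S01", age = 50L,
                        year = 1991:1993, sex = "m", race = "w",
                        quintile = 1L, deaths = c(10, 20, 30),
                        population = c(1000, 1000, 1000))

test_that("calendar-year grouping sums deaths and exposure around the center", {
  g <- aggregate_rates(panel_3yr, 1992, window = 3)
  expect_equal(g$deaths, 60)
  expect_equal(g$population, 3000)
  expect_equal(g$year, 1992)

  # window of one is the identity on counts
  g1 <- aggregate_rates(panel_3yr, 1992, window = 1)
  expect_equal(g1$deaths, 20)
  expect_equal(g1$population, 1000)

  # centering on the first year truncates to the available side
  ge <- aggregate_rates(panel_3yr, 1991, window = 3)
  expect_equal(ge$deaths, 30)
  expect_equal(ge$population, 2000)

  expect_error(aggregate_rates(panel_3yr, 1992, window = 2), "odd")
  expect_error(aggregate_rates(panel_3yr, 2050, window = 3), "empty")
})

test_that("a saturated single-cell fit returns the Poisson MLE D/P", {
  cell <- data.frame(county = 1L, age = 50L, year = 2000L,
                     deaths = 50, population = 1000)
  spec <- lt_model_spec("national", "none", age_knots = NULL, year_knots = NULL)
  fit <- fit_poisson_lt(cell, spec)
  expect_equal(unname(exp(fit$coefficients["(Intercept)"])), 0.05,
               tolerance = 1e-10)
})

test_that("a panel with no deaths is unidentifiable and rejected", {
  dead0 <- data.frame(county = 1:5, age = 50L, year = 2000L,
                      deaths = 0, population = 1000)
  spec <- lt_model_spec("national", "none", age_knots = NULL, year_knots = NULL)
  expect_error(fit_poisson_lt(dead0, spec), "zero total deaths")
})

test_that("predicted log rates equal the design-times-coefficient product", {
  s <- true_surface()
  cfg <- sim_config(15, c(5e3, 2e4), years = 1991:2013, seed = 5)
  g <- aggregate_rates(generate_mortality_panel(cfg, s), seq(1992, 2013, 3))
  spec <- lt_model_spec("state", "quintile5")
  fit <- fit_poisson_lt(g, spec)

  age <- c(30, 47, 84); year <- c(1995, 2005, 2010); lev <- c("Q1", "Q3", "Q5")
  pred <- predict_log_rate(fit, age, year, lev)
  # independent evaluation: assemble the basis by hand and multiply
  co <- fit$coefficients
  for (i in 1:3) {
    ab <- rcs_basis(age[i], spec$age_knots)
    yb <- rcs_basis(year[i], spec$year_knots)
    x <- c(1, ab[1, ], yb[1, ])
    manual <- sum(x * co[1:(1 + ncol(ab) + ncol(yb))])
    if (lev[i] != "Q5")
      manual <- manual + co[paste0("ses", lev[i])] +
        co[paste0("ses", lev[i], ":age")] * age[i]
    expect_equal(pred[i], unname(manual), tolerance = 1e-10)
  }
  expect_error(predict_log_rate(fit, 50, 2000, "Q9"), "unknown SES")
})

test_that("canonical-link score equations balance deaths within each SES level", {
  s <- true_surface()
  cfg <- sim_config(20, c(2e3, 2e4), years = 1995:2005, seed = 9)
  g <- aggregate_rates(generate_mortality_panel(cfg, s), c(1996, 1999, 2002, 2004))
  spec <- lt_model_spec("state", "quintile5",
                        year_knots = c(1996, 1999, 2002, 2004))
  fit <- fit_poisson_lt(g, spec)
  g <- g[g$population > 0, ]
  obs <- tapply(g$deaths, g$quintile, sum)
  fitted <- tapply(fit$fitted_deaths, g$quintile, sum)
  expect_equal(as.numeric(fitted / obs), rep(1, 5), tolerance = 1e-6)
})

test_that("splitting a county into identical halves leaves the fit unchanged", {
  s <- true_surface()
  cfg <- sim_config(10, c(1e4, 2e4), years = 1998:2002, seed = 21)
  p <- generate_mortality_panel(cfg, s)
  spec <- lt_model_spec("state", "quintile5", year_knots = c(1998, 2000, 2002))
  f1 <- fit_poisson_lt(p, spec)
  # split county 1's rows into two pseudo-counties with half the exposure
  p1 <- p[p$county == 1, ]
  even <- p1$deaths %% 2 == 0
  a <- p1; a$population <- a$population / 2; a$deaths <- floor(a$deaths / 2)
  b <- p1; b$population <- b$population / 2; b$deaths <- ceiling(b$deaths / 2)
  b$county <- max(p$county) + 1L
  f2 <- fit_poisson_lt(rbind(p[p$county != 1, ], a, b), spec)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-8)
})

test_that("deviance never increases moving up the SES ladder on the same data", {
  s <- true_surface()
  cfg <- sim_config(25, c(5e3, 2e4), years = 1995:2009, seed = 13)
  g <- aggregate_rates(generate_mortality_panel(cfg, s), seq(1996, 2008, 3))
  specs <- list(lt_model_spec("state", "none", year_knots = c(1996, 2002, 2008)),
                lt_model_spec("state", "level2", year_knots = c(1996, 2002, 2008)),
                lt_model_spec("state", "quintile5", year_knots = c(1996, 2002, 2008)))
  dev <- vapply(specs, function(sp) fit_poisson_lt(g, sp)$deviance, numeric(1))
  expect_true(all(diff(dev) <= 1e-6))
})

test_that("single-seed fit recovers the generating coefficients", {
  s <- true_surface()
  cfg <- sim_config(20, c(2e4, 6e4), years = 1991:2013, seed = 3)
  g <- aggregate_rates(generate_mortality_panel(cfg, s), seq(1992, 2013, 3))
  fit <- fit_poisson_lt(g, lt_model_spec("state", "quintile5"))
  tc <- true_coefficients(s, fit$spec)
  z <- abs(fit$coefficients[names(tc)] - tc) / sqrt(diag(fit$vcov))[names(tc)]
  expect_true(all(z < 5))
  expect_lt(stats::median(z), 2.5)
})

test_that("the model ladder picks the most detailed feasible spec", {
  tot <- expand.grid(state = c("S1", "S2"), quintile = 1:5)
  tot$region = "R1"
  tot$deaths <- 5000
  expect_identical(select_model_spec(tot)$ses_form, "quintile5")
  expect_identical(select_model_spec(tot)$area_level, "state")

  # sparse high-SES state cells drop state-level quintiles to two levels
  tot15 <- tot
  tot15$deaths[tot15$state == "S2" & tot15$quintile == 4] <- 3
  expect_identical(select_model_spec(tot15)$ses_form, "level2")
  expect_identical(select_model_spec(tot15)$area_level, "state")

  # a state too small for any state model falls back to regional quintiles
  tot2 <- tot
  tot2$deaths[tot2$state == "S2"] <- 10
  sel2 <- select_model_spec(tot2)
  expect_identical(sel2$area_level, "region")
  expect_identical(sel2$ses_form, "quintile5")

  # sparse everywhere except pooled national two-level
  tot3 <- tot
  tot3$deaths <- ifelse(tot3$state == "S1",
                        ifelse(tot3$quintile == 5, 4, 30), 4)
  sel3 <- select_model_spec(tot3, min_cell_deaths = 25, min_total_deaths = 60)
  expect_identical(sel3$area_level, "national")
  expect_identical(sel3$ses_form, "level2")

  tot4 <- tot; tot4$deaths <- 0
  expect_error(select_model_spec(tot4), "no candidate")
})
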