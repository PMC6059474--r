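#' Define a known ("true") log-mortality surface
#'
#' The generator's ground truth is expressed in exactly the parameterization
#' the mortality model estimates, so recovery can be checked coefficient by
#' coefficient.  The age effect \code{f(age)} is the natural cubic spline
#' through the supplied log-rate anchors at the age knots (linear beyond the
#' boundary knots, hence defined and finite over ages 0-99); calendar time
#' enters as a linear log-rate trend; each SES quintile adds a main log-rate
#' offset and a linear-age interaction slope.  The reference quintile must
#' carry a zero offset and a zero slope.
#'
#' Defaults approximate adult US male all-cause mortality around the 2000s
#' with a mild secular decline and a positive mortality gradient toward low
#' SES that narrows with age.
#'
#' @param age_knots strictly increasing knots (>= 3).
#' @param age_knot_values log rates at the knots.
#' @param year_slope per-year change in log rate.
#' @param year_ref calendar year at which \code{g(year) = 0}.
#' @param ses_effects named log-rate offsets for Q1-Q5 (reference = 0).
#' @param ses_age_slopes named per-year-of-age interaction slopes for Q1-Q5
#'   (reference = 0).
#' @param sex,race labels for the stratum the surface describes.
#' @param ses_ref reference quintile label.
#' @return object of class \code{"true_surface"}.
#' @export
true_surface <- function(age_knots = c(32, 40, 55, 70, 77, 82),
                         age_knot_values = c(-6.5, -6.0, -4.8, -3.7, -3.1, -2.6),
                         year_slope = -0.01, year_ref = 2002,
                         ses_effects = c(Q1 = 0.4, Q2 = 0.25, Q3 = 0.15,
                                         Q4 = 0.05, Q5 = 0),
                         ses_age_slopes = c(Q1 = -0.002, Q2 = -0.0015,
                                            Q3 = -0.001, Q4 = -0.0005, Q5 = 0),
                         sex = "male", race = "white", ses_ref = "Q5") {
  if (length(age_knot_values) != length(age_knots))
    stop("one log-rate anchor per age knot required")
  qn <- paste0("Q", 1:5)
  stopifnot(identical(sort(names(ses_effects)), qn),
            identical(sort(names(ses_age_slopes)), qn))
  if (ses_effects[ses_ref] != 0 || ses_age_slopes[ses_ref] != 0)
    stop("reference quintile must have zero offset and zero slope")
  # natural-spline interpolation through the anchors: k knots, k params
  A <- cbind(1, rcs_basis(age_knots, age_knots))
  fc <- solve(A, age_knot_values)
  structure(list(age_knots = age_knots, age_knot_values = age_knot_values,
                 f_coef = fc, year_slope = year_slope, year_ref = year_ref,
                 ses_effects = ses_effects[qn],
                 ses_age_slopes = ses_age_slopes[qn],
                 sex = sex, race = race, ses_ref = ses_ref),
            class = "true_surface")
}

#' Evaluate a true surface's log mortality rate
#'
#' @param surface a [true_surface()].
#' @param age,year numeric vectors (recycled).
#' @param quintile integer 1-5 or label \code{"Q1"}..\code{"Q5"} (recycled).
#' @return log rate vector.
#' @export
surface_log_rate <- function(surface, age, year, quintile = surface$ses_ref) {
  n <- max(length(age), length(year), length(quintile))
  age <- rep_len(age, n); year <- rep_len(year, n)
  quintile <- rep_len(quintile, n)
  q <- if (is.numeric(quintile)) paste0("Q", quintile) else as.character(quintile)
  if (!all(q %in% names(surface$ses_effects))) stop("bad quintile")
  f <- drop(cbind(1, rcs_basis(age, surface$age_knots)) %*% surface$f_coef)
  f + surface$year_slope * (year - surface$year_ref) +
    surface$ses_effects[q] + surface$ses_age_slopes[q] * age
}

#' True model coefficients implied by a surface
#'
#' Maps a [true_surface()] into the coefficient vector of the design built
#' by [fit_poisson_lt()] for a given spec, for coefficient-recovery checks.
#' Requires the spec's age knots to equal the surface's and the spec's SES
#' reference to be the surface's reference quintile; the surface's linear
#' year trend lands on the year spline's linear column (nonlinear year
#' coefficients are zero).
#'
#' @param surface a [true_surface()].
#' @param spec an [lt_model_spec()] with \code{ses_form = "quintile5"} or
#'   \code{"none"}.
#' @return named coefficient vector matching the fitted design.
#' @export
true_coefficients <- function(surface, spec) {
  if (!identical(as.numeric(spec$age_knots), as.numeric(surface$age_knots)))
    stop("spec age knots must match the surface knots")
  if (is.null(spec$year_knots)) stop("spec must include a year spline")
  co <- c("(Intercept)" = unname(surface$f_coef[1]) -
            surface$year_slope * surface$year_ref)
  k <- length(surface$age_knots)
  nm <- c("age", if (k > 2) paste0("age_nl", seq_len(k - 2)))
  co <- c(co, stats::setNames(surface$f_coef[-1], nm))
  ky <- length(spec$year_knots)
  co <- c(co, stats::setNames(c(surface$year_slope, rep(0, ky - 2)),
                              c("year", if (ky > 2) paste0("year_nl", seq_len(ky - 2)))))
  if (spec$ses_form == "quintile5") {
    if (spec$ses_ref != surface$ses_ref)
      stop("spec SES reference must match the surface reference quintile")
    for (lev in setdiff(spec$ses_levels, spec$ses_ref)) {
      co[paste0("ses", lev)] <- unname(surface$ses_effects[lev])
      co[paste0("ses", lev, ":age")] <- unname(surface$ses_age_slopes[lev])
    }
  } else if (spec$ses_form != "none") {
    stop("true coefficients are defined for quintile5 or none specs")
  }
  co
}

#' Simulation configuration for county mortality panels
#'
#' @param n_counties number of counties (>= 1).
#' @param population_range length-2 positive range; each county draws one
#'   population size, used for every age-year cell it contributes.
#' @param years inclusive span of calendar years.
#' @param ages single ages simulated (default 30-84, the model's fitting
#'   range).
#' @param quintile_scheme \code{"quintile5"} or \code{"level2"}; recorded
#'   so downstream fits know the intended SES coding.
#' @param seed integer RNG seed.
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_counties, population_range = c(1e3, 1e5),
                       years = 1990:2014, ages = 30:84,
                       quintile_scheme = c("quintile5", "level2"),
                       seed = 1L) {
  quintile_scheme <- match.arg(quintile_scheme)
  if (n_counties < 1) stop("n_counties must be >= 1")
  if (length(population_range) != 2 || any(population_range <= 0) ||
      diff(population_range) < 0)
    stop("population_range must be a positive min/max pair")
  if (length(years) < 1) stop("need at least one year")
  structure(list(n_counties = as.integer(n_counties),
                 population_range = population_range,
                 years = as.integer(years), ages = as.integer(ages),
                 quintile_scheme = quintile_scheme, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a county mortality panel from a known surface
#'
#' Each county draws a population size uniformly from the configured range
#' and an SES quintile (balanced across counties), then death counts are
#' drawn independently per county-age-year cell as
#' \code{Poisson(population * exp(log rate))}; draws exceeding the cell
#' population are rejected and redrawn so counts never exceed exposure.
#' Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param surface a [true_surface()] supplying the log rates.
#' @return mortality panel: data frame with columns \code{county},
#'   \code{state}, \code{age}, \code{year}, \code{sex}, \code{race},
#'   \code{quintile}, \code{deaths}, \code{population}; the generating
#'   seed is attached as attribute \code{"seed"}.
#' @export
generate_mortality_panel <- function(config, surface) {
  set.seed(config$seed)
  n <- config$n_counties
  quintile <- sample(rep_len(1:5, n))
  pop <- round(stats::runif(n, config$population_range[1],
                            config$population_range[2]))
  grid <- expand.grid(age = config$ages, year = config$years,
                      county = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  P <- pop[grid$county]
  lr <- surface_log_rate(surface, grid$age, grid$year, quintile[grid$county])
  mu <- P * exp(lr)
  D <- stats::rpois(length(mu), mu)
  while (any(bad <- D > P))
    D[bad] <- stats::rpois(sum(bad), mu[bad])
  out <- data.frame(county = grid$county, state = "S01", age = grid$age,
                    year = grid$year, sex = surface$sex, race = surface$race,
                    quintile = quintile[grid$county], deaths = D,
                    population = P)
  attr(out, "seed") <- config$seed
  out
}

#' Reference life table implied by a true surface
#'
#' Converts the surface's reference-quintile rates over ages 0-99 into
#' annual death probabilities, the synthetic stand-in for a national
#' reference life table used by [boundary_adjust()].
#'
#' @param surface a [true_surface()].
#' @param year calendar year.
#' @param quintile quintile whose rates to use (default the reference).
#' @return data frame with columns \code{age} (0-99) and \code{qx}.
#' @export
reference_lt_from_surface <- function(surface, year,
                                      quintile = surface$ses_ref) {
  m <- exp(surface_log_rate(surface, 0:99, year, quintile))
  data.frame(age = 0:99, qx = rate_to_q(m))
}

#' Life expectancy implied exactly by a true surface
#'
#' Oracle for pipeline-recovery tests: evaluates the surface at every
#' single age 0-99, converts rates to probabilities, and applies the same
#' life-table algebra as [build_life_table()] / [life_expectancy()].
#'
#' @inheritParams reference_lt_from_surface
#' @param from_age starting exact age.
#' @return expected years lived between \code{from_age} and exact age 99.
#' @export
true_life_expectancy <- function(surface, year, quintile = surface$ses_ref,
                                 from_age = 0) {
  q <- reference_lt_from_surface(surface, year, quintile)$qx
  life_expectancy(build_life_table(q), from_age)
}

#' Simulate a cancer cohort with a known excess hazard
#'
#' Patients receive a diagnosis age and year; their time to death is drawn
#' from a piecewise-constant hazard on annual follow-up segments equal to
#' the background rate (from the matched life table at attained age,
#' capped at 99) plus the specified excess cancer hazard.  At a simulated
#' death the cause is labeled \code{"cancer"} with probability
#' excess/(excess + background) for the segment in which death occurred.
#' Follow-up is administratively censored at the study end (diagnoses are
#' taken as mid-year, so a patient diagnosed in \code{study_end} itself
#' still accrues six months).
#'
#' @param lt background life table: data frame with columns \code{age} and
#'   \code{qx} covering every attainable age (ages beyond its range use
#'   its last row).
#' @param excess_hazard non-negative excess rate per person-year; a scalar
#'   or a vector indexed by follow-up year (recycled).
#' @param n cohort size.
#' @param seed integer RNG seed.
#' @param diag_age_range,diag_year_range inclusive integer ranges sampled
#'   uniformly.
#' @param study_end last calendar year of follow-up.
#' @param sex,race,county,stratum labels attached to every patient;
#'   \code{stratum} is the life-table matching key used downstream.
#' @return patient cohort data frame with columns \code{id},
#'   \code{diag_year}, \code{diag_age}, \code{sex}, \code{race},
#'   \code{county}, \code{stratum}, \code{surv_months}, \code{status}
#'   (\code{"dead"}/\code{"alive"}), \code{cause} (\code{"cancer"},
#'   \code{"other"} or \code{NA}), \code{source} and \code{n_primaries};
#'   seed attached as attribute \code{"seed"}.
#' @export
generate_cohort <- function(lt, excess_hazard, n, seed = 1L,
                            diag_age_range = c(55, 75),
                            diag_year_range = c(2000, 2012),
                            study_end = 2012,
                            sex = "male", race = "white", county = 1L,
                            stratum = "base") {
  if (any(excess_hazard < 0)) stop("negative excess hazard")
  if (n < 1) stop("n must be >= 1")
  if (nrow(lt) == 0L) stop("empty life table")
  set.seed(seed)
  lt <- lt[order(lt$age), , drop = FALSE]
  m_bg <- q_to_rate(lt$qx)
  age_min <- min(lt$age); age_max <- max(lt$age)
  bg_at <- function(a) m_bg[pmin(pmax(a, age_min), age_max) - age_min + 1L]

  diag_age <- sample(seq(diag_age_range[1], diag_age_range[2]), n, replace = TRUE)
  diag_year <- sample(seq(diag_year_range[1], diag_year_range[2]), n,
                      replace = TRUE)
  censor_months <- 12 * (study_end - diag_year) + 6
  S <- max(1L, ceiling(max(censor_months) / 12))
  ex <- rep_len(excess_hazard, S)

  # hazard per patient x annual follow-up segment; first crossing of a
  # unit-exponential target gives the exact event time under the
  # piecewise-constant model
  H <- outer(diag_age, 0:(S - 1L), function(a, s) bg_at(a + s)) +
    matrix(ex, n, S, byrow = TRUE)
  cumH <- H
  if (S > 1L) for (s in 2:S) cumH[, s] <- cumH[, s - 1L] + H[, s]
  E <- stats::rexp(n)
  crossed <- cumH >= E
  has_event <- crossed[, S]
  seg <- max.col(crossed, ties.method = "first")
  prev <- ifelse(seg > 1L, cumH[cbind(seq_len(n), pmax(seg - 1L, 1L))], 0)
  t_months <- 12 * ((seg - 1L) + (E - prev) / H[cbind(seq_len(n), seg)])
  t_months[!has_event] <- Inf

  dead <- t_months <= censor_months
  surv <- pmin(t_months, censor_months)
  p_cancer <- ex[seg] / H[cbind(seq_len(n), seg)]
  cause <- rep(NA_character_, n)
  cause[dead] <- ifelse(stats::rbinom(sum(dead), 1L, p_cancer[dead]) == 1L,
                        "cancer", "other")
  out <- data.frame(id = seq_len(n), diag_year = diag_year,
                    diag_age = diag_age, sex = sex, race = race,
                    county = county, stratum = stratum,
                    surv_months = surv,
                    status = ifelse(dead, "dead", "alive"),
                    cause = cause, source = "other", n_primaries = 1L)
  attr(out, "seed") <- seed
  out
}
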