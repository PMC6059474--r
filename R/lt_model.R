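#' Specify a Poisson spline mortality model
#'
#' Describes one mortality model for a sex-race stratum: the geographic
#' level it is fitted at, how (or whether) county SES enters, the
#' restricted-cubic-spline knots for age and calendar year, and the width
#' of the moving window used to group annual rates.  Log mortality is
#' modeled as
#' \deqn{\ln \lambda = f(age) + g(year) + \sum_j \beta_j SES_j +
#'   \sum_j \gamma_j SES_j \cdot age}
#' with \code{f}, \code{g} restricted cubic splines and the SES-by-age
#' interaction entering through *linear* age.
#'
#' @param area_level one of \code{"state"}, \code{"region"},
#'   \code{"national"}; metadata recording the geographic pooling.
#' @param ses_form \code{"quintile5"} (5-level quintile covariate),
#'   \code{"level2"} (low = Q1-Q3 vs high = Q4-Q5) or \code{"none"}.
#' @param age_knots,year_knots strictly increasing knot vectors (at least
#'   3 knots), or \code{NULL} to drop the term entirely.  Defaults are
#'   ages 32, 40, 55, 70, 77, 82 and years 1992, 1997, 2002, 2007, 2012.
#' @param grouping_window odd number of calendar years pooled around each
#'   center year (default 3).
#' @param ses_ref reference SES level carrying zero main effect and zero
#'   age interaction; defaults to \code{"Q5"} for \code{quintile5} and
#'   \code{"low"} for \code{level2}.
#' @return an object of class \code{"lt_model_spec"}.
#' @export
lt_model_spec <- function(area_level = c("state", "region", "national"),
                          ses_form = c("quintile5", "level2", "none"),
                          age_knots = c(32, 40, 55, 70, 77, 82),
                          year_knots = c(1992, 1997, 2002, 2007, 2012),
                          grouping_window = 3,
                          ses_ref = NULL) {
  area_level <- match.arg(area_level)
  ses_form <- match.arg(ses_form)
  for (kn in list(age_knots, year_knots))
    if (!is.null(kn) && (length(kn) < 3L || any(diff(kn) <= 0)))
      stop("knots must be strictly increasing, length >= 3 (or NULL)")
  if (grouping_window < 1 || grouping_window %% 2 != 1)
    stop("grouping_window must be odd and >= 1")
  if (is.null(ses_ref))
    ses_ref <- switch(ses_form, quintile5 = "Q5", level2 = "low", none = NA_character_)
  levels <- switch(ses_form,
                   quintile5 = paste0("Q", 1:5),
                   level2 = c("low", "high"),
                   none = character(0))
  if (ses_form != "none" && !ses_ref %in% levels)
    stop("ses_ref not a valid level for ses_form")
  structure(list(area_level = area_level, ses_form = ses_form,
                 age_knots = age_knots, year_knots = year_knots,
                 grouping_window = grouping_window, ses_ref = ses_ref,
                 ses_levels = levels),
            class = "lt_model_spec")
}

# Map a panel's integer quintile (1-5) to the SES factor level a spec uses.
ses_level_for <- function(spec, quintile) {
  switch(spec$ses_form,
         quintile5 = paste0("Q", quintile),
         level2 = ifelse(quintile <= 3, "low", "high"),
         none = rep(NA_character_, length(quintile)))
}

# Design matrix for the log-rate linear predictor. `ses` is a character
# vector of SES levels (ignored when the spec has ses_form "none").
lt_design_matrix <- function(spec, age, year, ses = NULL) {
  n <- length(age)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(spec$age_knots)) {
    B <- rcs_basis(age, spec$age_knots)
    colnames(B) <- sub("^lin$", "age", sub("^nl", "age_nl", colnames(B)))
    X <- cbind(X, B)
  }
  if (!is.null(spec$year_knots)) {
    B <- rcs_basis(year, spec$year_knots)
    colnames(B) <- sub("^lin$", "year", sub("^nl", "year_nl", colnames(B)))
    X <- cbind(X, B)
  }
  if (spec$ses_form != "none") {
    if (is.null(ses)) stop("SES levels required for this model spec")
    bad <- setdiff(unique(ses), spec$ses_levels)
    if (length(bad)) stop("unknown SES level: ", paste(bad, collapse = ", "))
    for (lev in setdiff(spec$ses_levels, spec$ses_ref)) {
      dummy <- as.numeric(ses == lev)
      Xl <- cbind(dummy, dummy * age)
      colnames(Xl) <- c(paste0("ses", lev), paste0("ses", lev, ":age"))
      X <- cbind(X, Xl)
    }
  }
  X
}

#' Group annual mortality counts into a moving calendar-year window
#'
#' Deaths and populations are summed over the window
#' \code{[center - (w-1)/2, center + (w-1)/2]} and labeled with the center
#' year, the usual device for stabilizing county-level rates (e.g. a
#' 3-year window pools 1991-1993 under the label 1992).  Years absent from
#' the panel simply contribute nothing, so windows at the edge of the
#' observed span are truncated rather than padded.
#'
#' @param panel mortality panel: data frame with columns \code{age},
#'   \code{year}, \code{deaths}, \code{population} plus any identifier
#'   columns (county, sex, race, quintile, ...), which are preserved as
#'   grouping keys.
#' @param center_years one or more center years to produce.
#' @param window odd window width in years.
#' @return grouped panel with one row per key x center year, \code{year}
#'   set to the center year.
#' @export
aggregate_rates <- function(panel, center_years, window = 3) {
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  half <- (window - 1) / 2
  keys <- setdiff(names(panel), c("year", "deaths", "population"))
  pieces <- lapply(center_years, function(cy) {
    d <- panel[panel$year >= cy - half & panel$year <= cy + half, , drop = FALSE]
    if (nrow(d) == 0L) stop("empty grouping window at center year ", cy)
    key <- if (length(keys)) do.call(paste, c(d[keys], sep = "\r"))
           else rep("", nrow(d))
    agg <- rowsum(cbind(deaths = d$deaths, population = d$population), key)
    first <- d[!duplicated(key), keys, drop = FALSE]
    first <- first[order(key[!duplicated(key)]), , drop = FALSE]
    out <- cbind(first, year = cy, as.data.frame(agg))
    rownames(out) <- NULL
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Fit the Poisson spline mortality model
#'
#' Maximum-likelihood fit of \code{deaths ~ Poisson(population * lambda)}
#' with \code{log(lambda)} given by the spec's design (age spline + year
#' spline + SES main effects + SES-by-linear-age interactions), i.e. a
#' log-link Poisson GLM with a log-population offset, via iteratively
#' reweighted least squares.
#'
#' @param grouped (grouped) mortality panel with columns \code{age},
#'   \code{year}, \code{deaths}, \code{population}, and \code{quintile}
#'   (integer 1-5) when the spec includes SES; rows with zero population
#'   are dropped.
#' @param spec an [lt_model_spec()].
#' @param quintiles optional quintile assignment (\code{county},
#'   \code{year}, \code{quintile}) merged onto the panel by county and
#'   year when the panel itself lacks a \code{quintile} column.
#' @param epsilon,maxit IRLS convergence tolerance on the relative
#'   deviance change and iteration cap.
#' @return object of class \code{"lt_model"}: coefficients, covariance,
#'   deviance, the spec, and fitting metadata.
#' @export
fit_poisson_lt <- function(grouped, spec = lt_model_spec(), quintiles = NULL,
                           epsilon = 1e-8, maxit = 100L) {
  d <- grouped
  if (spec$ses_form != "none" && !"quintile" %in% names(d)) {
    if (is.null(quintiles))
      stop("panel has no quintile column and no quintile assignment given")
    d <- merge(d, quintiles[c("county", "year", "quintile")],
               by = c("county", "year"), all.x = TRUE)
    if (anyNA(d$quintile)) stop("some county-years lack a quintile")
  }
  d <- d[d$population > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("no cells with positive population")
  if (sum(d$deaths) <= 0) stop("zero total deaths: log rate unidentifiable")
  ses <- if (spec$ses_form != "none") ses_level_for(spec, d$quintile) else NULL
  X <- lt_design_matrix(spec, d$age, d$year, ses)
  fit <- stats::glm.fit(X, d$deaths, family = stats::poisson(),
                        offset = log(d$population),
                        control = list(epsilon = epsilon, maxit = maxit))
  if (!fit$converged) stop("IRLS did not converge in ", maxit, " iterations")
  p <- ncol(X)
  if (fit$rank < p) stop("design matrix is collinear (rank ", fit$rank,
                         " < ", p, " columns)")
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  vc <- chol2inv(R)
  piv <- fit$qr$pivot
  vc <- vc[order(piv), order(piv), drop = FALSE]
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
                 vcov = vc, deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 spec = spec, nobs = nrow(d), total_deaths = sum(d$deaths),
                 iter = fit$iter, fitted_deaths = fit$fitted.values),
            class = "lt_model")
}

#' @export
print.lt_model <- function(x, ...) {
  cat("Poisson spline mortality model (", x$spec$area_level, ", SES ",
      x$spec$ses_form, ")\n", sep = "")
  cat("  cells:", x$nobs, "  deaths:", format(x$total_deaths, big.mark = ","),
      "  deviance:", format(x$deviance, digits = 6), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Evaluate a fitted model's log mortality rate
#'
#' @param model a fitted [fit_poisson_lt()] model.
#' @param age,year numeric vectors (recycled to common length).
#' @param ses_level SES level label (e.g. \code{"Q1"} or \code{"high"});
#'   ignored for SES-free specs.
#' @return numeric vector of log rates.
#' @export
predict_log_rate <- function(model, age, year, ses_level = NULL) {
  n <- max(length(age), length(year))
  age <- rep_len(age, n); year <- rep_len(year, n)
  ses <- NULL
  if (model$spec$ses_form != "none") {
    if (is.null(ses_level)) stop("ses_level required for this model")
    if (!all(ses_level %in% model$spec$ses_levels))
      stop("unknown SES level")
    ses <- rep_len(ses_level, n)
  }
  X <- lt_design_matrix(model$spec, age, year, ses)
  drop(X %*% model$coefficients)
}

#' Default model-selection ladder
#'
#' Candidate model specs ordered from most to least detailed: state
#' geography with 5-level SES, then state with 2-level SES, state without
#' SES, region with 5-level SES, national with 2-level SES, and national
#' without SES.
#'
#' @param ... passed to every [lt_model_spec()] call (e.g. knots).
#' @return list of \code{lt_model_spec} objects.
#' @export
default_ladder <- function(...) {
  list(lt_model_spec("state", "quintile5", ...),
       lt_model_spec("state", "level2", ...),
       lt_model_spec("state", "none", ...),
       lt_model_spec("region", "quintile5", ...),
       lt_model_spec("national", "level2", ...),
       lt_model_spec("national", "none", ...))
}

#' Choose the most detailed feasible model spec for a stratum
#'
#' Data sparsity dictates how much geographic and SES detail a sex-race
#' stratum can support.  Candidates are tried in ladder order and the
#' first one whose every design cell (area unit x SES level) holds at
#' least \code{min_cell_deaths} deaths, with every area unit totalling at
#' least \code{min_total_deaths}, is returned.
#'
#' @param stratum_totals data frame with columns \code{state},
#'   \code{region}, \code{quintile} (1-5) and \code{deaths}, one row per
#'   observed combination (finer rows are summed as needed).
#' @param ladder ordered list of candidate specs, most detailed first;
#'   default [default_ladder()].
#' @param min_cell_deaths,min_total_deaths sufficiency thresholds
#'   (defaults 25 per cell, 10,000 per area unit).
#' @return the first feasible \code{lt_model_spec}.
#' @export
select_model_spec <- function(stratum_totals, ladder = default_ladder(),
                              min_cell_deaths = 25,
                              min_total_deaths = 10000) {
  need <- c("state", "region", "quintile", "deaths")
  if (!all(need %in% names(stratum_totals)))
    stop("stratum_totals needs columns ", paste(need, collapse = ", "))
  for (spec in ladder) {
    area <- switch(spec$area_level,
                   state = stratum_totals$state,
                   region = stratum_totals$region,
                   national = rep("US", nrow(stratum_totals)))
    ses <- switch(spec$ses_form,
                  quintile5 = paste0("Q", stratum_totals$quintile),
                  level2 = ifelse(stratum_totals$quintile <= 3, "low", "high"),
                  none = rep("all", nrow(stratum_totals)))
    cell <- rowsum(stratum_totals$deaths, paste(area, ses, sep = "|"))
    per_area <- rowsum(stratum_totals$deaths, area)
    # a feasible spec must populate every SES level in every area unit
    n_lev <- max(1L, length(spec$ses_levels))
    full <- nrow(cell) == length(unique(area)) * n_lev
    if (full && all(cell >= min_cell_deaths) && all(per_area >= min_total_deaths))
      return(spec)
  }
  stop("no candidate model spec is feasible for this stratum")
}
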