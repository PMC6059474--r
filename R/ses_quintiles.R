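#' Interpolate a county SES index between anchor years
#'
#' County socioeconomic index values are typically available only at census
#' or survey anchor years (e.g. 1990, 2000, 2007-2009).  Values for the
#' remaining years are filled in per county: linear interpolation between
#' the two surrounding anchors, linear extrapolation from the two nearest
#' anchors outside the anchor span, and a constant carry for counties with
#' a single anchor.  A \code{population} column, if present, is treated the
#' same way (floored at zero).
#'
#' @param anchors data frame with columns \code{county}, \code{year},
#'   \code{index} and optionally \code{population}, one row per
#'   county-anchor-year.
#' @param target_years integer vector of years to produce.
#' @return data frame with columns \code{county}, \code{year}, \code{index}
#'   (and \code{population} if supplied), one row per county-target-year.
#' @export
interpolate_ses_index <- function(anchors, target_years) {
  if (!all(c("county", "year", "index") %in% names(anchors)))
    stop("anchors needs columns county, year, index")
  has_pop <- "population" %in% names(anchors)
  target_years <- sort(unique(as.integer(target_years)))

  fill1 <- function(ay, av) {
    # linear inside the span, linear extension from the two nearest anchors
    # outside it, constant for a single anchor
    if (length(ay) == 1L) return(rep(av, length(target_years)))
    out <- stats::approx(ay, av, xout = target_years, rule = 1)$y
    lo <- target_years < ay[1L]
    hi <- target_years > ay[length(ay)]
    if (any(lo)) {
      s <- (av[2L] - av[1L]) / (ay[2L] - ay[1L])
      out[lo] <- av[1L] + s * (target_years[lo] - ay[1L])
    }
    if (any(hi)) {
      k <- length(ay)
      s <- (av[k] - av[k - 1L]) / (ay[k] - ay[k - 1L])
      out[hi] <- av[k] + s * (target_years[hi] - ay[k])
    }
    out
  }

  pieces <- lapply(split(anchors, anchors$county), function(a) {
    a <- a[order(a$year), , drop = FALSE]
    if (anyDuplicated(a$year)) stop("duplicate anchor year for a county")
    out <- data.frame(county = a$county[1L], year = target_years,
                      index = fill1(a$year, a$index))
    if (has_pop)
      out$population <- pmax(fill1(a$year, a$population), 0)
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Assign population-weighted SES quintiles per year
#'
#' For each calendar year, counties are ranked from lowest to highest SES
#' index (ties broken by county ID) and cut into five bands each holding
#' 20% of the total population: Q1 holds the 20% of the population living
#' in the lowest-SES counties, Q5 the highest.  A county is assigned to the
#' band containing the *midpoint* of its cumulative-population interval, so
#' a county straddling a 20% boundary goes to whichever side holds more of
#' it; a single county holding all the population gets Q3.
#'
#' @param ses data frame with columns \code{county}, \code{year},
#'   \code{index}, \code{population}.
#' @return data frame with columns \code{county}, \code{year},
#'   \code{quintile} (integer 1-5, 1 = lowest SES).
#' @export
assign_quintiles <- function(ses) {
  if (!all(c("county", "year", "index", "population") %in% names(ses)))
    stop("ses needs columns county, year, index, population")
  if (anyNA(ses$index)) stop("missing SES index values")
  pieces <- lapply(split(ses, ses$year), function(d) {
    d <- d[order(d$index, d$county), , drop = FALSE]
    tot <- sum(d$population)
    if (tot <= 0) stop("total population is zero in a year")
    cum <- cumsum(d$population)
    mid <- (cum - d$population / 2) / tot
    data.frame(county = d$county, year = d$year,
               quintile = pmin(5L, findInterval(mid, c(0.2, 0.4, 0.6, 0.8)) + 1L))
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$year, res$county), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collapse SES quintiles to a low/high two-level grouping
#'
#' Q1-Q3 become \code{"low"}, Q4-Q5 become \code{"high"}.
#'
#' @param q a quintile assignment from [assign_quintiles()], or any data
#'   frame with an integer \code{quintile} column.
#' @return the input with a \code{level2} character column added.
#' @export
collapse_two_level <- function(q) {
  if (!"quintile" %in% names(q)) stop("no quintile column")
  if (any(!q$quintile %in% 1:5)) stop("quintile outside 1..5")
  q$level2 <- ifelse(q$quintile <= 3L, "low", "high")
  q
}
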