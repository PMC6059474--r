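#' Convert a central death rate to an annual death probability
#'
#' Uses the constant-hazard relation \code{q = 1 - exp(-m)} on single-year
#' age intervals.  This is the single declared scale on which the package
#' moves between modeled mortality rates and life-table probabilities.
#'
#' @param m non-negative central death rate (per person-year).
#' @return death probability in \code{[0, 1)}.
#' @export
rate_to_q <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop("negative death rate")
  1 - exp(-m)
}

#' Convert an annual death probability to a central death rate
#'
#' Inverse of [rate_to_q()]: \code{m = -log(1 - q)}.
#'
#' @param q death probability in \code{[0, 1)}.
#' @return central death rate.
#' @export
q_to_rate <- function(q) {
  if (any(q < 0 | q >= 1, na.rm = TRUE)) stop("q must lie in [0, 1)")
  -log(1 - q)
}

#' Extend modeled adult mortality rates to ages 0-99 using a reference table
#'
#' The mortality model is fitted to adult ages only; below age 35 and above
#' age 84 its level is anchored at the modeled rate while the *shape* of
#' mortality by age is borrowed from a reference life table:
#' \deqn{\hat m(a) = \hat m(35)\, m_{ref}(a) / m_{ref}(35), \quad a < 35}
#' \deqn{\hat m(a) = \hat m(84)\, m_{ref}(a) / m_{ref}(84), \quad a > 84}
#' Ages 35-84 pass through unchanged.  The reference table's death
#' probabilities are converted to rates (\code{-log(1 - q)}) before the
#' ratios are taken, so the adjustment is applied on one scale throughout.
#'
#' @param modeled data frame with columns \code{age} (exactly 35-84) and
#'   \code{rate} (central death rates).
#' @param reference data frame with columns \code{age} (exactly 0-99) and
#'   \code{qx} (annual death probabilities), e.g. one stratum-year of a
#'   national reference life table.
#' @return data frame with columns \code{age} (0-99) and \code{rate}.
#' @export
boundary_adjust <- function(modeled, reference) {
  modeled <- modeled[order(modeled$age), , drop = FALSE]
  reference <- reference[order(reference$age), , drop = FALSE]
  if (!identical(as.integer(modeled$age), 35:84))
    stop("modeled rates must cover ages 35-84 exactly")
  if (!identical(as.integer(reference$age), 0:99))
    stop("reference table must cover ages 0-99 exactly")
  m_ref <- q_to_rate(reference$qx)
  if (m_ref[36] <= 0 || m_ref[85] <= 0)
    stop("reference rate at an anchor age (35 or 84) is zero")
  out <- numeric(100)
  out[36:85] <- modeled$rate                     # ages 35-84 unchanged
  out[1:35] <- modeled$rate[1] * m_ref[1:35] / m_ref[36]
  out[86:100] <- modeled$rate[50] * m_ref[86:100] / m_ref[85]
  data.frame(age = 0:99, rate = out)
}

#' Build a period life table from single-age death probabilities
#'
#' Standard columns from a radix of 100,000: survivorship
#' \code{l_{x+1} = l_x (1 - q_x)}, person-years
#' \code{L_x = l_x - 0.5 d_x} (deaths spread uniformly in each interval,
#' \code{a_x = 0.5} at every age), and the remaining *temporary* life
#' expectancy up to exact age 99,
#' \code{e_x = sum(L_x ... L_98) / l_x}.  The table is closed at exact age
#' 99: no open-ended interval is added and nothing beyond age 99 is
#' credited.
#'
#' @param q numeric vector of 100 death probabilities for ages 0-99.
#' @param radix starting cohort size, default 100,000.
#' @param stratum,year optional labels stored as columns.
#' @return data frame of class \code{"lifetable"} with columns
#'   \code{stratum}, \code{year}, \code{age}, \code{qx}, \code{lx},
#'   \code{Lx}, \code{ex}.
#' @export
build_life_table <- function(q, radix = 1e5, stratum = NA_character_,
                             year = NA_integer_) {
  if (length(q) != 100L) stop("q must have 100 values (ages 0-99)")
  if (any(q < 0 | q > 1)) stop("q outside [0, 1]")
  lx <- radix * cumprod(c(1, 1 - q[-100L]))
  dx <- lx * q
  Lx <- lx - 0.5 * dx
  # T_x = person-years between exact ages x and 99 (L_99 excluded: exact-age cap)
  Tx <- c(rev(cumsum(rev(Lx[1:99]))), 0)
  ex <- ifelse(lx > 0, Tx / lx, NA_real_)
  out <- data.frame(stratum = stratum, year = year, age = 0:99,
                    qx = q, lx = lx, Lx = Lx, ex = ex)
  class(out) <- c("lifetable", "data.frame")
  out
}

#' Temporary life expectancy between an exact age and exact age 99
#'
#' @param lt a life table from [build_life_table()].
#' @param from_age integer age in 0-98.
#' @return expected years lived between \code{from_age} and exact age 99.
#' @export
life_expectancy <- function(lt, from_age = 0) {
  i <- match(from_age, lt$age)
  if (is.na(i)) stop("age not in life table")
  if (lt$lx[i] <= 0) stop("no survivors at from_age")
  idx <- lt$age >= from_age & lt$age <= 98
  sum(lt$Lx[idx]) / lt$lx[i]
}
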