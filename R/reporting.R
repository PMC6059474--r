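#' Compare relative survival under two life tables with cause-specific survival
#'
#' Builds the standard comparison summary: per group, the absolute
#' differences between each relative-survival estimate and cause-specific
#' survival, \code{diff_a = |a - c|} and \code{diff_b = |b - c|}, plus
#' \code{closer_by = diff_a - diff_b} (positive when the second life
#' table's relative survival sits closer to cause-specific survival).
#' By default the differences are taken on one-decimal displayed values,
#' matching how such tables are published; set \code{displayed = FALSE}
#' to difference the raw inputs.
#'
#' @param x data frame with columns \code{group}, \code{rs_a},
#'   \code{rs_b}, \code{css}: survival percentages in \code{[0, 200]}
#'   (relative survival may exceed 100).
#' @param displayed round inputs to one decimal before differencing.
#' @return data frame with columns \code{group}, \code{rs_a},
#'   \code{rs_b}, \code{css}, \code{diff_a}, \code{diff_b},
#'   \code{closer_by}.
#' @export
comparison_table <- function(x, displayed = TRUE) {
  need <- c("group", "rs_a", "rs_b", "css")
  if (!all(need %in% names(x)))
    stop("x needs columns ", paste(need, collapse = ", "))
  vals <- x[c("rs_a", "rs_b", "css")]
  if (any(unlist(vals) < 0 | unlist(vals) > 200, na.rm = TRUE))
    stop("survival percentages must lie in [0, 200]")
  v <- if (displayed) lapply(vals, round, digits = 1) else vals
  diff_a <- round(abs(v$rs_a - v$css), 10)
  diff_b <- round(abs(v$rs_b - v$css), 10)
  data.frame(group = x$group, rs_a = x$rs_a, rs_b = x$rs_b, css = x$css,
             diff_a = diff_a, diff_b = diff_b,
             closer_by = diff_a - diff_b)
}

#' Summarize life expectancies across SES quintiles
#'
#' For each group (e.g. state x race x sex x year), computes the
#' population-weighted mean life expectancy over its SES quintiles
#' together with the lowest- and highest-quintile expectancies - the
#' numbers behind a dot-and-range display of within-group SES disparity.
#'
#' @param lts named list of life tables from [build_life_table()].
#' @param meta data frame with one row per entry of \code{lts}: columns
#'   \code{name} (matching \code{names(lts)}), \code{group},
#'   \code{quintile} and \code{population}.
#' @param weighted population-weight the mean (otherwise unweighted).
#' @param from_age starting exact age for the expectancies.
#' @return data frame with columns \code{group}, \code{e_mean},
#'   \code{e_lowest_q}, \code{e_highest_q}, \code{quintile_lowest},
#'   \code{quintile_highest}.
#' @export
life_expectancy_summary <- function(lts, meta, weighted = TRUE,
                                    from_age = 0) {
  if (!all(meta$name %in% names(lts)))
    stop("meta names missing from the life-table list")
  meta$e <- vapply(meta$name, function(nm) life_expectancy(lts[[nm]], from_age),
                   numeric(1))
  pieces <- lapply(split(meta, meta$group), function(d) {
    d <- d[order(d$quintile), , drop = FALSE]
    w <- if (weighted) d$population else rep(1, nrow(d))
    data.frame(group = d$group[1],
               e_mean = sum(d$e * w) / sum(w),
               e_lowest_q = d$e[1], e_highest_q = d$e[nrow(d)],
               quintile_lowest = d$quintile[1],
               quintile_highest = d$quintile[nrow(d)])
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}
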