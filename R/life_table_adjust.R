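#' Fertility schedule over reproductive-age intervals
#'
#' Age-specific fertility rates (births per woman-year) on a set of age
#' intervals, used to spread averted maternal deaths across the reproductive
#' ages. Intervals must lie within the reproductive band [10, 55) and rates
#' must be non-negative.
#'
#' @param age_start interval start ages in years.
#' @param width interval widths in years.
#' @param rate births per woman-year in each interval.
#' @return An object of class `fertility_schedule` (a data.frame).
#' @export
fertility_schedule <- function(age_start, width, rate) {
  if (length(age_start) != length(width) || length(width) != length(rate))
    stop("age_start, width and rate must have equal length")
  if (any(rate < 0)) stop("fertility rates must be non-negative")
  if (any(age_start < 10 - 1e-9) || any(age_start + width > 55 + 1e-9))
    stop("fertility schedule intervals must lie within [10, 55) years")
  structure(data.frame(age_start = age_start, width = width, rate = rate),
            class = c("fertility_schedule", "data.frame"))
}

# Shift `amount` deaths out of the rows indexed by `from` (by the weights
# already subtracted from lt$deaths upstream) into the intervals at/above
# `min_age`, proportional to the baseline deaths recorded there. Keeps the
# radix exact.
redistribute_older <- function(deaths, age_start, amount, min_age) {
  older <- which(age_start >= min_age - 1e-9)
  if (!length(older))
    stop("no intervals above age ", min_age, " to receive redistributed deaths")
  w <- deaths[older]
  if (sum(w) <= 0) {
    # no baseline deaths above: park everything in the terminal interval
    deaths[older[length(older)]] <- deaths[older[length(older)]] + amount
  } else {
    deaths[older] <- deaths[older] + amount * w / sum(w)
  }
  deaths
}

#' Apply an under-five mortality reduction to a life table
#'
#' Removes averted neonatal and 1–59-month deaths from the `[0,1)` and
#' `[1,5)` intervals and lets the saved children age into the rest of the
#' table: the averted deaths are redistributed over the intervals above age
#' 5 proportionally to the baseline deaths there, so the conditional
#' mortality schedule above the affected ages is unchanged and the radix is
#' conserved exactly.
#'
#' Neonatal deaths sit entirely in the `[0,1)` interval. Averted 1–59-month
#' deaths are split between `[0,1)` (the post-neonatal infant part) and
#' `[1,5)` by `post_neonatal_infant_fraction`.
#'
#' @param lt a [life_table()] whose first two intervals are `[0,1)` and
#'   `[1,5)`.
#' @param neonatal_deaths_averted averted first-28-day deaths, per radix.
#' @param child_deaths_averted averted 1–59-month deaths, per radix.
#' @param post_neonatal_infant_fraction share of the 1–59-month averted
#'   deaths that would have occurred between 1 and 11 months, i.e. inside
#'   `[0,1)` (default 0.5).
#' @return A new [life_table()] with the same intervals, separation
#'   fractions and terminal handling.
#' @examples
#' base <- life_table(c(0, 1, 5, 60), c(1, 4, 55, Inf),
#'                    c(6850, 3250, 20000, 69900), neonatal_deaths = 3500)
#' saved <- apply_under5_reduction(base, 1000, 500)
#' life_expectancy(saved) > life_expectancy(base)
#' @export
apply_under5_reduction <- function(lt, neonatal_deaths_averted,
                                   child_deaths_averted,
                                   post_neonatal_infant_fraction = 0.5) {
  stopifnot(inherits(lt, "life_table"))
  if (neonatal_deaths_averted < 0 || child_deaths_averted < 0)
    stop("averted death counts must be non-negative")
  f <- post_neonatal_infant_fraction
  if (f < 0 || f > 1)
    stop("post_neonatal_infant_fraction must lie in [0, 1]")
  if (!(lt$age_start[1L] == 0 && lt$width[1L] == 1 &&
        lt$age_start[2L] == 1 && lt$width[2L] == 4))
    stop("life table must begin with the [0,1) and [1,5) intervals")

  take_infant <- neonatal_deaths_averted + f * child_deaths_averted
  take_child <- (1 - f) * child_deaths_averted
  if (take_infant > lt$deaths[1L] + 1e-9)
    stop(sprintf(
      "cannot avert %.6g deaths in the [0,1) interval: only %.6g available",
      take_infant, lt$deaths[1L]))
  if (take_child > lt$deaths[2L] + 1e-9)
    stop(sprintf(
      "cannot avert %.6g deaths in the [1,5) interval: only %.6g available",
      take_child, lt$deaths[2L]))

  neo <- attr(lt, "neonatal_deaths")
  if (!is.na(neo) && neonatal_deaths_averted > neo + 1e-9)
    stop(sprintf("cannot avert %.6g neonatal deaths: only %.6g recorded",
                 neonatal_deaths_averted, neo))

  d <- lt$deaths
  d[1L] <- d[1L] - take_infant
  d[2L] <- d[2L] - take_child
  d <- redistribute_older(d, lt$age_start, take_infant + take_child,
                          min_age = 5)
  life_table(lt$age_start, lt$width, d, a_x = lt$a_x,
             radix = attr(lt, "radix"),
             terminal_expectancy = attr(lt, "terminal_expectancy"),
             neonatal_deaths = if (is.na(neo)) NULL
                               else neo - neonatal_deaths_averted)
}

#' Apply a maternal-mortality reduction to a life table
#'
#' Removes averted maternal deaths from the reproductive-age intervals,
#' proportionally to the births contributed by each interval (age-specific
#' fertility rate times baseline person-years), and redistributes them to
#' the intervals at or above the end of the adjusted band proportionally to
#' the baseline deaths there. The radix is conserved exactly.
#'
#' @param lt a [life_table()].
#' @param maternal_deaths_averted averted maternal deaths, per radix.
#' @param fert a [fertility_schedule()] whose intervals each match a life
#'   table interval (same start and width).
#' @return A new [life_table()].
#' @export
apply_maternal_adjustment <- function(lt, maternal_deaths_averted, fert) {
  stopifnot(inherits(lt, "life_table"), inherits(fert, "fertility_schedule"))
  if (maternal_deaths_averted < 0)
    stop("maternal_deaths_averted must be non-negative")
  if (maternal_deaths_averted == 0) return(lt)

  idx <- match(paste(fert$age_start, fert$width),
               paste(lt$age_start, lt$width))
  if (anyNA(idx))
    stop("fertility schedule interval(s) do not match life table intervals: ",
         paste(fert$age_start[is.na(idx)], collapse = ", "))

  w <- fert$rate * lt$L[idx]
  if (sum(w) <= 0)
    stop("fertility schedule has no births; maternal adjustment undefined")
  take <- maternal_deaths_averted * w / sum(w)
  short <- which(take > lt$deaths[idx] + 1e-9)
  if (length(short))
    stop(sprintf(
      "cannot avert %.6g maternal deaths in interval starting at %g: only %.6g available",
      take[short[1L]], lt$age_start[idx[short[1L]]], lt$deaths[idx[short[1L]]]))

  d <- lt$deaths
  d[idx] <- d[idx] - take
  band_end <- max(fert$age_start + fert$width)
  d <- redistribute_older(d, lt$age_start, maternal_deaths_averted,
                          min_age = band_end)
  neo <- attr(lt, "neonatal_deaths")
  life_table(lt$age_start, lt$width, d, a_x = lt$a_x,
             radix = attr(lt, "radix"),
             terminal_expectancy = attr(lt, "terminal_expectancy"),
             neonatal_deaths = if (is.na(neo)) NULL else neo)
}
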