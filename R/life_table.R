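#' Construct an abridged life table
#'
#' Builds a period abridged life table from age-interval death counts on a
#' fixed radix (a hypothetical birth cohort, 100,000 by default). The table
#' follows the classical abridged-life-table (Chiang) layout: from the death
#' counts `d` it derives survivors at the start of each interval (`l`), the
#' conditional probability of dying in the interval (`q`), person-years lived
#' in the interval (`L`), cumulative person-years above the interval start
#' (`T`) and remaining life expectancy (`e`).
#'
#' Person-years in an interior interval of width `n` are
#' `L = n * l(x + n) + a_x * n * d(x)`, where the separation fraction `a_x`
#' is the average share of the interval lived by those dying in it. The
#' terminal interval is open-ended; its person-years are
#' `L = l * terminal_expectancy`, i.e. survivors reaching the terminal age
#' live `terminal_expectancy` further years on average (equivalently
#' `L = l / m` with hazard `m = 1/terminal_expectancy`).
#'
#' @param age_start numeric vector of interval start ages in years; the first
#'   must be 0 and intervals must be contiguous.
#' @param width interval widths in years; the last (terminal) interval is
#'   open-ended and encoded as `Inf` (or `NA`).
#' @param deaths deaths in each interval per `radix` live births; must be
#'   non-negative and sum to `radix` (relative tolerance 1e-6).
#' @param a_x optional separation fractions in (0, 1]. Defaults: 0.3 for a
#'   `[0,1)` first interval, 0.4 for a `[1,5)` second interval, 0.5 for all
#'   other interior intervals (standard abridged-table practice).
#' @param radix cohort size the deaths are expressed against (default 1e5).
#' @param terminal_expectancy mean further years lived by survivors entering
#'   the terminal interval (default 5).
#' @param neonatal_deaths optional count (per radix) of the `[0,1)` deaths
#'   occurring in the first 28 days; used only to report an implied neonatal
#'   mortality rate, never in the person-years arithmetic.
#'
#' @return An object of class `life_table`: a data.frame with columns
#'   `age_start, width, a_x, deaths, l, q, L, T, e` and attributes `radix`,
#'   `terminal_expectancy`, `neonatal_deaths`.
#' @seealso [life_expectancy()], [read_life_table()],
#'   [apply_under5_reduction()], [distribution_from_life_table()]
#' @examples
#' lt <- life_table(age_start = c(0, 1), width = c(1, Inf),
#'                  deaths = c(100000, 0))
#' life_expectancy(lt)  # everyone dies in [0,1): e(0) = a_0
#' @export
life_table <- function(age_start, width, deaths, a_x = NULL, radix = 1e5,
                       terminal_expectancy = 5, neonatal_deaths = NULL) {
  n <- length(age_start)
  if (n < 2L) stop("a life table needs at least two age intervals")
  if (length(width) != n || length(deaths) != n)
    stop("age_start, width and deaths must have equal length")
  width <- as.numeric(width)
  width[is.na(width)] <- Inf

  if (age_start[1L] != 0)
    stop("first age interval must start at age 0")
  open <- is.infinite(width)
  if (sum(open) != 1L || !open[n])
    stop("exactly one open-ended terminal interval (width = Inf) is required, ",
         "and it must be the last row")
  gap <- which(abs(age_start[-1L] - (age_start[-n] + width[-n])) > 1e-9)
  if (length(gap))
    stop(sprintf("intervals are not contiguous at row %d (age %g + width %g != %g)",
                 gap[1L] + 1L, age_start[gap[1L]], width[gap[1L]],
                 age_start[gap[1L] + 1L]))
  if (any(deaths < 0))
    stop(sprintf("negative deaths in row %d", which(deaths < 0)[1L]))
  if (radix <= 0) stop("radix must be positive")
  if (abs(sum(deaths) - radix) > 1e-6 * radix)
    stop(sprintf("deaths (%.6g) do not sum to the radix (%g)",
                 sum(deaths), radix))
  if (terminal_expectancy <= 0) stop("terminal_expectancy must be positive")

  if (is.null(a_x)) {
    a_x <- rep(0.5, n)
    if (age_start[1L] == 0 && isTRUE(all.equal(width[1L], 1))) a_x[1L] <- 0.3
    if (n >= 2L && age_start[2L] == 1 && isTRUE(all.equal(width[2L], 4)))
      a_x[2L] <- 0.4
  } else {
    if (length(a_x) != n) stop("a_x must match the number of intervals")
    if (any(!is.finite(a_x[-n])) || any(a_x[-n] <= 0) || any(a_x[-n] > 1))
      stop("interior a_x must lie in (0, 1]")
  }

  if (!is.null(neonatal_deaths)) {
    if (neonatal_deaths < 0 || neonatal_deaths > deaths[1L] + 1e-6)
      stop("neonatal_deaths must lie within the deaths of the [0,1) interval")
  }

  l <- radix - cumsum(c(0, deaths[-n]))
  l <- pmax(l, 0)
  q <- ifelse(l > 0, deaths / l, 0)
  q[n] <- ifelse(l[n] > 0, 1, 0)

  L <- numeric(n)
  l_next <- c(l[-1L], 0)
  L[-n] <- width[-n] * l_next[-n] + a_x[-n] * width[-n] * deaths[-n]
  L[n] <- l[n] * terminal_expectancy
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  out <- data.frame(age_start = age_start, width = width, a_x = a_x,
                    deaths = deaths, l = l, q = q, L = L, T = Tx, e = e)
  structure(out,
            class = c("life_table", "data.frame"),
            radix = radix,
            terminal_expectancy = terminal_expectancy,
            neonatal_deaths = if (is.null(neonatal_deaths)) NA_real_
                              else neonatal_deaths)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Abridged life table: %d intervals, radix %g, e(0) = %.2f years\n",
              nrow(x), attr(x, "radix"), life_expectancy(x)))
  if (!is.na(attr(x, "neonatal_deaths")))
    cat(sprintf("  neonatal deaths per radix: %g (NMR %.1f/1000)\n",
                attr(x, "neonatal_deaths"), implied_nmr(x)))
  print.data.frame(utils::head(as.data.frame(x), 25L), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 25L) cat(sprintf("  ... %d more rows\n", nrow(x) - 25L))
  invisible(x)
}

#' Life expectancy at birth
#'
#' Chiang life expectancy at birth from an abridged life table:
#' `e(0) = T(0) / l(0)`, with person-years as described in [life_table()].
#'
#' @param lt a [life_table()] object.
#' @return Life expectancy at birth in years.
#' @examples
#' lt <- life_table(c(0, 1), c(1, Inf), c(0, 100000), terminal_expectancy = 50)
#' life_expectancy(lt)  # 1 + 50 years
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  radix <- attr(lt, "radix")
  if (radix <= 0) stop("life expectancy is undefined for a zero radix")
  lt$T[1L] / radix
}

#' Under-five and neonatal mortality rates implied by a life table
#'
#' `implied_u5mr` is the share of the radix dying before exact age 5, per
#' 1,000 live births; it requires the table's intervals to break at age 5.
#' `implied_nmr` uses the neonatal split recorded at construction time (the
#' first-28-days deaths inside the `[0,1)` interval) and is `NA` when no
#' split was supplied.
#'
#' @param lt a [life_table()] object.
#' @return rate per 1,000 live births.
#' @export
implied_u5mr <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  under5 <- lt$age_start < 5
  end_age <- lt$age_start + lt$width
  if (any(under5 & end_age > 5 + 1e-9))
    stop("life table intervals do not break at age 5")
  sum(lt$deaths[under5]) / attr(lt, "radix") * 1000
}

#' @rdname implied_u5mr
#' @export
implied_nmr <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  attr(lt, "neonatal_deaths") / attr(lt, "radix") * 1000
}

#' Read and write abridged life tables as CSV
#'
#' The CSV schema has columns `age_start,width,deaths_per_100k` and an
#' optional `a_x` column; the terminal row encodes its width as empty, `NA`
#' or `inf`. The writer appends the derived columns `l,q,L,T,e`.
#'
#' @param path CSV file path.
#' @param ... passed on to [life_table()] (e.g. `terminal_expectancy`).
#' @return `read_life_table` returns a [life_table()]; `write_life_table`
#'   invisibly returns `path`.
#' @export
read_life_table <- function(path, ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "width", "deaths_per_100k")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("life table CSV is missing column(s): ", paste(miss, collapse = ", "))
  w <- raw$width
  if (is.character(w)) {
    w <- trimws(w)
    w[w %in% c("", "inf", "Inf", "INF")] <- "Inf"
    w <- as.numeric(w)
  }
  life_table(age_start = raw$age_start, width = w,
             deaths = raw$deaths_per_100k,
             a_x = if ("a_x" %in% names(raw)) raw$a_x else NULL, ...)
}

#' @rdname read_life_table
#' @param lt a [life_table()] object.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  out <- data.frame(age_start = lt$age_start,
                    width = ifelse(is.infinite(lt$width), "inf", lt$width),
                    deaths_per_100k = lt$deaths, a_x = lt$a_x,
                    l = lt$l, q = lt$q, L = lt$L, T = lt$T, e = lt$e)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
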