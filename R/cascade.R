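#' Burden profile for one projection year
#'
#' Cause-specific death counts for one year: annual live births, neonatal
#' (first 28 days) and 1–59-month deaths by cause, and maternal deaths.
#' Cause identifiers must be unique across periods so an intervention effect
#' can be matched to exactly one burden row.
#'
#' @param year calendar year the counts refer to.
#' @param live_births annual live births.
#' @param deaths data.frame with columns `cause`, `period` (one of
#'   `"neonatal"`, `"child"`, `"maternal"`) and `deaths` (non-negative
#'   counts).
#' @return An object of class `burden_profile`.
#' @seealso [run_cascade()], [project_scenario()], [make_baseline()]
#' @export
burden_profile <- function(year, live_births, deaths) {
  need <- c("cause", "period", "deaths")
  miss <- setdiff(need, names(deaths))
  if (length(miss))
    stop("deaths table is missing column(s): ", paste(miss, collapse = ", "))
  if (live_births <= 0) stop("live_births must be positive")
  if (!all(deaths$period %in% c("neonatal", "child", "maternal")))
    stop("period must be neonatal, child or maternal")
  if (any(deaths$deaths < 0)) stop("death counts must be non-negative")
  if (anyDuplicated(deaths$cause))
    stop("cause identifiers must be unique across periods")
  structure(list(year = as.integer(year), live_births = live_births,
                 deaths = as.data.frame(deaths)),
            class = "burden_profile")
}

#' @export
print.burden_profile <- function(x, ...) {
  cat(sprintf("Burden profile %d: %s live births\n", x$year,
              format(x$live_births, big.mark = ",")))
  cat(sprintf("  NMR %.1f, U5MR %.1f per 1000 live births; %s maternal deaths\n",
              burden_nmr(x), burden_u5mr(x),
              format(round(sum(x$deaths$deaths[x$deaths$period == "maternal"])),
                     big.mark = ",")))
  print.data.frame(x$deaths, row.names = FALSE)
  invisible(x)
}

#' Mortality rates implied by a burden profile
#'
#' `burden_nmr` is neonatal deaths per 1,000 live births. `burden_u5mr` is
#' the under-five cohort probability of death per 1,000 live births,
#' aggregated without double-counting denominators:
#' `q_neo = neonatal/births`, `q_child = child/(births - neonatal)`,
#' `U5MR = (1 - (1 - q_neo)(1 - q_child)) * 1000` — which reduces to total
#' under-five deaths per 1,000 live births.
#'
#' @param burden a [burden_profile()].
#' @return Rate per 1,000 live births.
#' @export
burden_nmr <- function(burden) {
  stopifnot(inherits(burden, "burden_profile"))
  sum(burden$deaths$deaths[burden$deaths$period == "neonatal"]) /
    burden$live_births * 1000
}

#' @rdname burden_nmr
#' @export
burden_u5mr <- function(burden) {
  stopifnot(inherits(burden, "burden_profile"))
  neo <- sum(burden$deaths$deaths[burden$deaths$period == "neonatal"])
  child <- sum(burden$deaths$deaths[burden$deaths$period == "child"])
  q_neo <- neo / burden$live_births
  q_child <- if (burden$live_births > neo)
    child / (burden$live_births - neo) else 0
  (1 - (1 - q_neo) * (1 - q_child)) * 1000
}

#' Read and write burden profiles as CSV
#'
#' Schema: `year,live_births,cause,period,deaths`, one row per cause.
#'
#' @param path CSV file path.
#' @return `read_burden` returns a [burden_profile()].
#' @export
read_burden <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "live_births", "cause", "period", "deaths")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("burden CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(raw$year)) != 1L || length(unique(raw$live_births)) != 1L)
    stop("burden CSV must describe a single year and birth cohort")
  burden_profile(raw$year[1L], raw$live_births[1L],
                 raw[, c("cause", "period", "deaths")])
}

#' @rdname read_burden
#' @param burden a [burden_profile()].
#' @export
write_burden <- function(burden, path) {
  stopifnot(inherits(burden, "burden_profile"))
  out <- cbind(year = burden$year, live_births = burden$live_births,
               burden$deaths)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Deaths averted by one intervention effect
#'
#' The elementary lives-saved step. With effectiveness `E`, affected
#' fraction `AF` and coverage moving from `c0` to `ct`, the deaths averted
#' among `deaths` cause-specific deaths are
#'
#' `averted = deaths * E*AF*(ct - c0) / (1 - E*AF*c0)`
#'
#' The denominator is the residual-counterfactual normalisation: the
#' `deaths` on input are deaths that occur *despite* baseline coverage
#' `c0`, so the impact of further scale-up is measured against the
#' already-partly-treated population. `ct < c0` (coverage loss) yields a
#' negative averted count, reported as increased deaths rather than an
#' error.
#'
#' @param deaths cause-specific deaths at the current residual.
#' @param effectiveness,affected_fraction fractions in `[0, 1]`.
#' @param c0 baseline coverage fraction.
#' @param ct target-year coverage fraction.
#' @return List with `averted` and `residual` (`deaths - averted`).
#' @examples
#' single_impact(1000, 0.8, 0.5, c0 = 0.25, ct = 0.90)$averted  # 288.9
#' @export
single_impact <- function(deaths, effectiveness, affected_fraction, c0, ct) {
  if (deaths < 0) stop("deaths must be non-negative")
  if (c0 < 0 || ct < 0) stop("coverage must be non-negative")
  r <- effectiveness * affected_fraction
  if (abs(1 - r * c0) < 1e-12)
    stop("degenerate baseline: effectiveness * affected_fraction * c0 = 1 ",
         "(all preventable deaths already removed at baseline)")
  averted <- deaths * r * (ct - c0) / (1 - r * c0)
  list(averted = averted, residual = deaths - averted)
}

# Deterministic cascade order: preventive before curative, catalogue order
# within each class. Subcomponents are not part of the residual-updating
# pass; they are evaluated against the residual immediately after their
# parent.
cascade_order <- function(catalogue) {
  iv <- catalogue$interventions
  top <- iv[is.na(iv$subcomponent_of), ]
  c(top$id[top$class == "preventive"], top$id[top$class == "curative"])
}

#' Run the lives-saved cascade for one year
#'
#' Applies an ordered intervention package sequentially to the cause-specific
#' residual deaths of a burden profile. Preventive interventions are applied
#' before curative ones (catalogue order within each class); each
#' intervention's averted deaths are computed from the residual left by the
#' interventions before it, so the package members interact — removing an
#' upstream intervention leaves more residual deaths for the downstream ones
#' to avert. Subcomponent interventions are evaluated against the residual
#' immediately after their parent but do not reduce the residual (their
#' deaths would double-count the parent's) and are excluded from package
#' totals.
#'
#' @param burden a [burden_profile()] of baseline deaths.
#' @param catalogue an [intervention_catalogue()].
#' @param coverage named vector, intervention id -> coverage fraction this
#'   year; ids absent from the vector stay at baseline coverage.
#' @return A list of class `cascade_result`: `ledger` (data.frame
#'   `id, cause, period, averted, subcomponent`), `residual` (a
#'   [burden_profile()]), and `order` (the ids in application order).
#' @export
run_cascade <- function(burden, catalogue, coverage = numeric()) {
  stopifnot(inherits(burden, "burden_profile"),
            inherits(catalogue, "intervention_catalogue"))
  iv <- catalogue$interventions
  ef <- catalogue$effects
  unknown <- setdiff(names(coverage), iv$id)
  if (length(unknown))
    stop("coverage names unknown intervention(s): ",
         paste(unknown, collapse = ", "))

  residual <- burden$deaths
  rownames(residual) <- residual$cause
  ord <- cascade_order(catalogue)
  ledger <- list()

  eval_one <- function(id, residual) {
    row <- iv[iv$id == id, ]
    c0 <- row$baseline_coverage
    ct <- if (id %in% names(coverage)) coverage[[id]] else c0
    eff <- ef[ef$id == id & ef$cause %in% residual$cause, , drop = FALSE]
    if (!nrow(eff)) return(NULL)
    averted <- vapply(seq_len(nrow(eff)), function(k)
      single_impact(residual[eff$cause[k], "deaths"], eff$effectiveness[k],
                    eff$affected_fraction[k], c0, ct)$averted,
      numeric(1))
    data.frame(id = id, cause = eff$cause,
               period = residual[eff$cause, "period"],
               averted = averted,
               subcomponent = !is.na(row$subcomponent_of))
  }

  for (id in ord) {
    entry <- eval_one(id, residual)
    if (!is.null(entry)) {
      residual[entry$cause, "deaths"] <-
        residual[entry$cause, "deaths"] - entry$averted
      ledger[[length(ledger) + 1L]] <- entry
    }
    for (sub in iv$id[!is.na(iv$subcomponent_of) & iv$subcomponent_of == id]) {
      sub_entry <- eval_one(sub, residual)
      if (!is.null(sub_entry)) ledger[[length(ledger) + 1L]] <- sub_entry
    }
  }

  ledger <- if (length(ledger)) do.call(rbind, ledger)
  else data.frame(id = character(), cause = character(), period = character(),
                  averted = numeric(), subcomponent = logical())
  rownames(ledger) <- NULL
  rownames(residual) <- NULL
  structure(list(ledger = ledger,
                 residual = burden_profile(burden$year, burden$live_births,
                                           residual),
                 order = ord),
            class = "cascade_result")
}

#' Project a scale-up scenario over a year range
#'
#' For each calendar year, coverage comes from [coverage_path()] and the
#' cascade is run against the baseline burden at that year's coverage. The
#' trajectory reports the residual neonatal mortality rate and under-five
#' mortality rate per year; deaths averted accumulate across years into the
#' by-end-year totals reported by [aggregate_package()].
#'
#' @param burden baseline [burden_profile()].
#' @param catalogue an [intervention_catalogue()].
#' @param scenario a [scenario()].
#' @param years years to evaluate (default the scenario's full range); must
#'   lie within the scenario range.
#' @return A list of class `projection`: `ledger` (per year/intervention/
#'   cause averted deaths), `trajectory` (data.frame
#'   `year, scenario, nmr, u5mr, deaths_averted`), `residuals` (list of
#'   year-end [burden_profile()]s), `scenario` name.
#' @export
project_scenario <- function(burden, catalogue, scenario,
                             years = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(years)) years <- seq(scenario$start_year, scenario$end_year)
  if (any(years < scenario$start_year | years > scenario$end_year))
    stop("projection years must lie within the scenario range")

  iv <- catalogue$interventions
  ledger <- list()
  residuals <- list()
  traj <- data.frame(year = years, scenario = scenario$name,
                     nmr = NA_real_, u5mr = NA_real_,
                     deaths_averted = NA_real_)
  for (k in seq_along(years)) {
    t <- years[k]
    cov_t <- vapply(seq_len(nrow(iv)), function(i)
      coverage_path(scenario, iv[i, ])[[as.character(t)]], numeric(1))
    names(cov_t) <- iv$id
    res <- run_cascade(burden, catalogue, cov_t)
    led <- res$ledger
    led <- if (nrow(led)) cbind(year = t, led)
    else data.frame(year = integer(), id = character(), cause = character(),
                    period = character(), averted = numeric(),
                    subcomponent = logical())
    ledger[[k]] <- led
    residuals[[as.character(t)]] <- res$residual
    traj$nmr[k] <- burden_nmr(res$residual)
    traj$u5mr[k] <- burden_u5mr(res$residual)
    traj$deaths_averted[k] <- sum(led$averted[!led$subcomponent])
  }
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL
  structure(list(ledger = ledger, trajectory = traj, residuals = residuals,
                 scenario = scenario$name),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("Projection '%s' over %d-%d\n", x$scenario,
              min(x$trajectory$year), max(x$trajectory$year)))
  print.data.frame(x$trajectory, row.names = FALSE, digits = 4)
  invisible(x)
}

# round half away from zero (printed tables use half-up, not banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate a projection ledger into a package report
#'
#' Per-intervention cumulative deaths averted over the projection years,
#' with the package total excluding subcomponent rows (their deaths are
#' nested inside their parent's). Optionally reports a named-subset subtotal
#' and its percentage share of the package total (one decimal, rounded half
#' up).
#'
#' @param projection a [project_scenario()] result, or a bare ledger
#'   data.frame with columns `id, averted, subcomponent`.
#' @param subset optional character vector of intervention ids for the
#'   subtotal.
#' @param total_basis total used for the share denominator (defaults to the
#'   computed package total; pass a printed/published total to reproduce
#'   shares quoted against it).
#' @return A list of class `package_report`: `by_intervention` (data.frame
#'   `id, averted, subcomponent`), `total`, and if `subset` given `subtotal`
#'   and `share_pct`.
#' @export
aggregate_package <- function(projection, subset = NULL, total_basis = NULL) {
  led <- if (inherits(projection, "projection")) projection$ledger
  else projection
  need <- c("id", "averted", "subcomponent")
  miss <- setdiff(need, names(led))
  if (length(miss))
    stop("ledger is missing column(s): ", paste(miss, collapse = ", "))

  agg <- stats::aggregate(averted ~ id + subcomponent, data = led, FUN = sum)
  agg <- agg[order(-agg$averted), c("id", "averted", "subcomponent")]
  rownames(agg) <- NULL
  total <- sum(agg$averted[!agg$subcomponent])
  out <- list(by_intervention = agg, total = total)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, agg$id)
    if (length(unknown))
      stop("subset names unknown intervention(s): ",
           paste(unknown, collapse = ", "))
    subtotal <- sum(agg$averted[agg$id %in% subset & !agg$subcomponent])
    basis <- if (is.null(total_basis)) total else total_basis
    out$subtotal <- subtotal
    out$share_pct <- round_half_up(subtotal / basis * 100, 1)
  }
  structure(out, class = "package_report")
}

#' @export
print.package_report <- function(x, ...) {
  cat(sprintf("Package report: total %s deaths averted (subcomponents excluded)\n",
              format(round(x$total), big.mark = ",")))
  if (!is.null(x$subtotal))
    cat(sprintf("  subset subtotal %s (%.1f%%)\n",
                format(round(x$subtotal), big.mark = ","), x$share_pct))
  print.data.frame(x$by_intervention, row.names = FALSE, digits = 6)
  invisible(x)
}
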