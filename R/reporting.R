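#' Yearly life expectancy and lifespan-inequality trajectory
#'
#' For each projection year, the deaths averted by the cascade in that year
#' (neonatal, 1–59-month and maternal, subcomponents excluded) are scaled
#' to the life table's radix, removed from the baseline life table with
#' [apply_under5_reduction()] (and [apply_maternal_adjustment()] when a
#' fertility schedule is supplied), and the resulting period life
#' expectancy at birth and extended Gini of age at death are recorded.
#'
#' @param projection a [project_scenario()] result.
#' @param lt baseline [life_table()].
#' @param live_births annual live births the ledger counts refer to.
#' @param fert optional [fertility_schedule()]; when `NULL`, averted
#'   maternal deaths are ignored in the life-table update.
#' @param v inequality-aversion parameter for [gini_health()] (default 2).
#' @param post_neonatal_infant_fraction passed to
#'   [apply_under5_reduction()].
#' @return data.frame with columns `year, scenario, e0_years, gini`.
#' @export
equity_trajectory <- function(projection, lt, live_births, fert = NULL,
                              v = 2, post_neonatal_infant_fraction = 0.5) {
  stopifnot(inherits(projection, "projection"), inherits(lt, "life_table"))
  led <- projection$ledger
  years <- sort(unique(projection$trajectory$year))
  radix <- attr(lt, "radix")
  out <- data.frame(year = years, scenario = projection$scenario,
                    e0_years = NA_real_, gini = NA_real_)
  for (k in seq_along(years)) {
    yr <- led[led$year == years[k] & !led$subcomponent, , drop = FALSE]
    per_radix <- function(period)
      sum(yr$averted[yr$period == period]) / live_births * radix
    lt_y <- apply_under5_reduction(
      lt, per_radix("neonatal"), per_radix("child"),
      post_neonatal_infant_fraction = post_neonatal_infant_fraction)
    mat <- per_radix("maternal")
    if (!is.null(fert) && mat > 0)
      lt_y <- apply_maternal_adjustment(lt_y, mat, fert)
    out$e0_years[k] <- life_expectancy(lt_y)
    out$gini[k] <- gini_health(distribution_from_life_table(lt_y), v = v)
  }
  out
}

format_pct <- function(x) sprintf("%.1f%%", round_half_up(x, 1))

#' Write mortality-trajectory report files
#'
#' Writes the per-year neonatal and under-five mortality trajectory of one
#' or more projections as CSV (columns
#' `year, scenario, nmr, u5mr, deaths_averted`, rates per 1,000 live
#' births) and, optionally, a trajectory figure with the MDG-4 reference
#' line at an under-five mortality rate of 68 per 1,000. The returned
#' summary flags, per scenario, whether the final-year U5MR is below the
#' MDG-4 threshold.
#'
#' @param projections a [project_scenario()] result or list of them.
#' @param dir output directory (created if needed).
#' @param plot also write `mortality_trajectory.png` (default TRUE).
#' @param mdg4 reference under-five mortality rate per 1,000 (default 68).
#' @return Invisibly, a data.frame `scenario, final_u5mr, mdg4_reached`.
#' @export
write_projection_report <- function(projections, dir, plot = TRUE,
                                    mdg4 = 68) {
  if (inherits(projections, "projection")) projections <- list(projections)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- do.call(rbind, lapply(projections, `[[`, "trajectory"))
  utils::write.csv(traj, file.path(dir, "mortality_trajectory.csv"),
                   row.names = FALSE)
  if (plot) {
    p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$year)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$u5mr,
                                      colour = .data$scenario)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$u5mr,
                                       colour = .data$scenario)) +
      ggplot2::geom_hline(yintercept = mdg4, linetype = "dotted") +
      ggplot2::labs(x = "Year", y = "U5MR per 1000 live births",
                    colour = "Scenario",
                    title = "Under-5 mortality under coverage scale-up",
                    subtitle = sprintf("dotted line: MDG-4 target (%g/1000)",
                                       mdg4))
    ggplot2::ggsave(file.path(dir, "mortality_trajectory.png"), p,
                    width = 7, height = 4.5, dpi = 150)
  }
  final <- do.call(rbind, lapply(projections, function(pr) {
    tr <- pr$trajectory
    data.frame(scenario = pr$scenario,
               final_u5mr = tr$u5mr[which.max(tr$year)],
               mdg4_reached = tr$u5mr[which.max(tr$year)] < mdg4)
  }))
  invisible(final)
}

#' Write life-expectancy / inequality report files
#'
#' Writes yearly life expectancy at birth and the extended Gini of age at
#' death per scenario as CSV (columns `year, scenario, e0_years, gini`)
#' and, optionally, a two-panel figure.
#'
#' @param trajectories an [equity_trajectory()] data.frame or list of them.
#' @param dir output directory.
#' @param plot also write `equity_trajectory.png` (default TRUE).
#' @return Invisibly, the combined trajectory data.frame.
#' @export
write_equity_report <- function(trajectories, dir, plot = TRUE) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- do.call(rbind, trajectories)
  utils::write.csv(traj, file.path(dir, "equity_trajectory.csv"),
                   row.names = FALSE)
  if (plot) {
    long <- rbind(
      data.frame(year = traj$year, scenario = traj$scenario,
                 measure = "Life expectancy at birth (years)",
                 value = traj$e0_years),
      data.frame(year = traj$year, scenario = traj$scenario,
                 measure = "Gini of age at death", value = traj$gini))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                            colour = .data$scenario)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~measure, scales = "free_y") +
      ggplot2::labs(x = "Year", y = NULL, colour = "Scenario",
                    title = "Equity impact of coverage scale-up")
    ggplot2::ggsave(file.path(dir, "equity_trajectory.png"), p,
                    width = 8, height = 4, dpi = 150)
  }
  invisible(traj)
}

#' Write a package deaths-averted report
#'
#' Emits a deaths-averted table in the layout of the published package
#' table: one row per intervention with baseline coverage and, per
#' scenario, target coverage and cumulative deaths averted; subcomponent
#' rows are flagged and excluded from the totals row. Percentages are
#' formatted to one decimal.
#'
#' @param projections named list of [project_scenario()] results (names =
#'   scenario labels).
#' @param catalogue the [intervention_catalogue()] projected.
#' @param scenarios the matching named list of [scenario()] objects.
#' @param dir output directory.
#' @param subset optional intervention ids to report a subtotal and share
#'   for (share of each scenario's computed total).
#' @return Invisibly, the report data.frame written to
#'   `deaths_averted.csv`.
#' @export
write_package_report <- function(projections, catalogue, scenarios, dir,
                                 subset = NULL) {
  stopifnot(inherits(catalogue, "intervention_catalogue"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iv <- catalogue$interventions
  out <- data.frame(intervention = iv$name, id = iv$id,
                    subcomponent = !is.na(iv$subcomponent_of),
                    baseline_coverage = format_pct(100 * iv$baseline_coverage))
  totals <- list(intervention = "Total", id = "total", subcomponent = FALSE,
                 baseline_coverage = "")
  for (nm in names(projections)) {
    rep <- aggregate_package(projections[[nm]])
    averted <- rep$by_intervention$averted[
      match(iv$id, rep$by_intervention$id)]
    averted[is.na(averted)] <- 0
    sc <- scenarios[[nm]]
    tgt <- vapply(seq_len(nrow(iv)), function(i) {
      id <- iv$id[i]
      if (id %in% names(sc$targets)) sc$targets[[id]]
      else iv$baseline_coverage[i]
    }, numeric(1))
    out[[paste0("target_", nm)]] <- format_pct(100 * tgt)
    out[[paste0("averted_", nm)]] <- round(averted)
    totals[[paste0("target_", nm)]] <- ""
    totals[[paste0("averted_", nm)]] <- round(rep$total)
  }
  out <- rbind(out, as.data.frame(totals))
  utils::write.csv(out, file.path(dir, "deaths_averted.csv"),
                   row.names = FALSE)
  if (!is.null(subset)) {
    shares <- do.call(rbind, lapply(names(projections), function(nm) {
      rep <- aggregate_package(projections[[nm]], subset = subset)
      data.frame(scenario = nm, subtotal = rep$subtotal,
                 share = format_pct(rep$share_pct))
    }))
    utils::write.csv(shares, file.path(dir, "subset_shares.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}

#' Run a full analysis from a configuration file
#'
#' Single entry point over the whole pipeline, driven by a YAML (or JSON)
#' run configuration. The config either points at input files
#' (`life_table`, `burden`, `catalogue`, `effects` CSV paths) or requests a
#' synthetic baseline (`synthetic: true` with an optional `seed`), names a
#' scenario configuration (`scenarios`: path or inline list), and sets
#' `out_dir`, optional `v` (default 2) and `years`. Writes the mortality
#' trajectory, equity trajectory and deaths-averted reports into
#' `out_dir`; reruns with the same config and seed produce identical CSVs.
#'
#' @param config path to a YAML/JSON run configuration, or an equivalent
#'   named list.
#' @return Invisibly, a list with the projections, equity trajectories and
#'   the MDG-4 summary.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("run config needs an 'out_dir'")
  v <- config$v %||% 2

  if (isTRUE(config$synthetic)) {
    cfg <- generator_config(seed = config$seed %||% 1L)
    base <- make_baseline(cfg)
    catalogue <- make_catalogue(cfg)
    lt <- base$life_table
    burden <- base$burden
    fert <- base$fertility
  } else {
    for (f in c("life_table", "burden", "catalogue", "effects"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("run config field '", f, "' must name an existing file")
    lt <- read_life_table(config$life_table)
    burden <- read_burden(config$burden)
    catalogue <- read_catalogue(config$catalogue, config$effects)
    fert <- NULL
  }

  scenarios <- if (is.character(config$scenarios))
    read_scenarios(config$scenarios, catalogue)
  else build_scenarios(catalogue, config$scenarios)

  projections <- lapply(scenarios, function(sc)
    project_scenario(burden, catalogue, sc))
  mdg <- write_projection_report(projections, config$out_dir)
  equity <- lapply(projections, equity_trajectory, lt = lt,
                   live_births = burden$live_births, fert = fert, v = v)
  write_equity_report(equity, config$out_dir)
  write_package_report(projections, catalogue, scenarios, config$out_dir)
  invisible(list(projections = projections, equity = equity,
                 mdg4 = mdg))
}
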