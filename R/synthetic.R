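# All stochastic draws go through one local RNG stream seeded from the
# config; the caller's .Random.seed is left untouched.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic baseline generator
#'
#' Targets and sizes for an Ethiopia-like 2011 baseline: an under-5
#' mortality rate of 101 and a neonatal (life-table) mortality rate of 35
#' per 1,000 live births, life expectancy at birth near 59.3 years, a
#' maternal mortality ratio of 590 per 100,000 live births, and cause-of-
#' death fractions led by neonatal causes (38%), diarrhea (22%) and
#' pneumonia (12%).
#'
#' The default cause fractions sum to 1, with neonatal causes split into
#' sepsis/asphyxia/prematurity (0.13 + 0.13 + 0.12 = 0.38) and the child
#' remainder covering diarrhea, pneumonia, malaria, measles, HIV and other.
#' Note one deliberate feature: the published cause fractions imply a
#' neonatal rate of `0.38 * 101 = 38.4` per 1,000 — not the 35 of the
#' vital-statistics table — so the burden profile (which follows cause
#' fractions) and the life table (which follows the rate targets) carry
#' slightly different neonatal counts, exactly as the source estimates do.
#'
#' @param seed integer seed for the generator's private RNG stream.
#' @param target_u5mr,target_nmr per-1,000-live-births rate targets for the
#'   life table; `target_nmr` must not exceed `target_u5mr`.
#' @param target_e0 life expectancy at birth to calibrate the adult
#'   mortality scale to, in years.
#' @param cause_fractions named vector of cause-of-death fractions for
#'   under-5 deaths; names starting with the neonatal causes listed in
#'   `neonatal_causes` are treated as neonatal period, the rest as
#'   1–59-month. Must sum to at most 1 (any remainder becomes "other").
#' @param neonatal_causes which cause names belong to the neonatal period.
#' @param live_births annual live births (default 3,180,000, which with a
#'   U5MR of 101 gives roughly 321,000 under-5 deaths per year).
#' @param mmr maternal deaths per 100,000 live births.
#' @param n_interventions number of (non-subcomponent) interventions for
#'   [make_catalogue()].
#' @param effectiveness_range interval in `[0, 1]` the synthetic
#'   effectiveness values are drawn from.
#' @return An object of class `generator_config` (a list).
#' @export
generator_config <- function(seed = 1L,
                             target_u5mr = 101,
                             target_nmr = 35,
                             target_e0 = 59.3,
                             cause_fractions = c(neonatal_sepsis = 0.13,
                                                 birth_asphyxia = 0.13,
                                                 prematurity = 0.12,
                                                 diarrhea = 0.22,
                                                 pneumonia = 0.12,
                                                 malaria = 0.07,
                                                 measles = 0.02,
                                                 hiv = 0.02,
                                                 other = 0.17),
                             neonatal_causes = c("neonatal_sepsis",
                                                 "birth_asphyxia",
                                                 "prematurity"),
                             live_births = 3180000,
                             mmr = 590,
                             n_interventions = 14L,
                             effectiveness_range = c(0.15, 0.85)) {
  if (target_nmr > target_u5mr)
    stop("infeasible targets: NMR cannot exceed U5MR")
  if (any(cause_fractions < 0) || sum(cause_fractions) > 1 + 1e-9)
    stop("cause fractions must be non-negative and sum to at most 1")
  if (sum(cause_fractions) < 1 - 1e-9) {
    cause_fractions["other"] <-
      (cause_fractions["other"] %||% 0) + (1 - sum(cause_fractions))
  }
  if (!all(neonatal_causes %in% names(cause_fractions)))
    stop("neonatal_causes must name entries of cause_fractions")
  if (effectiveness_range[1] < 0 || effectiveness_range[2] > 1 ||
      effectiveness_range[1] > effectiveness_range[2])
    stop("effectiveness_range must be an interval within [0, 1]")
  structure(list(seed = as.integer(seed), target_u5mr = target_u5mr,
                 target_nmr = target_nmr, target_e0 = target_e0,
                 cause_fractions = cause_fractions,
                 neonatal_causes = neonatal_causes,
                 live_births = live_births, mmr = mmr,
                 n_interventions = as.integer(n_interventions),
                 effectiveness_range = effectiveness_range),
            class = "generator_config")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Generate a synthetic Ethiopia-like baseline
#'
#' Builds the three baseline artifacts the projection pipeline consumes:
#'
#' * an abridged [life_table()] on the standard 21 intervals
#'   (0, 1–4, then 5-year bands to 95+) whose under-5 deaths match
#'   `target_u5mr` exactly and whose neonatal split matches `target_nmr`,
#'   with adult mortality following a Gompertz-like piecewise-constant
#'   hazard (plus a flat background) whose scale is calibrated by
#'   root-finding so that life expectancy at birth hits `target_e0`;
#' * a [burden_profile()] for 2011 allocating
#'   `target_u5mr/1000 * live_births` under-5 deaths across causes by
#'   `cause_fractions`, plus maternal deaths from `mmr`;
#' * a [fertility_schedule()] over ages 15–49 with an Ethiopia-like
#'   age pattern (total fertility rate about 3.9).
#'
#' The generator is fully deterministic for a given config (the calibration
#' is deterministic and the config's seed governs the one RNG stream), so
#' repeated calls are identical.
#'
#' @param cfg a [generator_config()].
#' @return A list with elements `life_table`, `burden`, `fertility`.
#' @examples
#' base <- make_baseline(generator_config(seed = 1))
#' implied_u5mr(base$life_table)  # 101
#' @export
make_baseline <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))

  age_start <- c(0, 1, seq(5, 95, by = 5))
  width <- c(1, 4, rep(5, 18), Inf)
  n <- length(age_start)

  radix <- 1e5
  u5_deaths <- cfg$target_u5mr / 1000 * radix
  neonatal <- cfg$target_nmr / 1000 * radix
  # Table-1-style infant mortality: split under-5 deaths into [0,1) and
  # [1,5) so that post-neonatal infant deaths roughly match the ~51%/49%
  # split implied by IMR 68.5 alongside NMR 35 and U5MR 101
  infant_deaths <- neonatal + 0.51 * (u5_deaths - neonatal)
  d_child <- u5_deaths - infant_deaths

  survivors5 <- radix - u5_deaths

  # adult hazard: background + Gompertz rise, scale calibrated on e(0)
  mid <- age_start[3:(n - 1)] + 2.5
  shape <- 0.00045 + exp(0.088 * (mid - 92))

  build <- function(scale) {
    m <- scale * shape
    surv <- exp(-5 * m)
    l <- survivors5 * cumprod(c(1, surv))
    d5 <- -diff(l)
    deaths <- c(infant_deaths, d_child, d5, l[length(l)])
    life_table(age_start, width, deaths, radix = radix,
               terminal_expectancy = 5, neonatal_deaths = neonatal)
  }
  f <- function(log_scale) life_expectancy(build(exp(log_scale))) - cfg$target_e0
  root <- stats::uniroot(f, lower = log(0.05), upper = log(50), tol = 1e-10)
  lt <- build(exp(root$root))

  fractions <- cfg$cause_fractions
  total_u5 <- cfg$target_u5mr / 1000 * cfg$live_births
  deaths <- data.frame(
    cause = names(fractions),
    period = ifelse(names(fractions) %in% cfg$neonatal_causes,
                    "neonatal", "child"),
    deaths = as.numeric(fractions) * total_u5)
  deaths <- rbind(deaths,
                  data.frame(cause = "maternal", period = "maternal",
                             deaths = cfg$mmr / 1e5 * cfg$live_births))
  burden <- burden_profile(2011L, cfg$live_births, deaths)

  # Ethiopia-like ASFR shape (births per woman-year), TFR ~ 3.9
  fert <- fertility_schedule(
    age_start = seq(15, 45, by = 5),
    width = rep(5, 7),
    rate = c(0.072, 0.212, 0.211, 0.152, 0.089, 0.035, 0.009))

  list(life_table = lt, burden = burden, fertility = fert)
}

# Table-2-style intervention template: class, delivery level, subcomponent
# linkage and targeted causes mirror the published package; the numeric
# effectiveness / affected-fraction / coverage values are synthetic.
catalogue_template <- function() {
  iv <- data.frame(
    id = c("institutional_delivery", "labor_delivery_mgmt", "ors",
           "pneumonia_case_mgmt", "breastfeeding", "neonatal_infection_mgmt",
           "antimalarials", "pneumococcal_vaccine", "zinc_treatment",
           "itn_irs", "postnatal_care", "kangaroo_care", "pmtct",
           "water_source", "measles_vaccine"),
    name = c("Institutional delivery", "Labor and delivery management",
             "Oral Rehydration Solution", "Case management of pneumonia",
             "Breastfeeding", "Case management of severe neonatal infection",
             "Antimalarials", "Pneumococcal vaccine", "Zinc for treatment",
             "Insecticide treated materials or indoor residual spraying",
             "Preventive postnatal care", "Kangaroo mother care",
             "Prevention of Mother To Child Transmission of HIV (PMTCT)",
             "Improved water source", "Measles vaccine"),
    class = c("preventive", "preventive", "curative", "curative",
              "preventive", "curative", "curative", "preventive",
              "curative", "preventive", "preventive", "preventive",
              "preventive", "preventive", "preventive"),
    level = c("facility", "facility", "community", "community", "community",
              "facility", "community", "outreach", "community", "outreach",
              "outreach", "facility", "facility", "community", "outreach"),
    subcomponent_of = c(NA, "institutional_delivery", rep(NA, 13)),
    stringsAsFactors = FALSE)
  causes <- list(
    institutional_delivery = c("birth_asphyxia", "prematurity", "maternal"),
    labor_delivery_mgmt = c("birth_asphyxia", "maternal"),
    ors = "diarrhea",
    pneumonia_case_mgmt = "pneumonia",
    breastfeeding = c("diarrhea", "pneumonia", "neonatal_sepsis"),
    neonatal_infection_mgmt = "neonatal_sepsis",
    antimalarials = "malaria",
    pneumococcal_vaccine = "pneumonia",
    zinc_treatment = "diarrhea",
    itn_irs = "malaria",
    postnatal_care = "neonatal_sepsis",
    kangaroo_care = "prematurity",
    pmtct = "hiv",
    water_source = "diarrhea",
    measles_vaccine = "measles")
  list(interventions = iv, causes = causes)
}

#' Generate a synthetic intervention catalogue
#'
#' Produces an [intervention_catalogue()] with the structure of the
#' published 14-intervention child-health package — classes, delivery
#' levels, targeted causes, and the labor-and-delivery-management
#' subcomponent nested in institutional delivery — but with synthetic
#' numeric values: per-cause effectiveness drawn uniformly from
#' `cfg$effectiveness_range`, affected fractions from `[0.3, 1]` and
#' baseline coverages from `[0, 0.8]`, all from the config's seeded stream.
#' The template guarantees preventive/curative pairs sharing a cause (e.g.
#' pneumococcal vaccine and pneumonia case management), so package
#' interaction effects are exercisable.
#'
#' For `n_interventions = 14` (the default) the catalogue has the 14
#' primary interventions plus the subcomponent row. Other values of `n`
#' recycle or truncate the template's non-subcomponent rows.
#'
#' @param cfg a [generator_config()].
#' @return An [intervention_catalogue()].
#' @export
make_catalogue <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  tpl <- catalogue_template()
  iv <- tpl$interventions
  top <- which(is.na(iv$subcomponent_of))
  n <- cfg$n_interventions
  if (n < 1) stop("n_interventions must be at least 1")
  keep_top <- top[((seq_len(n) - 1L) %% length(top)) + 1L]
  if (anyDuplicated(keep_top)) {
    # recycling beyond the template: clone rows under fresh ids
    keep_top <- unique(keep_top)
    extra <- n - length(keep_top)
  } else extra <- 0L
  keep <- sort(unique(c(keep_top,
                        which(iv$subcomponent_of %in% iv$id[keep_top]))))
  iv <- iv[keep, , drop = FALSE]
  if (extra > 0L) {
    clones <- iv[rep(which(is.na(iv$subcomponent_of)),
                     length.out = extra), , drop = FALSE]
    clones$id <- paste0(clones$id, "_v", seq_len(extra) + 1L)
    clones$name <- paste(clones$name, "(variant)")
    iv <- rbind(iv, clones)
  }
  rownames(iv) <- NULL

  with_local_seed(cfg$seed, {
    iv$baseline_coverage <- round(stats::runif(nrow(iv), 0, 0.8), 3)
    cause_map <- tpl$causes
    effects <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      base_id <- sub("_v[0-9]+$", "", iv$id[i])
      cs <- cause_map[[base_id]]
      data.frame(id = iv$id[i], cause = cs,
                 effectiveness = round(stats::runif(
                   length(cs), cfg$effectiveness_range[1],
                   cfg$effectiveness_range[2]), 3),
                 affected_fraction = round(stats::runif(length(cs), 0.3, 1), 3),
                 stringsAsFactors = FALSE)
    }))
    rownames(effects) <- NULL
    intervention_catalogue(iv, effects)
  })
}

#' Published deaths-averted reference table
#'
#' The printed deaths-averted table for the Ethiopian 2011–2015 scale-up
#' package, stored verbatim as packaged CSV: per intervention, the 2011
#' coverage, and for each of the three scenarios (government targets; 90%
#' of all 14; 90% of the top five) the target coverage and cumulative
#' deaths averted by 2015. The labor-and-delivery-management row is flagged
#' as a subcomponent of institutional delivery and is excluded from totals.
#'
#' The printed totals row is returned separately from the body rows because
#' the Scenario 1 column famously does not sum to its printed total: the
#' rows add to 120,500 against a printed 114,600 (the 5,900 gap equals the
#' improved-water-source and measles rows). `table2_fixture()` surfaces
#' this rather than reconciling it; see the package report helpers.
#'
#' @return A list with `rows` (data.frame: `intervention, id, subcomponent,
#'   current_coverage_pct`, and `target_scX_pct`/`averted_scX` for
#'   X = 1,2,3) and `printed_totals` (named vector sc1/sc2/sc3).
#' @examples
#' fx <- table2_fixture()
#' sum(fx$rows$averted_sc2[!fx$rows$subcomponent])  # 217200
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "deaths_averted_table.csv",
                      package = "equilife", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  totals <- raw[raw$id == "total", ]
  rows <- raw[raw$id != "total", ]
  rows$subcomponent <- !is.na(rows$subcomponent_of) & rows$subcomponent_of != ""
  rownames(rows) <- NULL
  list(rows = rows[, c("intervention", "id", "subcomponent",
                       "current_coverage_pct",
                       "target_sc1_pct", "averted_sc1",
                       "target_sc2_pct", "averted_sc2",
                       "target_sc3_pct", "averted_sc3")],
       printed_totals = c(sc1 = totals$averted_sc1,
                          sc2 = totals$averted_sc2,
                          sc3 = totals$averted_sc3))
}

#' Aggregate one scenario column of the reference table
#'
#' Runs the package-aggregation arithmetic over the fixture rows of one
#' scenario: cumulative deaths averted per intervention, the package total
#' excluding the subcomponent row, and (optionally) a named-subset subtotal
#' with its percentage share. Shares quoted in the source are computed
#' against the *printed* totals, so `share basis = "printed"` reproduces
#' them; the computed row sum is always reported alongside, surfacing the
#' Scenario 1 discrepancy.
#'
#' @param scenario_id `"sc1"`, `"sc2"` or `"sc3"`.
#' @param subset optional intervention ids for a subtotal (e.g. the five
#'   most effective interventions).
#' @param share_basis `"printed"` (default) or `"computed"`: denominator
#'   for the percentage share.
#' @return A list: `total` (computed row sum, subcomponents excluded),
#'   `printed_total`, `discrepancy` (computed - printed), and if `subset`
#'   given, `subtotal` and `share_pct` (one decimal, half-up).
#' @export
fixture_report <- function(scenario_id = c("sc1", "sc2", "sc3"),
                           subset = NULL, share_basis = c("printed",
                                                          "computed")) {
  scenario_id <- match.arg(scenario_id)
  share_basis <- match.arg(share_basis)
  fx <- table2_fixture()
  led <- data.frame(id = fx$rows$id,
                    averted = fx$rows[[paste0("averted_", scenario_id)]],
                    subcomponent = fx$rows$subcomponent)
  printed <- unname(fx$printed_totals[scenario_id])
  rep <- aggregate_package(led, subset = subset,
                           total_basis = if (share_basis == "printed")
                             printed else NULL)
  out <- list(total = rep$total, printed_total = printed,
              discrepancy = rep$total - printed)
  if (!is.null(subset)) {
    out$subtotal <- rep$subtotal
    out$share_pct <- rep$share_pct
  }
  out
}

#' The five most effective interventions of the reference package
#'
#' Ids of the five interventions with the highest deaths averted under the
#' 90%-coverage scenario: institutional delivery, oral rehydration
#' solution, case management of pneumonia, breastfeeding, and case
#' management of severe neonatal infection. These define the third
#' (top-five) scenario.
#'
#' @return Character vector of five intervention ids.
#' @export
top_five_interventions <- function() {
  c("institutional_delivery", "ors", "pneumonia_case_mgmt",
    "breastfeeding", "neonatal_infection_mgmt")
}
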