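#' Intervention catalogue
#'
#' An intervention catalogue couples the interventions themselves (id, name,
#' class, delivery level, baseline coverage, optional subcomponent linkage)
#' with their cause-specific effects. Each effect row gives, for one cause of
#' death, the effectiveness `E` (fraction of deaths prevented at full
#' coverage among those the intervention can affect) and the affected
#' fraction `AF` (share of the cause's deaths the intervention can reach).
#'
#' A subcomponent intervention (`subcomponent_of` set) is nested inside its
#' parent: in the lives-saved cascade it is evaluated against the residual
#' left after its parent, and it is excluded from package totals so its
#' deaths are not double-counted.
#'
#' @param interventions data.frame with columns
#'   `id, name, class, level, baseline_coverage, subcomponent_of`; `class`
#'   is `"preventive"` or `"curative"`, `level` one of
#'   `"community"/"outreach"/"facility"`, `subcomponent_of` is `NA` or the
#'   id of another catalogue member.
#' @param effects data.frame with columns
#'   `id, cause, effectiveness, affected_fraction`; both fractions in
#'   `[0, 1]`.
#' @return An object of class `intervention_catalogue`.
#' @seealso [run_cascade()], [build_scenarios()], [make_catalogue()]
#' @export
intervention_catalogue <- function(interventions, effects) {
  need_i <- c("id", "name", "class", "level", "baseline_coverage",
              "subcomponent_of")
  need_e <- c("id", "cause", "effectiveness", "affected_fraction")
  miss <- setdiff(need_i, names(interventions))
  if (length(miss))
    stop("interventions table is missing column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(need_e, names(effects))
  if (length(miss))
    stop("effects table is missing column(s): ", paste(miss, collapse = ", "))

  if (anyDuplicated(interventions$id))
    stop("intervention ids must be unique")
  if (!all(interventions$class %in% c("preventive", "curative")))
    stop("intervention class must be 'preventive' or 'curative'")
  if (!all(interventions$level %in% c("community", "outreach", "facility")))
    stop("delivery level must be community, outreach or facility")
  cv <- interventions$baseline_coverage
  if (any(cv < 0 | cv > 1)) stop("baseline coverage must lie in [0, 1]")
  sub <- interventions$subcomponent_of
  bad <- !is.na(sub) & !(sub %in% interventions$id)
  if (any(bad))
    stop("subcomponent_of refers to unknown intervention(s): ",
         paste(sub[bad], collapse = ", "))
  if (any(!is.na(sub) & sub == interventions$id))
    stop("an intervention cannot be a subcomponent of itself")
  # nesting one level deep only: a subcomponent's parent must be a top-level
  # intervention, which also rules out cycles
  parent_is_sub <- !is.na(sub) &
    !is.na(interventions$subcomponent_of[match(sub, interventions$id)])
  if (any(parent_is_sub))
    stop("subcomponent chains/cycles are not allowed: ",
         paste(interventions$id[parent_is_sub], collapse = ", "))

  if (!all(effects$id %in% interventions$id))
    stop("effects refer to unknown intervention id(s): ",
         paste(setdiff(effects$id, interventions$id), collapse = ", "))
  if (any(effects$effectiveness < 0 | effects$effectiveness > 1))
    stop("effectiveness must lie in [0, 1]")
  if (any(effects$affected_fraction < 0 | effects$affected_fraction > 1))
    stop("affected_fraction must lie in [0, 1]")
  if (anyDuplicated(effects[, c("id", "cause")]))
    stop("duplicate (id, cause) rows in effects")

  structure(list(interventions = as.data.frame(interventions),
                 effects = as.data.frame(effects)),
            class = "intervention_catalogue")
}

#' @export
print.intervention_catalogue <- function(x, ...) {
  iv <- x$interventions
  cat(sprintf("Intervention catalogue: %d interventions (%d subcomponent), %d effect rows\n",
              nrow(iv), sum(!is.na(iv$subcomponent_of)), nrow(x$effects)))
  print.data.frame(iv[, c("id", "class", "level", "baseline_coverage",
                          "subcomponent_of")], row.names = FALSE)
  invisible(x)
}

#' Read and write an intervention catalogue as CSV
#'
#' The catalogue is stored in two CSV files: the interventions themselves
#' (`id,name,class,level,baseline_coverage,subcomponent_of`) and their
#' effects (`id,cause,effectiveness,affected_fraction`).
#'
#' @param path,effects_path CSV file paths.
#' @return `read_catalogue` returns an [intervention_catalogue()].
#' @export
read_catalogue <- function(path, effects_path) {
  iv <- utils::read.csv(path, stringsAsFactors = FALSE)
  ef <- utils::read.csv(effects_path, stringsAsFactors = FALSE)
  if ("subcomponent_of" %in% names(iv)) {
    iv$subcomponent_of[iv$subcomponent_of %in% c("", "NA")] <- NA
  } else iv$subcomponent_of <- NA_character_
  intervention_catalogue(iv, ef)
}

#' @rdname read_catalogue
#' @param catalogue an [intervention_catalogue()].
#' @export
write_catalogue <- function(catalogue, path, effects_path) {
  stopifnot(inherits(catalogue, "intervention_catalogue"))
  iv <- catalogue$interventions
  iv$subcomponent_of[is.na(iv$subcomponent_of)] <- ""
  utils::write.csv(iv, path, row.names = FALSE)
  utils::write.csv(catalogue$effects, effects_path, row.names = FALSE)
  invisible(path)
}

#' Define a scale-up scenario
#'
#' A scenario names a target coverage for a subset of interventions at
#' `end_year`; coverage moves from each intervention's baseline in
#' `start_year` to its target by linear interpolation. Interventions absent
#' from `targets` stay at baseline coverage throughout.
#'
#' @param name scenario label.
#' @param start_year,end_year calendar years, `end_year > start_year`.
#' @param targets named numeric vector (or list), intervention id ->
#'   target coverage fraction in `[0, 1]`. May be empty.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, start_year, end_year, targets = numeric()) {
  targets <- unlist(targets)
  if (is.null(targets)) targets <- numeric()
  if (end_year <= start_year) stop("end_year must exceed start_year")
  if (length(targets) && (is.null(names(targets)) || any(names(targets) == "")))
    stop("targets must be named by intervention id")
  if (any(targets < 0 | targets > 1))
    stop("target coverage must lie in [0, 1]")
  structure(list(name = name, start_year = as.integer(start_year),
                 end_year = as.integer(end_year), targets = targets),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d-%d): %d target(s)\n", x$name, x$start_year,
              x$end_year, length(x$targets)))
  if (length(x$targets))
    print(round(x$targets, 3))
  invisible(x)
}

#' Linear coverage interpolation
#'
#' Coverage scales up by linear interpolation from `c0` at year `y0` to
#' `c1` at year `y1`.
#'
#' @param c0,c1 coverage fractions at `y0` and `y1`.
#' @param y0,y1 start and end years, `y0 < y1`.
#' @param t evaluation year, within `[y0, y1]`.
#' @return Coverage fraction at `t`.
#' @examples
#' interpolate_coverage(0.157, 0.65, 2011, 2015, 2013)  # 0.4035
#' @export
interpolate_coverage <- function(c0, c1, y0, y1, t) {
  if (any(c(c0, c1) < 0) || any(c(c0, c1) > 1))
    stop("coverage fractions must lie in [0, 1]")
  if (y1 <= y0) stop("y1 must exceed y0")
  if (t < y0 || t > y1)
    stop(sprintf("year %g outside the interpolation range [%g, %g]", t, y0, y1))
  c0 + (c1 - c0) * (t - y0) / (y1 - y0)
}

#' Build scenarios from a configuration
#'
#' Turns a configuration (a list, or a YAML/JSON file read with
#' [read_scenarios()]) into validated [scenario()] objects against a
#' catalogue. Every target id must exist in the catalogue. A subcomponent
#' intervention without an explicit target inherits its parent's target, so
#' it scales up together with the intervention it is nested in; an explicit
#' target overrides the inherited one.
#'
#' @param catalogue an [intervention_catalogue()].
#' @param config list of scenario specifications, each with fields
#'   `name, start_year, end_year, targets`.
#' @return A named list of [scenario()] objects.
#' @export
build_scenarios <- function(catalogue, config) {
  stopifnot(inherits(catalogue, "intervention_catalogue"))
  iv <- catalogue$interventions
  out <- lapply(config, function(sc) {
    targets <- unlist(sc$targets)
    if (is.null(targets)) targets <- numeric()
    unknown <- setdiff(names(targets), iv$id)
    if (length(unknown))
      stop("scenario '", sc$name, "' targets unknown intervention(s): ",
           paste(unknown, collapse = ", "))
    subs <- iv$id[!is.na(iv$subcomponent_of)]
    for (s in subs) {
      parent <- iv$subcomponent_of[iv$id == s]
      if (!(s %in% names(targets)) && parent %in% names(targets))
        targets[s] <- targets[[parent]]
    }
    scenario(sc$name, sc$start_year, sc$end_year, targets)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Read and write scenario configurations
#'
#' Scenario configurations are stored as YAML (or JSON) documents: a list of
#' scenarios, each with `name`, `start_year`, `end_year` and a `targets`
#' mapping of intervention id to target coverage fraction.
#'
#' @param path file path; format chosen by extension (`.json` for JSON,
#'   anything else parsed as YAML).
#' @param catalogue an [intervention_catalogue()] used for validation.
#' @return `read_scenarios` returns a named list of [scenario()] objects.
#' @export
read_scenarios <- function(path, catalogue) {
  config <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  build_scenarios(catalogue, config)
}

#' @rdname read_scenarios
#' @param scenarios a list of [scenario()] objects.
#' @export
write_scenarios <- function(scenarios, path) {
  config <- lapply(unname(scenarios), function(sc)
    list(name = sc$name, start_year = sc$start_year, end_year = sc$end_year,
         targets = as.list(sc$targets)))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Yearly coverage trajectory for one intervention under a scenario
#'
#' One coverage value per calendar year from the scenario's start to end
#' year, linearly interpolated from the intervention's baseline coverage to
#' its scenario target (or held at baseline if the scenario does not target
#' it).
#'
#' @param scenario a [scenario()].
#' @param intervention one row of the catalogue's interventions table (or a
#'   list with `id` and `baseline_coverage`).
#' @return Named numeric vector, year -> coverage fraction.
#' @export
coverage_path <- function(scenario, intervention) {
  stopifnot(inherits(scenario, "scenario"))
  years <- seq(scenario$start_year, scenario$end_year)
  c0 <- intervention$baseline_coverage
  c1 <- if (intervention$id %in% names(scenario$targets))
    scenario$targets[[intervention$id]] else c0
  out <- vapply(years, function(t)
    interpolate_coverage(c0, c1, scenario$start_year, scenario$end_year, t),
    numeric(1))
  names(out) <- years
  out
}
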