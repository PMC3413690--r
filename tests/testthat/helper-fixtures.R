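# Shared builders for tests; everything is generated in code.

# standard-ish four-interval table used by the adjustment tests
toy_life_table <- function(neonatal = 3500) {
  life_table(age_start = c(0, 1, 5, 60), width = c(1, 4, 55, Inf),
             deaths = c(6850, 3250, 20000, 69900),
             neonatal_deaths = neonatal)
}

# constant-hazard table on a fine grid; closed form e(0) = 1/m
constant_hazard_table <- function(m = 0.02, width = 0.1, n = 2000) {
  starts <- (seq_len(n) - 1) * width
  surv <- exp(-m * c(starts, n * width))
  deaths <- 1e5 * (-diff(surv))
  deaths <- c(deaths, 1e5 * surv[n + 1])
  life_table(c(starts, n * width), c(rep(width, n), Inf), deaths,
             terminal_expectancy = 1 / m)
}

random_death_distribution <- function(max_groups = 12) {
  k <- sample(2:max_groups, 1)
  h <- stats::runif(k, 0, 100)
  f <- stats::rgamma(k, 1)
  death_distribution(h, f / sum(f))
}

# two interventions acting on one cause; preventive then curative
two_step_catalogue <- function(e1 = 0.5, e2 = 0.4, af1 = 1, af2 = 1,
                               c0 = c(0, 0)) {
  intervention_catalogue(
    data.frame(id = c("prev", "cure"), name = c("Preventive", "Curative"),
               class = c("preventive", "curative"),
               level = c("outreach", "facility"),
               baseline_coverage = c0, subcomponent_of = c(NA, NA)),
    data.frame(id = c("prev", "cure"), cause = "pneumonia",
               effectiveness = c(e1, e2), affected_fraction = c(af1, af2)))
}

tiny_burden <- function(births = 1e5) {
  burden_profile(2011, births, data.frame(
    cause = c("neonatal_sepsis", "pneumonia", "diarrhea", "maternal"),
    period = c("neonatal", "child", "child", "maternal"),
    deaths = c(3500, 2000, 3000, 590)))
}
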