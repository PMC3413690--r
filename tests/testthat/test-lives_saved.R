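test_that("the elementary impact formula matches hand evaluation", {
  expect_equal(single_impact(1000, 0.5, 1, 0.3, 0.3)$averted, 0)
  expect_equal(single_impact(1000, 0.5, 1, 0, 1)$averted, 500)
  # deaths=1000, E=0.8, AF=0.5, c0=0.25, ct=0.90:
  # 1000 * (0.4 * 0.65) / (1 - 0.4 * 0.25) = 260/0.9
  expect_equal(single_impact(1000, 0.8, 0.5, 0.25, 0.90)$averted, 260 / 0.9)
  expect_equal(single_impact(1000, 0.8, 0.5, 0.25, 0.90)$residual,
               1000 - 260 / 0.9)
  # coverage loss yields negative averted (increased deaths), not an error
  expect_lt(single_impact(1000, 0.5, 1, 0.8, 0.4)$averted, 0)
  expect_error(single_impact(1000, 1, 1, 1, 1), "degenerate baseline")
})

test_that("a cascade of length one reduces to the single-impact formula", {
  catal <- intervention_catalogue(
    data.frame(id = "ors", name = "ORS", class = "curative",
               level = "community", baseline_coverage = 0.37,
               subcomponent_of = NA),
    data.frame(id = "ors", cause = "diarrhea", effectiveness = 0.7,
               affected_fraction = 0.9))
  res <- run_cascade(tiny_burden(), catal, c(ors = 0.9))
  expect_equal(res$ledger$averted,
               single_impact(3000, 0.7, 0.9, 0.37, 0.9)$averted)

  # empty coverage map: nothing changes
  res0 <- run_cascade(tiny_burden(), catal)
  expect_equal(res0$ledger$averted, 0)
  expect_equal(res0$residual$deaths$deaths, tiny_burden()$deaths$deaths)
})

test_that("sequential residuals combine multiplicatively", {
  e1 <- 0.5; e2 <- 0.4; D <- 2000
  catal <- two_step_catalogue(e1, e2)
  res <- run_cascade(tiny_burden(), catal, c(prev = 1, cure = 1))
  total <- sum(res$ledger$averted)
  expect_equal(total, D * (1 - (1 - e1) * (1 - e2)), tolerance = 1e-12)
  # preventive is applied first and takes D*e1; curative gets the residual
  expect_equal(res$ledger$averted[res$ledger$id == "prev"], D * e1)
  expect_equal(res$ledger$averted[res$ledger$id == "cure"],
               D * (1 - e1) * e2)
})

test_that("dropping an upstream intervention inflates the downstream one", {
  catal <- two_step_catalogue(0.5, 0.4)
  both <- run_cascade(tiny_burden(), catal, c(prev = 1, cure = 1))
  only_cure <- run_cascade(tiny_burden(), catal, c(cure = 1))
  averted_with <- both$ledger$averted[both$ledger$id == "cure"]
  averted_without <- only_cure$ledger$averted[only_cure$ledger$id == "cure"]
  expect_gt(averted_without, averted_with)
})

test_that("total package impact is invariant to catalogue order", {
  cfg <- generator_config(seed = 4)
  catal <- make_catalogue(cfg)
  burden <- make_baseline(cfg)$burden
  cov <- stats::setNames(rep(0.9, nrow(catal$interventions)),
                         catal$interventions$id)
  base_run <- run_cascade(burden, catal, cov)
  totals <- function(res) {
    led <- res$ledger[!res$ledger$subcomponent, ]
    out <- tapply(led$averted, led$cause, sum)
    out[order(names(out))]
  }
  set.seed(99)
  for (rep in 1:5) {
    perm <- sample(nrow(catal$interventions))
    shuffled <- intervention_catalogue(catal$interventions[perm, ],
                                       catal$effects)
    res <- run_cascade(burden, shuffled, cov)
    expect_equal(totals(res), totals(base_run), tolerance = 1e-9)
  }
})

test_that("baseline deaths are conserved as residual plus attributed averted", {
  cfg <- generator_config(seed = 4)
  catal <- make_catalogue(cfg)
  burden <- make_baseline(cfg)$burden
  cov <- stats::setNames(rep(0.9, nrow(catal$interventions)),
                         catal$interventions$id)
  res <- run_cascade(burden, catal, cov)
  led <- res$ledger[!res$ledger$subcomponent, ]
  for (cause in burden$deaths$cause) {
    base_d <- burden$deaths$deaths[burden$deaths$cause == cause]
    resid <- res$residual$deaths$deaths[res$residual$deaths$cause == cause]
    averted <- sum(led$averted[led$cause == cause])
    expect_equal(base_d, resid + averted, tolerance = 1e-9 * max(base_d, 1))
  }
})

test_that("raising one target never lowers its impact or raises residuals", {
  cfg <- generator_config(seed = 8)
  catal <- make_catalogue(cfg)
  burden <- make_baseline(cfg)$burden
  cov <- stats::setNames(rep(0.6, nrow(catal$interventions)),
                         catal$interventions$id)
  lo <- run_cascade(burden, catal, cov)
  cov["ors"] <- 0.95
  hi <- run_cascade(burden, catal, cov)
  ors_lo <- sum(lo$ledger$averted[lo$ledger$id == "ors"])
  ors_hi <- sum(hi$ledger$averted[hi$ledger$id == "ors"])
  expect_gte(ors_hi, ors_lo)
  expect_lte(sum(hi$residual$deaths$deaths),
             sum(lo$residual$deaths$deaths))
})

test_that("subcomponents see the residual after their parent and stay out of totals", {
  catal <- intervention_catalogue(
    data.frame(id = c("parent", "sub"),
               name = c("Parent", "Sub"),
               class = "preventive", level = "facility",
               baseline_coverage = c(0.2, 0.1),
               subcomponent_of = c(NA, "parent")),
    data.frame(id = c("parent", "sub"), cause = "neonatal_sepsis",
               effectiveness = c(0.6, 0.5), affected_fraction = 1))
  res <- run_cascade(tiny_burden(), catal, c(parent = 0.9, sub = 0.9))
  parent_averted <- res$ledger$averted[res$ledger$id == "parent"]
  sub_averted <- res$ledger$averted[res$ledger$id == "sub"]
  # sub evaluated on the post-parent residual, but residual ignores it
  expect_equal(sub_averted,
               single_impact(3500 - parent_averted, 0.5, 1, 0.1, 0.9)$averted)
  expect_equal(
    res$residual$deaths$deaths[res$residual$deaths$cause == "neonatal_sepsis"],
    3500 - parent_averted)
  expect_true(res$ledger$subcomponent[res$ledger$id == "sub"])
})

test_that("catalogue validation rejects subcomponent cycles and bad refs", {
  iv <- data.frame(id = c("a", "b"), name = c("A", "B"),
                   class = "preventive", level = "community",
                   baseline_coverage = 0.1, subcomponent_of = c("b", "a"))
  ef <- data.frame(id = "a", cause = "diarrhea", effectiveness = 0.5,
                   affected_fraction = 1)
  expect_error(intervention_catalogue(iv, ef), "chains/cycles")
  iv$subcomponent_of <- c("missing", NA)
  expect_error(intervention_catalogue(iv, ef), "unknown intervention")
  iv$subcomponent_of <- c("a", NA)
  expect_error(intervention_catalogue(iv, ef), "subcomponent of itself")
})

test_that("projection trajectories behave at the extremes", {
  cfg <- generator_config(seed = 6)
  base <- make_baseline(cfg)
  catal <- make_catalogue(cfg)

  null_pr <- project_scenario(base$burden, catal, scenario("null", 2011, 2015))
  expect_equal(unique(null_pr$trajectory$nmr), burden_nmr(base$burden))
  expect_equal(unique(null_pr$trajectory$u5mr), burden_u5mr(base$burden))
  expect_equal(unique(null_pr$trajectory$deaths_averted), 0)

  # all-powerful package: E = 1, AF = 1 on every cause, full coverage
  causes <- base$burden$deaths$cause
  perfect <- intervention_catalogue(
    data.frame(id = "everything", name = "Everything", class = "preventive",
               level = "community", baseline_coverage = 0,
               subcomponent_of = NA),
    data.frame(id = "everything", cause = causes, effectiveness = 1,
               affected_fraction = 1))
  pr <- project_scenario(base$burden, perfect,
                         scenario("total", 2011, 2015,
                                  targets = c(everything = 1)))
  expect_equal(pr$trajectory$u5mr[pr$trajectory$year == 2015], 0,
               tolerance = 1e-9)
})

test_that("cumulative totals and subset shares aggregate correctly", {
  cfg <- generator_config(seed = 6)
  base <- make_baseline(cfg)
  catal <- make_catalogue(cfg)
  ids <- catal$interventions$id[is.na(catal$interventions$subcomponent_of)]
  sc <- scenario("sc2", 2011, 2015,
                 stats::setNames(rep(0.9, length(ids)), ids))
  pr <- project_scenario(base$burden, catal, sc)
  rep <- aggregate_package(pr, subset = top_five_interventions())
  expect_equal(rep$total, sum(pr$trajectory$deaths_averted), tolerance = 1e-9)
  expect_equal(rep$subtotal,
               sum(pr$ledger$averted[pr$ledger$id %in%
                                       top_five_interventions()]),
               tolerance = 1e-9)
  expect_equal(rep$share_pct, round(rep$subtotal / rep$total * 100, 1),
               tolerance = 0.051)
  expect_error(aggregate_package(pr, subset = "bogus"), "unknown")

  one <- aggregate_package(data.frame(id = "x", averted = 123,
                                      subcomponent = FALSE))
  expect_equal(one$total, 123)
})
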