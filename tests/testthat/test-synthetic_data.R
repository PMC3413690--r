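test_that("the synthetic baseline hits its demographic targets", {
  base <- make_baseline(generator_config(seed = 1))
  lt <- base$life_table
  expect_equal(implied_u5mr(lt), 101, tolerance = 0.5 / 101)
  expect_equal(implied_nmr(lt), 35, tolerance = 0.5 / 35)
  expect_gt(life_expectancy(lt), 55)
  expect_lt(life_expectancy(lt), 65)

  b <- base$burden
  u5 <- b$deaths$deaths[b$deaths$period != "maternal"]
  neo_share <- sum(b$deaths$deaths[b$deaths$period == "neonatal"]) / sum(u5)
  expect_equal(neo_share, 0.38, tolerance = 0.02 / 0.38)
  expect_equal(burden_u5mr(b), 101, tolerance = 0.5 / 101)
  # the burden follows the cause-of-death fractions, so its implied
  # neonatal rate sits near 38-39, not the vital-statistics 35
  expect_equal(burden_nmr(b), 38.4, tolerance = 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  a <- make_baseline(generator_config(seed = 123))
  b <- make_baseline(generator_config(seed = 123))
  expect_identical(a, b)
  ca <- make_catalogue(generator_config(seed = 123))
  cb <- make_catalogue(generator_config(seed = 123))
  expect_identical(ca, cb)
  # a different seed moves the stochastic parts
  cc <- make_catalogue(generator_config(seed = 124))
  expect_false(identical(ca$interventions$baseline_coverage,
                         cc$interventions$baseline_coverage))
})

test_that("generator calls do not disturb the global RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(make_catalogue(generator_config(seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("infeasible or malformed configs are rejected", {
  expect_error(generator_config(target_u5mr = 30, target_nmr = 35),
               "NMR cannot exceed U5MR")
  expect_error(generator_config(effectiveness_range = c(0.9, 0.2)),
               "effectiveness_range")
  expect_error(generator_config(cause_fractions = c(diarrhea = 1.5)),
               "cause fractions")
})

test_that("the synthetic catalogue has the reference-package structure", {
  catal <- make_catalogue(generator_config(seed = 2))
  iv <- catal$interventions
  expect_equal(sum(is.na(iv$subcomponent_of)), 14L)
  expect_false(anyDuplicated(iv$id) > 0)
  expect_true(all(iv$baseline_coverage >= 0 & iv$baseline_coverage <= 0.8))
  expect_equal(iv$subcomponent_of[iv$id == "labor_delivery_mgmt"],
               "institutional_delivery")

  # a preventive/curative pair sharing a cause exists (interaction property)
  ef <- merge(catal$effects, iv[, c("id", "class")], by = "id")
  pneu <- ef[ef$cause == "pneumonia", ]
  expect_true(all(c("preventive", "curative") %in% pneu$class))
  rng <- generator_config(seed = 2)$effectiveness_range
  expect_true(all(catal$effects$effectiveness >= rng[1] &
                    catal$effects$effectiveness <= rng[2]))
})

test_that("generator output passes every consuming module's validation", {
  cfg <- generator_config(seed = 31)
  base <- make_baseline(cfg)
  catal <- make_catalogue(cfg)
  # round-trip through the I/O layer revalidates every artifact
  lt_path <- withr::local_tempfile(fileext = ".csv")
  bu_path <- withr::local_tempfile(fileext = ".csv")
  iv_path <- withr::local_tempfile(fileext = ".csv")
  ef_path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(base$life_table, lt_path)
  write_burden(base$burden, bu_path)
  write_catalogue(catal, iv_path, ef_path)
  expect_s3_class(read_life_table(lt_path), "life_table")
  expect_s3_class(read_burden(bu_path), "burden_profile")
  expect_s3_class(read_catalogue(iv_path, ef_path), "intervention_catalogue")
})

test_that("a 90% scale-up improves all three headline outcomes", {
  cfg <- generator_config(seed = 1)
  base <- make_baseline(cfg)
  catal <- make_catalogue(cfg)
  ids <- catal$interventions$id[is.na(catal$interventions$subcomponent_of)]
  sc <- scenario("sc2", 2011, 2015,
                 stats::setNames(rep(0.9, length(ids)), ids))
  pr <- project_scenario(base$burden, catal, sc)
  expect_lt(pr$trajectory$u5mr[5], burden_u5mr(base$burden))
  expect_true(all(diff(pr$trajectory$u5mr) < 0))
  expect_true(all(diff(pr$trajectory$nmr) < 0))

  eq <- equity_trajectory(pr, base$life_table, base$burden$live_births,
                          fert = base$fertility)
  expect_gt(eq$e0_years[5], life_expectancy(base$life_table))
  expect_lt(eq$gini[5],
            gini_health(distribution_from_life_table(base$life_table)))
})

test_that("the packaged reference table is stored verbatim", {
  fx <- table2_fixture()
  rows <- fx$rows
  expect_equal(nrow(rows), 15L)
  expect_equal(sum(!rows$subcomponent), 14L)
  expect_equal(rows$averted_sc2[rows$id == "ors"], 42600)
  expect_equal(rows$current_coverage_pct[rows$id == "institutional_delivery"],
               15.7)
  expect_equal(rows$target_sc3_pct[rows$id == "antimalarials"], 8.0)
  expect_true(rows$subcomponent[rows$id == "labor_delivery_mgmt"])
  expect_equal(unname(fx$printed_totals),
               c(114600, 217200, 164400))
})
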