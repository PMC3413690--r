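test_that("perfect equality gives zero at any aversion level", {
  d <- death_distribution(60, 1)
  expect_equal(gini_health(d, v = 2), 0, tolerance = 1e-12)
  expect_equal(gini_health(d, v = 5), 0, tolerance = 1e-12)
  expect_equal(gini_oracle(d), 0)
})

test_that("the two-group case matches the hand-computed value 1/6", {
  # G = sum f_i f_j |h_i - h_j| / (2 mu) = 2*0.25*40 / 120 = 1/6
  d <- death_distribution(c(40, 80), c(0.5, 0.5))
  expect_equal(gini_health(d, v = 2), 1 / 6, tolerance = 1e-12)
  expect_equal(gini_oracle(d), 1 / 6, tolerance = 1e-12)
  expect_equal(gini_health(d, v = 1), 0)
})

test_that("v = 2 agrees with the pairwise oracle on 1000 random distributions", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    d <- random_death_distribution()
    worst <- max(worst, abs(gini_health(d, v = 2) - gini_oracle(d)))
  }
  expect_lt(worst, 1e-10)
})

test_that("v = 2 also equals the fractional-rank covariance identity", {
  set.seed(17)
  for (i in 1:50) {
    d <- random_death_distribution()
    mu <- sum(d$h * d$f)
    cov_rank <- sum(d$f * d$h * d$rank) - mu * sum(d$f * d$rank)
    # ranks run best-off first, so the covariance with h is negative
    expect_equal(gini_health(d, v = 2), -2 / mu * cov_rank,
                 tolerance = 1e-10)
  }
})

test_that("scaling ages leaves the coefficient unchanged; shifting lowers it", {
  set.seed(7)
  for (i in 1:20) {
    d <- random_death_distribution()
    scaled <- death_distribution(d$h * 3.7, d$f)
    shifted <- death_distribution(d$h + 25, d$f)
    for (v in c(1.5, 2, 3)) {
      expect_equal(gini_health(scaled, v), gini_health(d, v),
                   tolerance = 1e-12)
      expect_lt(gini_health(shifted, v), gini_health(d, v))
    }
  }
})

test_that("the coefficient is non-decreasing in the aversion parameter", {
  set.seed(13)
  vs <- c(1, 1.25, 1.5, 2, 3, 4, 6, 10)
  for (i in 1:20) {
    d <- random_death_distribution()
    g <- vapply(vs, function(v) gini_health(d, v), numeric(1))
    expect_true(all(diff(g) >= -1e-12))
    expect_true(all(g >= -1e-12 & g <= 1))
  }
})

test_that("mass moved to a higher-age group weakly raises inequality", {
  d0 <- death_distribution(c(20, 50, 80), c(0.3, 0.4, 0.3))
  d1 <- death_distribution(c(20, 50, 80), c(0.35, 0.4, 0.25))  # worse-off grows
  expect_gt(gini_health(d1), gini_health(d0))
})

test_that("group order and tied ages do not affect the result", {
  d_sorted <- death_distribution(c(10, 40, 70), c(0.2, 0.3, 0.5))
  d_perm <- death_distribution(c(70, 10, 40), c(0.5, 0.2, 0.3))
  d_ties <- death_distribution(c(10, 40, 40, 70), c(0.2, 0.1, 0.2, 0.5))
  expect_equal(gini_health(d_perm), gini_health(d_sorted))
  expect_equal(gini_health(d_ties), gini_health(d_sorted))
  expect_equal(nrow(d_ties), 3L)  # ties merged before ranking
})

test_that("all deaths at age zero is an undefined coefficient", {
  d <- death_distribution(0, 1)
  expect_error(gini_health(d), "undefined")
  expect_error(gini_oracle(d), "undefined")
})

test_that("distributions are validated", {
  expect_error(death_distribution(c(10, 20), c(0.6, 0.6)), "sum to")
  expect_error(death_distribution(c(-1, 20), c(0.5, 0.5)), "non-negative")
  # zero-proportion groups are dropped
  d <- death_distribution(c(10, 20, 30), c(0.5, 0, 0.5))
  expect_equal(nrow(d), 2L)
})

test_that("life tables map to midpoint distributions consistently", {
  # all deaths in one interval -> a single group and zero inequality
  lt <- life_table(c(0, 1, 5), c(1, 4, Inf), c(0, 1e5, 0))
  d <- distribution_from_life_table(lt)
  expect_equal(nrow(d), 1L)
  expect_equal(d$h, 1 + 0.4 * 4)
  expect_equal(gini_health(d), 0)

  # uniform 100-interval table: package value equals the oracle on the
  # same midpoint distribution
  n <- 100
  ult <- life_table(0:(n - 1), c(rep(1, n - 1), Inf), rep(1e3, n),
                    a_x = rep(0.5, n), terminal_expectancy = 0.5)
  ud <- distribution_from_life_table(ult)
  expect_equal(gini_health(ud), gini_oracle(ud), tolerance = 1e-12)
  expect_equal(ud$h, seq(0.5, 99.5, by = 1)[order(-seq_len(n))])
})

test_that("the synthetic baseline lies in the plausible inequality band", {
  lt <- make_baseline(generator_config(seed = 1))$life_table
  g <- gini_health(distribution_from_life_table(lt))
  expect_gt(g, 0.10)
  expect_lt(g, 0.50)
})

test_that("averting child deaths lowers inequality and raises expectancy", {
  lt <- make_baseline(generator_config(seed = 1))$life_table
  adj <- apply_under5_reduction(lt, 1500, 1500)
  expect_lt(gini_health(distribution_from_life_table(adj)),
            gini_health(distribution_from_life_table(lt)))
  expect_gt(life_expectancy(adj), life_expectancy(lt))
})

test_that("death distributions read from either CSV schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age_at_death = c(40, 80),
                              proportion = c(0.5, 0.5)),
                   path, row.names = FALSE)
  d <- read_death_distribution(path)
  expect_equal(gini_health(d), 1 / 6, tolerance = 1e-12)

  lt_path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(toy_life_table(), lt_path)
  d2 <- read_death_distribution(lt_path)
  expect_equal(sum(d2$f), 1, tolerance = 1e-12)

  out <- withr::local_tempfile(fileext = ".csv")
  write_gini_summary(d, out)
  summ <- utils::read.csv(out)
  expect_equal(names(summ), c("v", "gini", "mu", "n_groups"))
  expect_equal(summ$mu, 60)
})
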