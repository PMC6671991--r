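test_that("chi-square GOF equals the brute-force formula", {
  expect_equal(chisq_gof(c(25, 25, 25, 25))$statistic, 0)
  g <- chisq_gof(c(10, 20))
  expect_equal(g$statistic, 10 / 3)
  expect_equal(g$df, 1)
  # all count vectors of length <= 6 with varied totals, vs the oracle
  set.seed(31)
  for (k in 1:60) {
    len <- sample(2:6, 1)
    counts <- as.integer(rmultinom(1, sample(5:50, 1), rep(1, len)))
    g <- chisq_gof(counts)
    expect_equal(g$statistic, chisq_oracle(counts))
    expect_equal(g$p, pchisq(chisq_oracle(counts), len - 1,
                             lower.tail = FALSE))
  }
  # p decreases as counts grow more skewed at fixed total
  expect_gt(chisq_gof(c(30, 30))$p, chisq_gof(c(50, 10))$p)
  expect_error(chisq_gof(c(1, 1), expected = c(1, 0)))
  expect_error(chisq_gof(c(0, 0)))
})

test_that("count trends recover closed-form slopes in both families", {
  years <- 2000:2012
  # exactly exponential series: poisson-log slope = b
  b <- 0.07
  series <- tibble::tibble(year = years, count = exp(1.2 + b * years))
  fit <- suppressWarnings(fit_yearly_counts(series, "poisson-log"))
  expect_equal(fit$slope_per_year, b, tolerance = 1e-6)
  # exactly linear series: gaussian-identity slope = least-squares oracle
  series2 <- tibble::tibble(year = years, count = 5 + 3.25 * (years - 2000))
  fit2 <- fit_yearly_counts(series2, "gaussian-identity")
  expect_equal(fit2$slope_per_year,
               ls_slope_oracle(series2$year, series2$count),
               tolerance = 1e-8)
  # constant series: slope 0; p ~ 1 under the likelihood-based Poisson SE
  # (the Gaussian fit has zero residual variance, so its p is degenerate)
  series3 <- tibble::tibble(year = years, count = rep(40, length(years)))
  fit3 <- fit_yearly_counts(series3, "gaussian-identity")
  expect_equal(fit3$slope_per_year, 0, tolerance = 1e-10)
  fit3p <- fit_yearly_counts(series3, "poisson-log")
  expect_equal(fit3p$slope_per_year, 0, tolerance = 1e-10)
  expect_gt(fit3p$p, 0.99)
  expect_error(fit_yearly_counts(tibble::tibble(year = c(2000, 2001),
                                                count = c(1, 2))))
})

test_that("both GLM families recover planted slopes on noisy series", {
  set.seed(19)
  hits_p <- hits_g <- 0
  n_rep <- 40
  for (k in seq_len(n_rep)) {
    yrs <- 2000:2016
    lam <- exp(3 + 0.05 * (yrs - 2000))
    sp <- fit_yearly_counts(tibble::tibble(year = yrs,
                                           count = rpois(length(yrs), lam)),
                            "poisson-log")
    if (abs(sp$slope_per_year - 0.05) <= 2 * sp$se) hits_p <- hits_p + 1
    mu <- 100 + 4 * (yrs - 2000)
    sg <- fit_yearly_counts(
      tibble::tibble(year = yrs, count = mu + rnorm(length(yrs), 0, 10)),
      "gaussian-identity")
    if (abs(sg$slope_per_year - 4) <= 2 * sg$se) hits_g <- hits_g + 1
  }
  expect_gte(hits_p / n_rep, 0.85)
  expect_gte(hits_g / n_rep, 0.85)
})

test_that("jeopardy rates reproduce printed one-decimal percentages", {
  expect_equal(jeopardy_rate(60, 3012, digits = 1), 2.0)
  expect_equal(jeopardy_rate(9, 186, digits = 1), 4.8)
  expect_equal(jeopardy_rate(0, 100), 0)
  expect_equal(jeopardy_rate(1, 3), 100 / 3)
  expect_error(jeopardy_rate(1, 0))
  expect_error(jeopardy_rate(5, 3))
  # half-up rounding, not round-half-even
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

test_that("outcome summary tallies consultations and their partitions", {
  rec <- tibble::tibble(
    consultation_id = rep(sprintf("C%02d", 1:20), each = 1),
    type = c(rep("formal", 4), rep("informal", 16)),
    expert_final = c("jeopardy", rep("no jeopardy", 3), rep("NLAA", 16)),
    critical_habitat = c("no critical habitat", "adverse modification",
                         rep("no critical habitat", 18))
  )
  s <- consultation_outcome_summary(rec)
  expect_equal(s$formal_pct, 20)
  expect_equal(s$jeopardy_pct_of_formal, 25)
  expect_equal(s$jeopardy_pct_of_all, 5)
  # jeopardy-without-AM and AM-without-jeopardy are disjoint tallies
  expect_equal(s$n_jeopardy_without_am, 1)
  expect_equal(s$n_am_without_jeopardy, 1)
  expect_lte(s$jeopardy_pct_of_all, s$jeopardy_pct_of_formal)
  # no formal consultations: formal-based percentages undefined but flagged
  s2 <- consultation_outcome_summary(rec[rec$type == "informal", ])
  expect_true(s2$formal_denominator_empty)
  expect_true(is.na(s2$jeopardy_pct_of_formal))
})

test_that("frequency tables conserve totals across groupings", {
  rec <- generate_consultations(synthetic_config(n_consultations = 150,
                                                 seed = 2))
  for (key in c("agency", "work_type", "region")) {
    ft <- frequency_table(rec, key)
    expect_equal(attr(ft, "total"),
                 length(unique(rec$consultation_id)))
    expect_true(all(diff(ft$n) <= 0))
  }
  expect_error(frequency_table(rec, "banana"))
})

test_that("the jeopardy-rate trend fits proportions against year", {
  series <- tibble::tibble(year = 2000:2010, jeopardy = rep(2, 11),
                           formal = rep(100, 11))
  fit <- fit_jeopardy_trend(series)
  expect_equal(fit$slope_per_year, 0, tolerance = 1e-12)
  series2 <- tibble::tibble(year = 2000:2010,
                            jeopardy = seq(2, 22, 2), formal = 100)
  fit2 <- fit_jeopardy_trend(series2)
  expect_equal(fit2$slope_per_year,
               ls_slope_oracle(series2$year, series2$jeopardy / 100),
               tolerance = 1e-10)
  expect_error(fit_jeopardy_trend(series[1, ]))
})
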