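test_that("pooling sums per-variant frequencies and tracks missing data", {
  v <- make_variants(2, ac_all = c(10, 5), an_all = c(1000, 500))
  p <- pool_allele_frequencies(v, "all", an_strategy = "mean")
  expect_equal(p$q_sum, 0.02)
  expect_equal(p$ac_total, 15)
  expect_equal(p$an_effective, 750)
  expect_equal(p$n_missing, 0)
  expect_equal(pool_allele_frequencies(v, "all",
                                       an_strategy = "min")$an_effective,
               500)
  expect_equal(pool_allele_frequencies(v, "all",
                                       an_strategy = "fixed:282912")$an_effective,
               282912)

  # frequencies alone also pool; counts stay at zero
  fx <- tmprss6_missense_variants()
  pf <- pool_allele_frequencies(fx, "all", an_strategy = "fixed:282912")
  expect_equal(pf$q_sum, sum(fx$af_global), tolerance = 1e-12)
  expect_equal(pf$q_sum, 5.57911e-4, tolerance = 1e-9)
  expect_equal(pf$n_with_counts, 0)

  # a population with no data is reported missing, not an error
  pm <- pool_allele_frequencies(v, "eas")
  expect_equal(pm$q_sum, 0)
  expect_equal(pm$n_missing, pm$n_variants)
  expect_true(is.na(pm$an_effective))

  empty <- pool_allele_frequencies(make_variants(0), "all")
  expect_equal(empty$q_sum, 0)
  expect_equal(empty$ac_total, 0)

  expect_error(pool_allele_frequencies(v, "martian"),
               class = "carrierprev_config_error")
  expect_error(pool_allele_frequencies(v, "all", an_strategy = "fixed:-1"),
               class = "carrierprev_config_error")
})

test_that("prevalence and carrier formulas match hand-computed oracles", {
  # (1 - 0.99 * 0.98)^2 and 0.03^2, by hand
  expect_equal(genetic_prevalence(c(0.01, 0.02), "exact"), 8.8804e-4,
               tolerance = 1e-12)
  expect_equal(genetic_prevalence(c(0.01, 0.02), "approx"), 9e-4,
               tolerance = 1e-12)
  expect_equal(genetic_prevalence(numeric(0)), 0)
  expect_equal(genetic_prevalence(c(0, 0, 0)), 0)

  expect_equal(carrier_frequency(0.25, "exact"), 0.375)
  expect_equal(carrier_frequency(0.25, "approx"), 0.5)
  expect_equal(carrier_frequency(0, "exact"), 0)
  expect_equal(carrier_frequency(0, "approx"), 0)

  expect_error(genetic_prevalence(c(0.1, 1.2)),
               class = "carrierprev_validation_error")
  expect_error(carrier_frequency(-0.1),
               class = "carrierprev_validation_error")

  # exact never exceeds approx, equality only at zero
  q <- seq(0, 1, by = 0.05)
  expect_true(all(carrier_frequency(q, "exact") <=
                  carrier_frequency(q, "approx")))
  eq <- carrier_frequency(q, "exact") == carrier_frequency(q, "approx")
  expect_equal(which(eq), 1L)
})

test_that("first-order formulas stay within the Taylor bound for rare alleles", {
  withr::with_seed(421, {
    for (rep in 1:50) {
      k <- sample(2:60, 1)
      q <- runif(k, 0, 1e-2 / k) # guarantees sum(q) <= 1e-2
      s <- sum(q)
      prev_exact <- genetic_prevalence(q, "exact")
      prev_approx <- genetic_prevalence(q, "approx")
      expect_lt(abs(prev_exact - prev_approx) / prev_approx, 2e-2)
      car_exact <- carrier_frequency(s, "exact")
      car_approx <- carrier_frequency(s, "approx")
      expect_lt(abs(car_exact - car_approx) / car_approx, 2e-2)
    }
  })
})

test_that("Wilson interval matches an independent score-equation solve", {
  grid <- expand.grid(
    ac = c(0, 1, 5, 50, 286),
    an = c(10, 100, 1000, 282912),
    level = c(0.9, 0.95, 0.99)
  )
  grid <- grid[grid$ac <= grid$an, ]
  grid <- rbind(grid, data.frame(ac = c(10, 282912), an = c(10, 282912),
                                 level = 0.95))
  for (i in seq_len(nrow(grid))) {
    wi <- wilson_interval(grid$ac[i], grid$an[i], grid$level[i])
    oracle <- wilson_oracle(grid$ac[i], grid$an[i], grid$level[i])
    expect_lt(abs(wi$low - oracle["low"]), 1e-10)
    expect_lt(abs(wi$high - oracle["high"]), 1e-10)
  }
  # second independent route: the score interval in stats::prop.test
  pt <- prop.test(286, 282912, correct = FALSE)$conf.int
  wi <- wilson_interval(286, 282912)
  expect_equal(wi$low, pt[1], tolerance = 1e-10)
  expect_equal(wi$high, pt[2], tolerance = 1e-10)
})

test_that("Wilson interval honours its boundary and containment guarantees", {
  expect_equal(wilson_interval(0, 100)$low, 0)
  expect_equal(wilson_interval(50, 50)$high, 1)
  wi <- wilson_interval(286, 282912)
  expect_equal(wi$low, 9.004e-4, tolerance = 1e-4)
  expect_equal(wi$high, 1.135e-3, tolerance = 1e-4)
  cases <- data.frame(ac = c(0, 1, 7, 99, 100), an = 100)
  wi <- wilson_interval(cases$ac, cases$an)
  expect_true(all(wi$low <= cases$ac / cases$an))
  expect_true(all(wi$high >= cases$ac / cases$an))
  expect_true(all(wi$low >= 0 & wi$high <= 1))
  expect_error(wilson_interval(5, 0), class = "carrierprev_validation_error")
  expect_error(wilson_interval(11, 10), class = "carrierprev_validation_error")
  expect_error(wilson_interval(5, 10, level = 1),
               class = "carrierprev_validation_error")
})

test_that("population estimates propagate one allele-scale interval to both scales", {
  v <- make_variants(2, ac_all = c(10, 5), an_all = c(1000, 1000))
  pooled <- pool_allele_frequencies(v, "all", an_strategy = "mean")
  est <- estimate_population(pooled, method = "approx")
  wi <- wilson_interval(15, 1000)
  expect_equal(est$carrier$ci_low, 2 * wi$low)
  expect_equal(est$carrier$ci_high, 2 * wi$high)
  expect_equal(est$prevalence$ci_low, wi$low^2)
  expect_equal(est$prevalence$ci_high, wi$high^2)
  expect_equal(est$carrier$point, 2 * 0.015)
  expect_equal(est$prevalence$point, 0.015^2)
  # interval ordering on both scales
  expect_true(est$prevalence$ci_low <= est$prevalence$point)
  expect_true(est$prevalence$point <= est$prevalence$ci_high)
  expect_true(est$carrier$ci_low <= est$carrier$point)
  expect_true(est$carrier$point <= est$carrier$ci_high)
  # carrier exceeds prevalence whenever q < 1/2
  expect_gt(est$carrier$point, est$prevalence$point)

  # zero-frequency input yields zero estimates with a zero lower bound
  v0 <- make_variants(1, ac_all = 0, an_all = 1000)
  est0 <- estimate_population(pool_allele_frequencies(v0, "all"))
  expect_equal(est0$prevalence$point, 0)
  expect_equal(est0$prevalence$ci_low, 0)

  # wider allele-scale intervals give nested transformed intervals
  small <- make_variants(1, ac_all = 10, an_all = 1000)
  big <- make_variants(1, ac_all = 10000, an_all = 1000000)
  est_small <- estimate_population(pool_allele_frequencies(small, "all"))
  est_big <- estimate_population(pool_allele_frequencies(big, "all"))
  expect_lt(est_big$carrier$ci_high - est_big$carrier$ci_low,
            est_small$carrier$ci_high - est_small$carrier$ci_low)
  expect_true(est_big$carrier$ci_low >= est_small$carrier$ci_low)
  expect_true(est_big$carrier$ci_high <= est_small$carrier$ci_high)

  # no effective allele number -> explicit error, never a silent guess
  fx <- tmprss6_missense_variants()
  pooled_na <- pool_allele_frequencies(fx, "all", an_strategy = "mean")
  expect_error(estimate_population(pooled_na),
               class = "carrierprev_validation_error")
})
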