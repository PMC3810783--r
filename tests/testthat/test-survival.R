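test_that("KM estimate matches hand product-limit results", {
  st <- makeSurv(c(1, 2, 3))
  km <- kmEstimate(st, "A")
  expect_equal(km$event_times, c(1, 2, 3))
  expect_equal(km$survival, c(2/3, 1/3, 0))

  # with censoring, agree with the independent recursion on random tables
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    tm <- round(runif(n, 1, 100))
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1L
    st <- makeSurv(tm, ev)
    km <- kmEstimate(st, "A")
    orc <- oracleKM(tm, ev)
    expect_equal(km$event_times, orc$event_times)
    expect_equal(km$survival, orc$survival)
  }
})

test_that("KM handles degenerate censoring patterns", {
  allcens <- kmEstimate(makeSurv(c(5, 8, 9), c(0, 0, 0)), "A")
  expect_length(allcens$event_times, 0)
  expect_true(is.na(medianSurvival(allcens)))

  one <- kmEstimate(makeSurv(5), "A")
  expect_equal(one$survival, 0)
  expect_equal(medianSurvival(one), 5)

  expect_error(kmEstimate(makeSurv(1:3), "missing"), "not present")
})

test_that("KM equals 1 - ECDF when nothing is censored", {
  set.seed(7)
  for (i in 1:10) {
    tm <- sample(50:500, sample(10:60, 1), replace = TRUE)
    km <- kmEstimate(makeSurv(tm), "A")
    ecdf_vals <- 1 - ecdf(tm)(km$event_times)
    expect_equal(km$survival, ecdf_vals)
  }
})

test_that("median survival follows the S(t) <= 0.5 convention", {
  expect_equal(medianSurvival(kmEstimate(makeSurv(c(1, 2, 3)), "A")), 2)
  expect_equal(medianSurvival(kmEstimate(makeSurv(c(4, 4, 4, 4)), "A")), 4)
  heavy <- kmEstimate(makeSurv(c(1, 10, 10, 10, 10),
                               c(1, 0, 0, 0, 0)), "A")
  expect_true(min(heavy$survival) > 0.5)
  expect_true(is.na(medianSurvival(heavy)))
})

test_that("percent change reproduces median-lifespan contrasts", {
  expect_equal(percentChange(931, 636)$rounded, 46L)
  expect_equal(round(percentChange(931, 636)$percent, 1), 46.4)
  expect_equal(percentChange(931, 636)$difference, 295)
  expect_equal(percentChange(1156, 956)$rounded, 21L)
  expect_equal(percentChange(700, 700)$percent, 0)
  expect_error(percentChange(500, 0), "positive")
})

test_that("log-rank test is symmetric and null on identical groups", {
  a <- makeSurv(c(10, 20, 30, 40), group = "A")
  b <- makeSurv(c(10, 20, 30, 40), group = "B")
  lr <- logrankTest(bindSurv(a, b), "A", "B")
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(5)
  c1 <- makeSurv(round(runif(30, 10, 100)), group = "A")
  c2 <- makeSurv(round(runif(25, 30, 120)), group = "B")
  tab <- bindSurv(c1, c2)
  expect_equal(logrankTest(tab, "A", "B")$chi2,
               logrankTest(tab, "B", "A")$chi2)
  expect_warning(
    logrankTest(bindSurv(makeSurv(1:5, rep(0L, 5), "A"), c2), "A", "B"),
    "zero observed events")
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(11)
  ps <- replicate(300, {
    st <- genSurvivalCohort(list(
      list(label = "A", n = 30, shape = 0.005, rate = 1e-4),
      list(label = "B", n = 30, shape = 0.005, rate = 1e-4)),
      seed = sample.int(1e6, 1))
    logrankTest(st, "A", "B")$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("maximal-lifespan quantile test matches exact enumeration", {
  st <- bindSurv(makeSurv(1:10, group = "A"), makeSurv(11:20, group = "B"))
  ml <- maxlifeQuantileTest(st, "A", "B")
  expect_equal(unname(ml$counts), rbind(c(0, 10), c(2, 8)))
  expect_equal(ml$p, 0.4737, tolerance = 1e-4)
  expect_equal(ml$p, oracleFisherTwoSided(ml$counts))
})

test_that("pooled threshold keeps at most 10 percent strictly beyond", {
  set.seed(23)
  for (i in 1:20) {
    tm <- round(runif(sample(12:80, 1), 100, 1200))
    g <- rep(c("A", "B"), length.out = length(tm))
    st <- SurvivalTable(sprintf("m%03d", seq_along(tm)), g, tm,
                        rep(1L, length(tm)))
    ml <- maxlifeQuantileTest(st, "A", "B")
    expect_lte(mean(tm > ml$threshold_age), 0.10)
  }
})

test_that("maximal-lifespan test guards its preconditions", {
  ident <- bindSurv(makeSurv(c(100, 200, 300, 400, 500, 600), group = "A"),
                    makeSurv(c(100, 200, 300, 400, 500, 600), group = "B"))
  expect_equal(maxlifeQuantileTest(ident, "A", "B")$percent_change_q90, 0)

  small <- bindSurv(makeSurv(1:4, group = "A"), makeSurv(5:8, group = "B"))
  expect_error(maxlifeQuantileTest(small, "A", "B"), "fewer than 10")

  cens <- bindSurv(makeSurv(1:10, group = "A"),
                   makeSurv(11:20, c(rep(1L, 9), 0L), group = "B"))
  expect_warning(maxlifeQuantileTest(cens, "A", "B"), "censored")
})
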