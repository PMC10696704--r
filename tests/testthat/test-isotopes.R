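test_that("delta/ratio/atom-fraction conversions match their definitions", {
  expect_identical(deltaToRatio(0), 0.0112372)
  expect_equal(deltaToRatio(1000), 2 * 0.0112372)
  expect_error(deltaToRatio(-1000), "exceed -1000")
  expect_equal(ratioToAtomFraction(0), 0)
  expect_equal(ratioToAtomFraction(1), 0.5)
  expect_equal(ratioToAtomFraction(0.0112372), 0.0112372 / 1.0112372)
})

test_that("delta -> ratio -> atom fraction chain is strictly increasing and invertible", {
  deltas <- seq(-900, 5000, length.out = 201)
  n <- ratioToAtomFraction(deltaToRatio(deltas))
  expect_true(all(diff(n) > 0))
  expect_true(all(n >= 0 & n < 1))
  back <- ratioToDelta(atomFractionToRatio(n))
  expect_equal(back, deltas, tolerance = 1e-12)
})

test_that("the worked incubation matches an independent step-by-step oracle", {
  inc <- tracerIncubation(delta0 = -25, deltaT = 100, poc0 = 10, pocT = 10,
                          t = 1, caDic = 2000, csDic = 3000)
  res <- dicAssimilationRate(inc)
  expect_false(res$bdl)
  expect_equal(res$rate, oracleRate(-25, 100, 10, 10, 1, 2000, 3000),
               tolerance = 1e-12)
  expect_equal(res$rate, 0.022875, tolerance = 1e-6 / 0.022875)
})

test_that("rate is linear in the labeled-POC excess and scales by the dilution factor", {
  base <- oracleRate(-25, 50, 10, 10, 1, 0, 3000)  # no ambient DIC
  for (ca in c(0, 1000, 4000)) {
    inc <- tracerIncubation(-25, 50, 10, 10, 1, ca, 3000)
    expect_equal(dicAssimilationRate(inc)$rate, base * (ca + 3000) / 3000,
                 tolerance = 1e-12)
  }
  # doubling incubation time halves the rate
  inc2 <- tracerIncubation(-25, 50, 10, 10, 2, 2000, 3000)
  inc1 <- tracerIncubation(-25, 50, 10, 10, 1, 2000, 3000)
  expect_equal(dicAssimilationRate(inc2)$rate,
               dicAssimilationRate(inc1)$rate / 2, tolerance = 1e-12)
})

test_that("detection-limit handling flags sub-precision delta shifts as BDL", {
  cfg <- runConfig()
  null <- tracerIncubation(-25, -25, 10, 10, 1, 2000, 3000)
  res <- dicAssimilationRate(null, cfg)
  expect_true(res$bdl)
  expect_true(is.na(res$rate))
  expect_gt(res$detectionLimit, 0)
  # the detection limit is the rate a precision-sized shift would imply
  expect_equal(res$detectionLimit,
               oracleRate(-25, -25 + 0.1, 10, 10, 1, 2000, 3000),
               tolerance = 1e-12)
  # just above precision: a real (tiny) rate
  above <- tracerIncubation(-25, -25 + 0.11, 10, 10, 1, 2000, 3000)
  expect_false(dicAssimilationRate(above, cfg)$bdl)
  # sub-precision negative excursions clamp to BDL, larger ones are inconsistent
  neg <- tracerIncubation(-25, -25.08, 10, 10, 1, 2000, 3000)
  res2 <- dicAssimilationRate(neg, cfg)
  expect_true(res2$bdl)
  expect_true(is.na(res2$rate))
  worse <- tracerIncubation(-25, -40, 10, 10, 1, 2000, 3000)
  expect_error(dicAssimilationRate(worse, cfg), "inconsistent")
})

test_that("replicate averaging reproduces printed condition means and the ND rule", {
  wv65 <- averageReplicates(c(1.43, 1.68, 1.38))
  expect_equal(round(wv65$mean, 2), 1.50)
  expect_equal(wv65$n, 3L)
  expect_equal(wv65$sd, sd(c(1.43, 1.68, 1.38)))
  yv45 <- averageReplicates(c(0.017, 0.012, 0.013))
  expect_equal(round(yv45$mean, 3), 0.014)
  allBdl <- averageReplicates(c(NA, NA, NA), bdl = c(TRUE, TRUE, TRUE))
  expect_true(allBdl$nd)
  expect_equal(allBdl$n, 0L)
  expect_error(averageReplicates(numeric(0)), "no replicates")
  # RateResult list input: BDL replicates are dropped from the mean
  cfg <- runConfig()
  rs <- list(dicAssimilationRate(tracerIncubation(-25, 100, 10, 10, 1, 2000, 3000), cfg),
             dicAssimilationRate(tracerIncubation(-25, -25, 10, 10, 1, 2000, 3000), cfg))
  avg <- averageReplicates(rs)
  expect_equal(avg$n, 1L)
  expect_equal(avg$mean, oracleRate(-25, 100, 10, 10, 1, 2000, 3000),
               tolerance = 1e-12)
})
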