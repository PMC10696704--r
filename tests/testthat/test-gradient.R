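test_that("min-max normalization maps min to 0, max to 1 and is idempotent", {
  gp <- gradientProfile("s", density = c(1.70, 1.72, 1.74),
                        copies = c(2, 8, 4))
  norm <- normalizeProfile(gp)
  expect_equal(fractions(norm)$copies, c(0, 1, 1 / 3))
  expect_equal(fractions(norm)$density, fractions(gp)$density)
  again <- normalizeProfile(norm)
  expect_equal(fractions(again)$copies, fractions(norm)$copies)
  # order preservation on a random profile
  gp2 <- randomProfile(20, seed = 11)
  n2 <- fractions(normalizeProfile(gp2))$copies
  expect_equal(order(n2), order(fractions(gp2)$copies))
  expect_equal(min(n2), 0)
  expect_equal(max(n2), 1)
  flat <- gradientProfile("s", density = c(1.70, 1.72, 1.74),
                          copies = c(5, 5, 5))
  expect_error(normalizeProfile(flat), "degenerate")
})

test_that("peak density is the argmax fraction with heavier-side tie break", {
  gp <- gradientProfile("s", density = c(1.70, 1.72, 1.74),
                        copies = c(100, 500, 300))
  expect_equal(peakDensity(gp), 1.72)
  tie <- gradientProfile("s", density = c(1.71, 1.72, 1.73),
                         copies = c(500, 100, 500))
  expect_equal(peakDensity(tie), 1.73)
})

test_that("fractions are labeled by half-open density windows", {
  cfg <- runConfig()
  gp <- gradientProfile("s",
                        density = c(1.680, 1.690, 1.700, 1.712, 1.715,
                                    1.735, 1.750, 1.760, 1.762),
                        copies = rep(1, 9))
  lab <- as.character(classifyFractions(gp, cfg))
  expect_equal(lab, c("outside", "L", "L", "outside", "H",
                      "UH", "UH", "UH", "outside"))
  # boundary densities belong to the upper window: 1.735 is UH, not H
  expect_equal(lab[6], "UH")
  # labels partition the profile
  expect_equal(length(lab), 9)
  expect_false(any(is.na(lab)))
})

test_that("selected fractions maximize summed copies over contiguous runs", {
  cfg <- runConfig()
  gp <- gradientProfile("s", density = c(1.716, 1.720, 1.724, 1.728),
                        copies = c(1, 5, 4, 2))
  sel <- selectFractions(gp, "H", cfg, k = 2)
  expect_equal(sel$fractionIds, c("F2", "F3"))
  expect_equal(sel$summedCopies, 9)
  sel1 <- selectFractions(gp, "H", cfg, k = 1)
  expect_equal(sel1$fractionIds, "F2")
  expect_error(selectFractions(gp, "UH", cfg), "no fraction")
})

test_that("selection agrees with exhaustive search on random profiles", {
  cfg <- runConfig()
  for (i in 1:200) {
    gp <- randomProfile(sample(5:30, 1), seed = 1000 + i)
    labels <- classifyFractions(gp, cfg)
    copies <- fractions(gp)$copies
    for (w in c("L", "H", "UH")) {
      idx <- which(labels == w)
      if (!length(idx)) next
      for (k in seq_len(min(3, length(idx)))) {
        sel <- selectFractions(gp, w, cfg, k = k)
        orc <- oracleSelect(copies, idx, k)
        expect_equal(sel$summedCopies, orc$sum)
        expect_equal(sel$fractionIds, fractions(gp)$fraction_id[orc$run])
      }
    }
  }
})

test_that("cross-feeding verdict follows the peak-density comparison", {
  mk <- function(peakAt) {
    d <- seq(1.70, 1.76, by = 0.005)
    gradientProfile("s", density = d, copies = dnorm(d, peakAt, 0.006))
  }
  expect_equal(crossfeedCheck(mk(1.735), mk(1.730))$verdict, "negligible")
  expect_equal(crossfeedCheck(mk(1.725), mk(1.730))$verdict, "suspected")
  same <- crossfeedCheck(mk(1.730), mk(1.730))
  expect_equal(same$verdict, "suspected")
  expect_equal(same$difference, 0)
  # non-single-peaked input warns
  d <- seq(1.70, 1.76, by = 0.005)
  bimodal <- gradientProfile("s", density = d,
                             copies = dnorm(d, 1.71, 0.004) +
                                      dnorm(d, 1.75, 0.004))
  expect_warning(crossfeedCheck(bimodal, mk(1.72)), "single-peaked")
})

test_that("a dually labeled population bands almost entirely in the UH window", {
  cfg <- runConfig()
  pops <- data.frame(name = "auto", gc = 0.38, state = "C13N15",
                     abundance = 1e6, band_sigma = 0.004)
  gp <- simulateGradient(pops, seq(1.66, 1.79, by = 0.002), noiseCv = 0,
                         seed = 1)
  lab <- classifyFractions(gp, cfg)
  copies <- fractions(gp)$copies
  expect_gte(sum(copies[lab == "UH"]) / sum(copies), 0.99)
})
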