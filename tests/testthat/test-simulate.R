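test_that("gradient bands sit at the GC-implied density with labeling shifts", {
  grid <- seq(1.66, 1.80, by = 0.004)
  pop <- data.frame(name = "A", gc = 0.40, state = "unlabeled",
                    abundance = 1e6, band_sigma = 0.004)
  gp <- simulateGradient(pop, grid, noiseCv = 0, seed = 1)
  expect_equal(peakDensity(gp), grid[which.min(abs(grid - (1.660 + 0.098 * 0.40)))])
  gp13 <- simulateGradient(transform(pop, state = "C13"), grid, noiseCv = 0,
                           seed = 1)
  expect_equal(peakDensity(gp13), grid[which.min(abs(grid - (1.6992 + 0.036)))])
  gp1315 <- simulateGradient(transform(pop, state = "C13N15"), grid,
                             noiseCv = 0, seed = 1)
  expect_equal(peakDensity(gp1315),
               grid[which.min(abs(grid - (1.6992 + 0.036 + 0.016)))])
  # total copies approximately conserved when the grid covers the band
  expect_equal(sum(fractions(gp)$copies), 1e6, tolerance = 0.01)
})

test_that("gradient generator validates inputs and honors the seeding contract", {
  grid <- seq(1.66, 1.78, by = 0.004)
  pop <- data.frame(name = "A", gc = 0.4, state = "C13", abundance = 1e6,
                    band_sigma = 0.004)
  expect_error(simulateGradient(pop[0, ], grid), "at least one population")
  expect_error(simulateGradient(pop, rev(grid)), "strictly increasing")
  a <- simulateGradient(pop, grid, noiseCv = 0.1, seed = 7)
  b <- simulateGradient(pop, grid, noiseCv = 0.1, seed = 7)
  c <- simulateGradient(pop, grid, noiseCv = 0.1, seed = 8)
  expect_identical(fractions(a)$copies, fractions(b)$copies)
  expect_false(identical(fractions(a)$copies, fractions(c)$copies))
})

test_that("tracer forward model inverts exactly through the rate estimator", {
  # null rate: nothing changes
  inc0 <- simulateTracer(trueRate = 0, deltaNoiseSd = 0, seed = 1)
  expect_equal(inc0@deltaT, inc0@delta0, tolerance = 1e-12)
  expect_equal(inc0@pocT, inc0@poc0)
  # the worked rate round-trips to better than 6 significant digits
  inc <- simulateTracer(trueRate = 0.022875, poc0 = 10, delta0 = -25, t = 1,
                        caDic = 2000, csDic = 3000, deltaNoiseSd = 0, seed = 1)
  est <- dicAssimilationRate(inc)$rate
  expect_equal(est, 0.022875, tolerance = 1e-7)
  # property: exact recovery over a random grid of specs at zero noise
  withr::with_seed(42, {
    for (i in 1:50) {
      spec <- list(rate = 10^runif(1, -2, 0.4), poc0 = runif(1, 2, 50),
                   delta0 = runif(1, -35, -10), t = runif(1, 0.5, 3),
                   ca = runif(1, 500, 4500), cs = runif(1, 1000, 5000))
      inc <- simulateTracer(spec$rate, spec$poc0, spec$delta0, spec$t,
                            spec$ca, spec$cs, deltaNoiseSd = 0, seed = i)
      expect_equal(dicAssimilationRate(inc)$rate, spec$rate,
                   tolerance = 1e-9)
    }
  })
  # the final atom fraction is a mixture of n0 and the labeled-pool fraction,
  # so it stays below 1 even for extreme rates
  extreme <- simulateTracer(1e6, poc0 = 1, t = 1, caDic = 10, csDic = 1e9,
                            deltaNoiseSd = 0, seed = 1)
  expect_lt(ratioToAtomFraction(deltaToRatio(extreme@deltaT)), 1)
  expect_error(simulateTracer(-1), "trueRate")
})

test_that("planted KO classes are recovered", {
  cfg <- runConfig()
  # noiseless: all-core and enriched-only tables recover exactly
  core <- classifyKO(simulateKOTable(nCore = 10, fold = 4, noiseCv = 0,
                                     seed = 1), cfg)
  expect_true(all(koCategories(core) == "core"))
  enr <- classifyKO(simulateKOTable(nCore = 0, nEnriched = c(5, 0, 0),
                                    fold = 4, noiseCv = 0, seed = 1), cfg)
  expect_true(all(koCategories(enr) == "enriched_lib1"))
  # fold at or below the threshold is rejected by construction
  expect_error(simulateKOTable(nCore = 5, fold = 2, seed = 1), "foldThreshold")
  # Monte-Carlo: >= 95% recovery at cv 0.05, fold 8, 1000 KOs
  kset <- simulateKOTable(nCore = 400, nEnriched = c(100, 100, 100),
                          nDiluted = c(100, 100, 100), fold = 8,
                          noiseCv = 0.05, seed = 99)
  kset <- classifyKO(kset, cfg)
  truth <- SummarizedExperiment::rowData(kset)$trueClass
  expect_gte(mean(as.character(koCategories(kset)) == truth), 0.95)
})

test_that("fraction-taxa tables are closed per fraction and deterministic", {
  sim <- simulateFractionTaxa(labeledTaxa = c("A", "B"),
                              unlabeledTaxa = "C", seed = 3, noiseCv = 0.1)
  expect_equal(sum(sim$rel_abundance_L), 1, tolerance = 1e-12)
  expect_equal(sum(sim$rel_abundance_H), 1, tolerance = 1e-12)
  expect_equal(sum(sim$rel_abundance_UH), 1, tolerance = 1e-12)
  sim2 <- simulateFractionTaxa(labeledTaxa = c("A", "B"),
                               unlabeledTaxa = "C", seed = 3, noiseCv = 0.1)
  expect_identical(sim, sim2)
  expect_error(simulateFractionTaxa(character()), "at least one taxon")
  # labeled taxa rise toward heavy fractions, unlabeled decline twofold or more
  noiseless <- simulateFractionTaxa(labeledTaxa = "A", unlabeledTaxa = "B",
                                    seed = 1, noiseCv = 0)
  lab <- noiseless[noiseless$true_state == "labeled", ]
  unl <- noiseless[noiseless$true_state == "unlabeled", ]
  expect_gte(lab$rel_abundance_H, lab$rel_abundance_L)
  expect_gte(lab$rel_abundance_UH, lab$rel_abundance_L)
  expect_lte(unl$rel_abundance_H, unl$rel_abundance_L / 2)
})
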