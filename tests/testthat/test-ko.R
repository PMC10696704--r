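test_that("the twofold rule classifies the canonical triples", {
  cfg <- runConfig()
  cls <- function(a) as.character(koCategories(
    classifyKO(koAbundanceSet(matrix(a, nrow = 1)), cfg)))
  expect_equal(cls(c(100, 100, 100)), "core")
  expect_equal(cls(c(400, 100, 100)), "enriched_lib1")
  expect_equal(cls(c(100, 200, 300)), "diluted_lib1")
  # boundary: exactly twofold is enriched, not core
  expect_equal(cls(c(200, 100, 100)), "enriched_lib1")
  # a KO present in exactly one library is enriched there
  expect_equal(cls(c(0, 0, 50)), "enriched_lib3")
  # present in two, absent in one: diluted where absent
  expect_equal(cls(c(50, 50, 0)), "diluted_lib3")
  # the three rules do not cover all triples
  expect_equal(cls(c(1, 1.5, 2.5)), "unclassified")
  # enriched takes precedence when both rules could fire
  expect_equal(cls(c(1, 3, 9)), "enriched_lib3")
  expect_error(classifyKO(koAbundanceSet(matrix(0, 1, 3)), cfg), "all-zero")
})

test_that("classification is scale-invariant and permutation-equivariant", {
  cfg <- runConfig()
  set.seed(9)
  m <- matrix(rlnorm(300 * 3, sdlog = 1.5), ncol = 3)
  m[sample(length(m), 30)] <- 0
  m <- m[rowSums(m) > 0, ]
  cats <- koCategories(classifyKO(koAbundanceSet(m), cfg))
  scaled <- koCategories(classifyKO(koAbundanceSet(m * 17.3), cfg))
  expect_equal(as.character(cats), as.character(scaled))
  # per-row positive scaling also preserves the category
  rowScaled <- koCategories(classifyKO(
    koAbundanceSet(m * runif(nrow(m), 0.1, 10)), cfg))
  expect_equal(as.character(cats), as.character(rowScaled))
  perm <- c(2, 3, 1)  # new column j is old column perm[j]
  permCats <- koCategories(classifyKO(
    koAbundanceSet(m[, perm], libNames = paste0("lib", 1:3)), cfg))
  relabel <- vapply(as.character(cats), function(cc) {
    if (!grepl("_lib", cc)) return(cc)
    i <- as.integer(sub(".*_lib", "", cc))
    paste0(sub("_lib.*", "", cc), "_lib", match(i, perm))
  }, "", USE.NAMES = FALSE)
  expect_equal(as.character(permCats), relabel)
})

test_that("ternary coordinates are barycentric", {
  expect_equal(unname(ternaryCoordinates(matrix(c(1, 1, 1), 1))[1, ]),
               rep(1 / 3, 3))
  expect_equal(unname(ternaryCoordinates(matrix(c(1, 0, 0), 1))[1, ]),
               c(1, 0, 0))
  set.seed(2)
  b <- ternaryCoordinates(matrix(rlnorm(60), ncol = 3))
  expect_equal(unname(rowSums(b)), rep(1, 20), tolerance = 1e-12)
  expect_error(ternaryCoordinates(matrix(0, 1, 3)), "positive")
})

test_that("category summaries partition KOs and conserve abundance", {
  cfg <- runConfig()
  kset <- classifyKO(simulateKOTable(nCore = 30, nEnriched = c(5, 4, 3),
                                     nDiluted = c(2, 2, 2), fold = 4,
                                     noiseCv = 0.05, seed = 13), cfg)
  summ <- summarizeCategories(kset)
  expect_equal(sum(summ$n_ko), nrow(kset))
  for (lib in colnames(koAbundance(kset))) {
    expect_equal(sum(summ[[paste0("share_", lib)]]), 1, tolerance = 1e-9)
    expect_equal(sum(summ[[paste0("abundance_", lib)]]),
                 sum(koAbundance(kset)[, lib]), tolerance = 1e-9)
  }
  # degenerate: all core
  allCore <- classifyKO(koAbundanceSet(matrix(100, 10, 3)), cfg)
  s <- summarizeCategories(allCore)
  expect_equal(s$category, "core")
  expect_equal(s$n_ko, 10L)
  expect_equal(s$share_lib1, 1)
})

test_that("the high-abundance filter uses a strict per-million floor", {
  m <- rbind(a = c(999, 10, 10), b = c(1000, 10, 10), c = c(1001, 10, 10))
  kset <- koAbundanceSet(m)
  kept <- rownames(filterHighAbundance(kset, floor = 1000))
  expect_equal(kept, "c")
  expect_equal(nrow(filterHighAbundance(kset, floor = 0)), 3)
})
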