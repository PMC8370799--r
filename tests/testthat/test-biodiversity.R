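test_that("richness counts strictly positive entries", {
  expect_identical(richness(c(0, 0, 0)), 0L)
  expect_identical(richness(c(2, 0, 3)), 2L)
  expect_identical(richness(rep(1, 5)), 5L)
  expect_error(richness(c(-1, 2)), "non-negative")
})

test_that("shannon matches closed forms and hand computation", {
  expect_equal(shannon(7), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  ## -(0.5 ln 0.5 + 0.3 ln 0.3 + 0.2 ln 0.2)
  expect_equal(shannon(c(5, 3, 2)), 1.0296530140645, tolerance = 1e-10)
  expect_error(shannon(c(0, 0)), "undefined")
})

test_that("pielou is H / ln(richness), undefined for monocultures", {
  expect_equal(pielou(c(1, 1, 1, 1)), 1)
  expect_equal(pielou(c(5, 3, 2)), 1.0296530140645 / log(3),
               tolerance = 1e-10)
  expect_true(is.na(pielou(10)))
  expect_true(is.na(pielou(c(0, 7, 0))))
})

test_that("shannon/pielou invariances hold on random communities", {
  set.seed(11)
  for (r in 1:30) {
    x <- rpois(sample(3:12, 1), sample(2:8, 1)) + 1
    expect_equal(shannon(sample(x)), shannon(x))
    expect_equal(shannon(3.7 * x), shannon(x))
    expect_lte(shannon(x), log(richness(x)) + 1e-12)
    j <- pielou(x)
    expect_true(j >= 0 && j <= 1 + 1e-12)
    ## oracle equivalence
    expect_equal(shannon(x), oracle_shannon(x), tolerance = 1e-12)
    expect_equal(pielou(x), oracle_pielou(x), tolerance = 1e-12)
  }
})

test_that("trait matrix applies the score-times-abundance rule", {
  cts <- matrix(c(4L, 0L), 1, 2,
                dimnames = list("sp1", c("s1", "s2")))
  se <- SeepExperiment(cts, family = "FamA",
                       sampleData = data.frame(
                         habitat = c("active", "background"),
                         n_cores = 2, core_diameter_m = 0.064,
                         biomass_g = 0.1))
  traits <- data.frame(family = "FamA", trait = c("T1", "T2"),
                       grouping = "g", score = c(5L, 0L))
  m <- buildTraitMatrix(se, traits)
  expect_equal(m["s1", "T1"], 20)       # 4 individuals x score 5
  expect_equal(m["s1", "T2"], 0)
  expect_equal(unname(m["s2", ]), c(0, 0))

  ## two species of one family: abundances add before scoring
  cts2 <- matrix(c(2L, 3L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  se2 <- SeepExperiment(cts2, family = c("FamA", "FamA"),
                        sampleData = data.frame(habitat = "active",
                                                n_cores = 2,
                                                core_diameter_m = 0.064,
                                                biomass_g = 0.1))
  traits2 <- data.frame(family = "FamA", trait = "T1", grouping = "g",
                        score = 1L)
  expect_equal(buildTraitMatrix(se2, traits2)["s1", "T1"], 5)
})

test_that("trait matrix is linear in abundance and errors on unmapped family", {
  se <- random_seep(21)
  fams <- unique(speciesFamilies(se))
  set.seed(22)
  traits <- expand.grid(family = fams, trait = paste0("T", 1:6),
                        stringsAsFactors = FALSE)
  traits$grouping <- "g"
  traits$score <- sample(0:5, nrow(traits), replace = TRUE)

  m <- buildTraitMatrix(se, traits)
  expect_equal(m, oracle_trait_matrix(seepCounts(se),
                                      speciesFamilies(se), traits),
               tolerance = 1e-12)

  ## linearity: doubling counts doubles the matrix
  se2 <- SeepExperiment(2 * seepCounts(se), speciesFamilies(se),
                        as.data.frame(SummarizedExperiment::colData(se)))
  expect_equal(buildTraitMatrix(se2, traits), 2 * m)

  expect_error(buildTraitMatrix(se, traits[traits$family != fams[1], ]),
               fams[1])
})

test_that("trait-level diversity uses the species methodology verbatim", {
  even <- matrix(5, 1, 32, dimnames = list("s1", paste0("T", 1:32)))
  b <- matrixBiodiversity(even)
  expect_equal(b$trait_richness, 32L)
  expect_equal(b$trait_shannon, log(32))
  expect_equal(b$trait_pielou, 1)

  one <- matrix(c(9, rep(0, 31)), 1, 32)
  b1 <- matrixBiodiversity(one)
  expect_equal(b1$trait_shannon, 0)
  expect_true(is.na(b1$trait_pielou))
})

test_that("biodiversityTable stacks species and trait metrics per sample", {
  ds <- generateDataset(simConfig(seed = 3))
  tb <- biodiversityTable(ds$se, ds$traits)
  expect_equal(nrow(tb), 38L)
  expect_named(tb, c("sample", "species_richness", "species_shannon",
                     "species_pielou", "trait_richness", "trait_shannon",
                     "trait_pielou"))
  ## spot-check one sample against the oracles
  x <- seepCounts(ds$se)[, 5]
  expect_equal(tb$species_shannon[5], oracle_shannon(x),
               tolerance = 1e-12)
  expect_equal(tb$species_richness[5], oracle_richness(x))
})
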