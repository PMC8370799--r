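test_that("sampled area follows core geometry", {
  expect_equal(sampledArea(1, 0.064), pi * 0.032^2, tolerance = 1e-12)
  expect_equal(sampledArea(2, 0.064), 2 * pi * 0.032^2,
               tolerance = 1e-12)
  expect_error(sampledArea(2, 0), "> 0")
  expect_error(sampledArea(0, 0.064), "positive integer")
})

test_that("density and standing stock are per-square-metre conversions", {
  a2 <- sampledArea(2, 0.064)
  expect_equal(densityPerM2(0, a2), 0)
  expect_equal(densityPerM2(10, a2), 10 / a2, tolerance = 1e-12)
  expect_equal(round(densityPerM2(10, 6.4340e-3), 1), 1554.2)
  expect_equal(densityPerM2(100, 1), 100)
  expect_equal(biomassPerM2(0.05, 6.4340e-3), 7.771, tolerance = 1e-3)
  expect_error(biomassPerM2(-0.1, a2), ">= 0")
  expect_error(densityPerM2(5, 0), "> 0")
})

test_that("BPc matches the index arithmetic and its loop oracle", {
  p1 <- data.frame(family = "FamA", Mi = 3, Ri = 2)
  expect_equal(bpc(c(FamA = 10), 0.5, p1), 30)   # 0.5 x 10 x 3 x 2

  p2 <- data.frame(family = c("FamA", "FamB"), Mi = c(3, 3),
                   Ri = c(2, 2))
  expect_equal(bpc(c(FamA = 10, FamB = 10), 0.5, p2), 60)  # additivity

  set.seed(31)
  for (r in 1:25) {
    fams <- paste0("F", 1:5)
    params <- random_family_params(fams, seed = 100 + r)
    ab <- stats::setNames(rpois(5, 6), fams)
    mbar <- runif(1, 0.001, 0.1)
    expect_equal(bpc(ab, mbar, params),
                 oracle_bpc(as.list(ab), mbar, params),
                 tolerance = 1e-10)
    expect_equal(bpc(ab, mbar, params, variant = "sqrt"),
                 oracle_bpc(as.list(ab), mbar, params,
                            sqrt_variant = TRUE),
                 tolerance = 1e-10)
  }
  expect_error(bpc(c(FamX = 2), 0.5, p1), "FamX")
})

test_that("BPc scales linearly in mean biomass and any abundance", {
  params <- random_family_params(paste0("F", 1:4), seed = 9)
  ab <- stats::setNames(c(3, 7, 2, 5), params$family)
  base <- bpc(ab, 0.02, params)
  expect_equal(bpc(ab, 0.04, params), 2 * base, tolerance = 1e-12)
  ab2 <- ab
  ab2[2] <- 2 * ab2[2]
  delta <- bpc(ab2, 0.02, params) - base
  expect_equal(delta,
               unname(0.02 * ab[2] * params$Mi[2] * params$Ri[2]),
               tolerance = 1e-10)
})

test_that("calcification index is abundance-weighted score total", {
  p <- data.frame(family = c("FamA", "FamB"), calc_score = c(5, 0))
  expect_equal(calcificationIndex(c(FamA = 10, FamB = 2), p), 50)
  p0 <- data.frame(family = c("FamA", "FamB"), calc_score = c(0, 0))
  expect_equal(calcificationIndex(c(FamA = 10, FamB = 2), p0), 0)
  set.seed(41)
  for (r in 1:25) {
    params <- random_family_params(paste0("F", 1:6), seed = 200 + r)
    ab <- stats::setNames(rpois(6, 5), params$family)
    expect_equal(calcificationIndex(ab, params),
                 oracle_calc(as.list(ab), params), tolerance = 1e-10)
  }
  expect_error(calcificationIndex(c(Nope = 1), p), "Nope")
})

test_that("family parameter fallback averages species-level scores", {
  reg <- data.frame(family = c("FamA", "FamA", "FamB"),
                    species = c("a1", "a2", "b1"),
                    Mi = c(2, 4, 3), Ri = c(1, 3, 2),
                    calc_score = c(0, 2, 5),
                    provenance = "species-scored")
  fa <- familyParamFallback("FamA", reg)
  expect_equal(fa$Mi, 3)          # mean of {2, 4}
  expect_equal(fa$Ri, 2)
  expect_equal(fa$provenance, "species-mean")
  expect_equal(familyParamFallback("FamB", reg)$Mi, 3)
  expect_error(familyParamFallback("FamZ", reg), "FamZ")
  fz <- familyParamFallback("FamZ", reg, policy = "default")
  expect_equal(fz$provenance, "default-policy")

  ## packaged example registry resolves its species-scored families
  pkg <- read.csv(system.file("extdata", "synthetic_family_params.csv",
                              package = "seepBEF"))
  dorv <- familyParamFallback("Dorvilleidae", pkg)
  expect_equal(dorv$Mi, mean(c(3, 3, 2)))
})

test_that("functioningTable proxies respond to abundance doubling while diversity does not", {
  se <- random_seep(55)
  params <- random_family_params(unique(speciesFamilies(se)), seed = 56)
  ft <- functioningTable(se, params)
  expect_true(all(ft$density >= 0 & ft$bpc >= 0 & ft$calcification >= 0))
  expect_equal(ft$density,
               colSums(seepCounts(se)) / sampleArea(se),
               ignore_attr = TRUE)

  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cd$biomass_g <- 2 * cd$biomass_g      # doubled with abundance
  se2 <- SeepExperiment(2 * seepCounts(se), speciesFamilies(se), cd)
  ft2 <- functioningTable(se2, params)
  expect_equal(ft2$density, 2 * ft$density)
  expect_equal(ft2$bpc, 2 * ft$bpc, tolerance = 1e-10)
  expect_equal(ft2$calcification, 2 * ft$calcification)
  ## Shannon is scale-free
  expect_equal(apply(seepCounts(se2), 2, shannon),
               apply(seepCounts(se), 2, shannon))
})
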