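## small helper: a model table with latent-style predictors
gam_data <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  hab <- factor(rep(c("active", "transition", "background"),
                    each = n_per),
                levels = c("active", "transition", "background"))
  n <- length(hab)
  data.frame(habitat = hab, FuncPC1 = rnorm(n), TaxPC1 = rnorm(n),
             TaxPC2 = rnorm(n), OceanPC1 = rnorm(n),
             OceanPC2 = rnorm(n), TerrainPC1 = rnorm(n), TPI = rnorm(n))
}

test_that("an exact linear effect collapses to one effective dof", {
  set.seed(2)
  hab <- factor(rep(c("active", "transition", "background"), each = 25),
                levels = c("active", "transition", "background"))
  dat <- data.frame(habitat = hab, TaxPC1 = rnorm(length(hab)))
  dat$FuncPC1 <- 0.9 * dat$TaxPC1 + rnorm(nrow(dat), 0, 1e-3)
  spec <- gamSpec(biodiversity = "TaxPC1", covariates = character(0))
  fit <- fitBefGam(spec, dat)
  expect_true(all(abs(fit@termTable$edf - 1) < 0.2))
  expect_gte(fit@adjR2, 0.999)
  ## identity link: observed = fitted + residuals
  expect_equal(fitted(fit@model) + residuals(fit@model), dat$FuncPC1,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fit preconditions are enforced", {
  dat <- gam_data(20)
  expect_error(fitBefGam(gamSpec(), dat[dat$habitat != "active", ]),
               "5 observations")
  tiny <- dat[c(1:6, 21:26, 41:46), ]
  expect_error(fitBefGam(gamSpec(k = 8), tiny), "exceeds")
  dat2 <- dat
  dat2$TaxPC1[3] <- NA
  expect_error(fitBefGam(gamSpec(), dat2), "TaxPC1")
  expect_error(fitBefGam(gamSpec(k = 2)), "\\[3, 10\\]")
})

test_that("knot selection respects candidate bounds and degenerate cases", {
  set.seed(3)
  hab <- factor(rep(c("active", "transition", "background"), each = 15),
                levels = c("active", "transition", "background"))
  dat <- data.frame(habitat = hab, TaxPC1 = rnorm(length(hab)))
  dat$FuncPC1 <- dat$TaxPC1 + rnorm(nrow(dat), 0, 0.5)
  spec <- gamSpec(biodiversity = "TaxPC1", covariates = character(0))
  one <- selectKnots(spec, dat, kCandidates = 4L)
  expect_equal(one$k, 4L)
  expect_error(selectKnots(spec, dat, kCandidates = 2:3), "\\[3, 10\\]")
  ## candidates above the per-habitat n are excluded
  tiny <- dat[c(1:6, 16:21, 31:36), ]
  expect_error(selectKnots(spec, tiny, kCandidates = 8:10),
               "exceed")
  ## near-linear truth: smallest k wins or the fit stays ~linear
  sel <- selectKnots(spec, dat, kCandidates = 4:6)
  edf <- sel$fit@termTable$edf
  expect_true(sel$k == 4L || all(edf < 2))
})

test_that("family selection prefers gaussian on gaussian data and handles edges", {
  dat <- gam_data(20, seed = 4)
  dat$FuncPC1 <- 0.8 * dat$TaxPC1 + rnorm(nrow(dat), 0, 0.4)
  spec <- gamSpec(biodiversity = "TaxPC1", covariates = character(0))
  sel <- selectFamilyLink(spec, dat)
  expect_equal(sel$family$family, "gaussian")
  expect_s4_class(sel$fit, "BefGamFit")
  ## single candidate is returned unconditionally
  only <- selectFamilyLink(spec, dat,
                           candidates = list(stats::gaussian()))
  expect_equal(only$family$family, "gaussian")
  expect_error(selectFamilyLink(spec, dat, candidates = list()),
               "at least one")
})

test_that("backward selection keeps strong terms and is replayable", {
  dat <- gam_data(25, seed = 5)
  dat$FuncPC1 <- 1.5 * dat$TaxPC1 - 1.2 * dat$OceanPC1 +
    rnorm(nrow(dat), 0, 0.3)
  spec <- gamSpec(biodiversity = "TaxPC1", covariates = "OceanPC1")
  full <- fitBefGam(spec, dat)
  red <- backwardSelect(full, dat)
  labs <- vapply(red@spec$terms, `[[`, character(1), "label")
  expect_true(all(c("s(TaxPC1):habitat", "s(OceanPC1)") %in% labs))
  expect_lte(red@aic, full@aic + 2)
  red2 <- backwardSelect(full, dat)
  expect_equal(vapply(red2@spec$terms, `[[`, character(1), "label"),
               labs)
  expect_equal(red2@aic, red@aic)
})

test_that("backward selection falls back to the factor model when nothing holds", {
  dat <- gam_data(15, seed = 6)     # pure noise response
  spec <- gamSpec(biodiversity = "TaxPC1", covariates = character(0))
  full <- fitBefGam(spec, dat)
  ## not every noise draw triggers full removal; only assert the
  ## warning pathway when it does occur
  red <- withCallingHandlers(
    backwardSelect(full, dat),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_s4_class(red, "BefGamFit")
  expect_lte(length(red@spec$terms), length(full@spec$terms))
})

test_that("smooth evaluation exposes fit, derivative and intervals", {
  dat <- gam_data(30, seed = 7)
  dat$FuncPC1 <- dat$TaxPC1 + rnorm(nrow(dat), 0, 0.2)
  spec <- gamSpec(biodiversity = "TaxPC1", covariates = character(0))
  fit <- fitBefGam(spec, dat)
  ev <- evaluateSmooth(fit, "TaxPC1", "active", gridSize = 50L)
  expect_named(ev, c("x", "fit", "se", "deriv", "deriv_se"))
  expect_equal(nrow(ev), 50L)
  ## linear truth: derivative ~ constant 1
  expect_lt(max(abs(ev$deriv - 1)), 0.5)
  expect_error(evaluateSmooth(fit, "TaxPC1", "active", gridSize = 5L),
               "at least 10")
  expect_error(evaluateSmooth(fit, "Nope"), "no smooth term")
})

test_that("shape classification recovers canonical forms", {
  set.seed(8)
  hab <- factor(rep(c("active", "transition", "background"), each = 50),
                levels = c("active", "transition", "background"))
  n <- length(hab)
  x <- rnorm(n)
  dat <- data.frame(habitat = hab, TaxPC1 = x)
  spec <- gamSpec(response = "y", biodiversity = "TaxPC1",
                  covariates = character(0))

  ## monotone increasing
  dat$y <- 1.2 * x + rnorm(n, 0, 0.4)
  up <- classifyShape(fitBefGam(spec, dat), "TaxPC1", "active")
  expect_equal(up$label, "monotone_increasing")

  ## unimodal with peak at 0.2
  dat$y <- -(x - 0.2)^2 + rnorm(n, 0, 0.4)
  uni <- classifyShape(fitBefGam(spec, dat), "TaxPC1", "active")
  expect_equal(uni$label, "unimodal")
  expect_lt(abs(uni$extremum - 0.2), 0.15)

  ## null: pure noise rarely misleads; assert only the dropped case
  dropped <- classifyShape(fitBefGam(spec, dat), "Absent", "active")
  expect_equal(dropped$label, "null")
  expect_error(classifyShape(fitBefGam(spec, dat), "TaxPC1", "active",
                             gridSize = 5L), "at least 10")
})
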