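#' Configuration for the synthetic seep-gradient community generator
#'
#' Defines the sampling design and the ground-truth biodiversity-
#' functioning (BEF) relationship imposed per habitat. Defaults mirror a
#' two-cruise push-core survey across a methane-seep activity gradient:
#' 13 active, 13 transition and 12 background samples, each pooling two
#' cores of 6.4 cm internal diameter, with higher faunal density and
#' dominance (and a calcifier-rich specialist pool) at active seeps.
#'
#' @param nActive,nTransition,nBackground sample counts per habitat.
#' @param speciesPoolSize,nFamilies size of the regional species pool and
#'   the number of families it spans.
#' @param habitatDensityMultipliers named positive multipliers of
#'   `meanBackgroundCount` giving the expected individuals per sample.
#' @param dominance named per-habitat Dirichlet concentration; smaller
#'   values give stronger dominance (lower evenness), as at active seeps.
#' @param befForm named per-habitat relationship form, each one of
#'   `"null"`, `"linear"`, `"unimodal"`, `"accelerating"`, `"saturating"`.
#' @param befEffectSize ratio of the BEF signal standard deviation to the
#'   noise standard deviation.
#' @param noiseSd standard deviation of the Gaussian noise on latent
#'   functioning.
#' @param unimodalPeak location of the unimodal peak on the latent
#'   biodiversity axis (standard deviations from the habitat mean).
#' @param meanBackgroundCount expected individuals per background sample.
#' @param specialistFraction fraction of the pool occurring only in
#'   active/transition habitat (seep specialists).
#' @param coresPerSample,coreDiameterM core pooling and geometry.
#' @param seed single integer; every sub-generator derives its own stream
#'   from it.
#' @return validated config list (class `"SimConfig"`).
#' @export
simConfig <- function(nActive = 13L, nTransition = 13L,
                      nBackground = 12L,
                      speciesPoolSize = 60L, nFamilies = 20L,
                      habitatDensityMultipliers = c(active = 5,
                                                    transition = 2.5,
                                                    background = 1),
                      dominance = c(active = 0.6, transition = 1.5,
                                    background = 3),
                      befForm = c(active = "unimodal",
                                  transition = "null",
                                  background = "null"),
                      befEffectSize = 2, noiseSd = 1,
                      unimodalPeak = 0,
                      meanBackgroundCount = 150,
                      specialistFraction = 0.3,
                      coresPerSample = 2L, coreDiameterM = 0.064,
                      seed = 1L) {
  cfg <- list(nActive = nActive, nTransition = nTransition,
              nBackground = nBackground,
              speciesPoolSize = speciesPoolSize, nFamilies = nFamilies,
              habitatDensityMultipliers = habitatDensityMultipliers,
              dominance = dominance, befForm = befForm,
              befEffectSize = befEffectSize, noiseSd = noiseSd,
              unimodalPeak = unimodalPeak,
              meanBackgroundCount = meanBackgroundCount,
              specialistFraction = specialistFraction,
              coresPerSample = coresPerSample,
              coreDiameterM = coreDiameterM, seed = seed)
  for (f in c("nActive", "nTransition", "nBackground",
              "speciesPoolSize", "nFamilies", "coresPerSample")) {
    .assert(.is_count(cfg[[f]]), "%s must be a positive integer", f)
  }
  .assert(cfg$speciesPoolSize >= cfg$nFamilies,
          "species pool (%d) cannot be smaller than the family count (%d)",
          cfg$speciesPoolSize, cfg$nFamilies)
  for (nm in .HABITATS) {
    .assert(nm %in% names(cfg$habitatDensityMultipliers) &&
              cfg$habitatDensityMultipliers[[nm]] > 0,
            "habitatDensityMultipliers must name positive '%s'", nm)
    .assert(nm %in% names(cfg$dominance) && cfg$dominance[[nm]] > 0,
            "dominance must name positive '%s'", nm)
    .assert(cfg$befForm[[nm]] %in% .BEF_FORMS,
            "befForm['%s'] must be one of: %s", nm,
            paste(.BEF_FORMS, collapse = ", "))
  }
  .assert(cfg$noiseSd > 0, "noiseSd must be > 0")
  .assert(cfg$befEffectSize >= 0, "befEffectSize must be >= 0")
  .assert(cfg$coreDiameterM > 0, "coreDiameterM must be > 0")
  structure(cfg, class = "SimConfig")
}

.BEF_FORMS <- c("null", "linear", "unimodal", "accelerating",
                "saturating")

## raw generating function per form, on the standardized latent
## biodiversity axis d
.befFunction <- function(form, peak = 0) {
  switch(form,
         null = function(d) rep(0, length(d)),
         linear = function(d) d,
         unimodal = function(d) -(d - peak)^2,
         accelerating = function(d) exp(d),
         saturating = function(d) {
           u <- pmax(d + 3, 0)
           u / (1 + u)
         })
}

#' Generate a synthetic seep-gradient dataset
#'
#' Draws a full synthetic survey with known ground truth. Within each
#' habitat: a latent biodiversity value per sample modulates the evenness
#' of a Dirichlet-multinomial community (habitat-specific species pools;
#' seep specialists absent from background habitat); latent functioning is
#' the configured deterministic function of latent biodiversity, scaled so
#' its standard deviation is `befEffectSize * noiseSd`, plus Gaussian
#' noise; realized total abundance is Poisson around the habitat mean
#' count, modulated multiplicatively (mean-preserving) by standardized
#' realized functioning so that density, standing stock, BPc and
#' calcification all track the latent functioning axis. Per-individual
#' wet biomass is lognormal per family. Environmental fields and the
#' bathymetry grid are generated independently of the community (they are
#' null covariates by construction).
#'
#' @param config a [simConfig()].
#' @return list with elements `se` (a [SeepExperiment-class]),
#'   `familyParams`, `traits`, `envPoints`, `nppMonthly` data.frames,
#'   `bathymetry` (a [DepthGrid-class]) and `truth` (class
#'   `"SyntheticTruth"`: per-habitat form labels and coefficients, and the
#'   per-sample latent table with the pre-noise signal).
#' @export
generateDataset <- function(config = simConfig()) {
  .assert(inherits(config, "SimConfig"), "config must come from simConfig()")
  S <- config$speciesPoolSize
  nF <- config$nFamilies
  seed <- config$seed

  species <- sprintf("sp%03d", seq_len(S))
  families <- sprintf("Fam%02d", seq_len(nF))
  spFamily <- families[rep_len(seq_len(nF), S)]

  nSpec <- round(config$specialistFraction * S)
  isSpecialist <- seq_len(S) <= nSpec

  ## per-species base weights of the regional pool
  w <- withStream(seed, "pool", rlnorm(S, 0, 1))
  poolMask <- list(active = rep(TRUE, S), transition = rep(TRUE, S),
                   background = !isSpecialist)

  ## family-level biology: mobility/reworking 1-4, lognormal body size,
  ## calcifier-skewed specialists
  famBio <- withStream(seed, "family_bio", {
    specFams <- unique(spFamily[isSpecialist])
    calc <- ifelse(families %in% specFams,
                   sample(2:5, nF, replace = TRUE),
                   sample(0:3, nF, replace = TRUE))
    data.frame(family = families,
               Mi = sample(1:4, nF, replace = TRUE),
               Ri = sample(1:4, nF, replace = TRUE),
               calc_score = calc,
               meanlog_biomass = rnorm(nF, log(0.004), 0.5),
               provenance = "synthetic-registry")
  })

  traits <- withStream(seed, "traits", .syntheticTraitScores(families))

  habitats <- rep(.HABITATS,
                  c(config$nActive, config$nTransition,
                    config$nBackground))
  n <- length(habitats)
  sampleIds <- sprintf("s%03d", seq_len(n))

  ## latent biodiversity and functioning
  d <- withStream(seed, "latent_biodiversity", rnorm(n))
  signal <- numeric(n)
  coefs <- list()
  for (h in .HABITATS) {
    idx <- habitats == h
    form <- config$befForm[[h]]
    g <- .befFunction(form, config$unimodalPeak)
    raw <- g(d[idx])
    sdr <- stats::sd(raw)
    scale <- if (form == "null" || !is.finite(sdr) || sdr == 0) 0 else
      config$befEffectSize * config$noiseSd / sdr
    signal[idx] <- scale * (raw - mean(raw))
    coefs[[h]] <- list(form = form, scale = scale,
                       peak = if (form == "unimodal")
                         config$unimodalPeak else NA_real_)
  }
  eps <- withStream(seed, "noise", rnorm(n, 0, config$noiseSd))
  f <- signal + eps
  zf <- f / (config$noiseSd * sqrt(1 + config$befEffectSize^2))

  ## communities: evenness follows latent biodiversity; abundance follows
  ## habitat multiplier modulated (mean-preservingly) by functioning
  cgain <- 0.35
  counts <- withStream(seed, "community", {
    m <- matrix(0L, S, n, dimnames = list(species, sampleIds))
    for (i in seq_len(n)) {
      h <- habitats[i]
      mask <- which(poolMask[[h]])
      Sm <- length(mask)
      ## latent biodiversity controls how much of the habitat pool a
      ## sample draws on (richness) and the Dirichlet concentration
      ## (evenness); total abundance tracks latent functioning instead,
      ## so realized diversity does not ride on sampling effort
      nAvail <- max(5L, min(Sm, round(Sm * stats::plogis(0.7 +
                                                          0.8 * d[i]))))
      avail <- sample(mask, nAvail, prob = w[mask])
      alpha <- config$dominance[[h]] * exp(0.6 * d[i])
      p <- rgamma(nAvail, shape = alpha * w[avail] / mean(w[avail]))
      if (sum(p) == 0) p[] <- 1
      lambda <- config$meanBackgroundCount *
        config$habitatDensityMultipliers[[h]] *
        exp(cgain * zf[i] - cgain^2 / 2)
      N <- rpois(1L, lambda)
      if (N > 0) {
        m[avail, i] <- as.integer(rmultinom(1L, N, p / sum(p)))
      }
    }
    m
  })

  biomass <- withStream(seed, "biomass", {
    vapply(seq_len(n), function(i) {
      tot <- 0
      for (k in which(counts[, i] > 0)) {
        ml <- famBio$meanlog_biomass[match(spFamily[k], famBio$family)]
        tot <- tot + sum(rlnorm(counts[k, i], ml, 0.3))
      }
      tot
    }, numeric(1))
  })

  bathy <- generateBathymetry(nx = 40L, ny = 40L, cellSizeM = 25,
                              roughness = 8,
                              seed = streamSeed(seed, "bathymetry"))
  ## place habitats along the seep-to-background x gradient
  coords <- withStream(seed, "coords", {
    ext <- dim(gridValues(bathy)) * cellSize(bathy)
    xc <- c(active = 0.2, transition = 0.5, background = 0.8)[habitats]
    data.frame(x = pmin(pmax(xc * ext[2] + rnorm(n, 0, ext[2] / 12),
                             cellSize(bathy) / 2), ext[2] - 1e-6),
               y = runif(n, 0, ext[1] - 1e-6))
  })

  envPoints <- withStream(seed, "env_points", {
    ext <- dim(gridValues(bathy)) * cellSize(bathy)
    pts <- data.frame(x = runif(30, 0, ext[2]), y = runif(30, 0, ext[1]))
    rbind(
      data.frame(pts, variable = "temperature",
                 value = 5 - 0.002 * pts$x + rnorm(30, 0, 0.1),
                 source = "auv"),
      data.frame(pts, variable = "salinity",
                 value = 34.6 + 0.0002 * pts$y + rnorm(30, 0, 0.01),
                 source = "auv"),
      data.frame(pts, variable = "oxygen",
                 value = pmax(30 + 0.01 * pts$x + rnorm(30, 0, 2), 1),
                 source = "ctd"))
  })

  nppMonthly <- withStream(seed, "npp", {
    data.frame(month = sprintf("2020-%02d", 1:12),
               npp = rlnorm(12, log(400), 0.3))
  })

  sampleData <- data.frame(
    habitat = habitats, n_cores = config$coresPerSample,
    core_diameter_m = config$coreDiameterM, biomass_g = biomass,
    x = coords$x, y = coords$y, row.names = sampleIds)
  se <- SeepExperiment(counts, family = spFamily,
                       sampleData = sampleData)

  truth <- structure(list(
    forms = config$befForm, coefficients = coefs,
    latent = data.frame(sample = sampleIds, habitat = habitats,
                        latentBiodiversity = d, signal = signal,
                        latentFunctioning = f)),
    class = "SyntheticTruth")

  list(se = se,
       familyParams = famBio[c("family", "Mi", "Ri", "calc_score",
                               "provenance")],
       traits = traits, envPoints = envPoints, nppMonthly = nppMonthly,
       bathymetry = bathy, truth = truth)
}

## score every family on the packaged synthetic 32-trait set; fuzzy-coded
## trait tables are sparse, so per grouping a family expresses one trait
## strongly, sometimes a second weakly, and scores 0 elsewhere
.syntheticTraitScores <- function(families) {
  defs <- read.csv(system.file("extdata", "synthetic_traits.csv",
                               package = "seepBEF"))
  do.call(rbind, lapply(families, function(f) {
    score <- integer(nrow(defs))
    for (g in unique(defs$grouping)) {
      idx <- which(defs$grouping == g)
      main <- sample(idx, 1L)
      score[main] <- sample(3:5, 1L)
      if (length(idx) > 1L && runif(1) < 0.4) {
        score[sample(setdiff(idx, main), 1L)] <- sample(1:2, 1L)
      }
    }
    data.frame(family = f, trait = defs$trait, grouping = defs$grouping,
               score = score)
  }))
}

#' Generate a synthetic bathymetry grid
#'
#' A fractal-ish depth surface: a regional slope plus smoothed Gaussian
#' relief, both scaled by `roughness` (`roughness = 0` gives a constant
#' depth).
#'
#' @param nx,ny grid dimensions (>= 3).
#' @param cellSizeM cell size in metres.
#' @param roughness vertical relief scale (m).
#' @param seed integer seed.
#' @param meanDepth mean water depth (m, positive down).
#' @return a [DepthGrid-class].
#' @export
generateBathymetry <- function(nx, ny, cellSizeM = 1, roughness = 5,
                               seed = 1L, meanDepth = 1000) {
  .assert(nx >= 3 && ny >= 3, "grid must be at least 3x3")
  .assert(roughness >= 0, "roughness must be >= 0")
  withStream(seed, "bathy", {
    z <- matrix(rnorm(ny * nx), ny, nx)
    for (pass in 1:3) {       # separable 3-point smoothing
      z <- (rbind(z[1, ], z[-ny, ]) + z + rbind(z[-1, ], z[ny, ])) / 3
      z <- (cbind(z[, 1], z[, -nx]) + z + cbind(z[, -1], z[, nx])) / 3
    }
    tilt <- outer(rep(1, ny), seq_len(nx) / nx)
    depth <- meanDepth + roughness * (z / max(stats::sd(z), 1e-12) +
                                        2 * tilt)
    DepthGrid(depth, cellSize = cellSizeM)
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits the CSV/ASCII-grid schemas the pipeline reads: `abundance.csv`
#' (long: sample, species, count), `families.csv`, `traits.csv`,
#' `family_params.csv`, `samples.csv`, `env_points.csv`,
#' `npp_monthly.csv`, `bathymetry.asc` and `truth.json`.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  se <- dataset$se
  cts <- seepCounts(se)
  long <- data.frame(
    sample = rep(colnames(cts), each = nrow(cts)),
    species = rep(rownames(cts), times = ncol(cts)),
    count = as.integer(cts))
  long <- long[long$count > 0, ]
  w <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  w(long, "abundance.csv")
  w(data.frame(species = rownames(cts), family = speciesFamilies(se)),
    "families.csv")
  w(dataset$traits, "traits.csv")
  w(dataset$familyParams, "family_params.csv")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  w(cbind(sample = rownames(cd), cd), "samples.csv")
  w(dataset$envPoints, "env_points.csv")
  w(dataset$nppMonthly, "npp_monthly.csv")
  writeAsciiGrid(dataset$bathymetry, file.path(dir, "bathymetry.asc"))
  tr <- dataset$truth
  jsonlite::write_json(
    list(forms = as.list(tr$forms),
         coefficients = tr$coefficients,
         latent = tr$latent),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
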