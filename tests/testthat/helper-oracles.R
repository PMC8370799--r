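## Independent straight-loop oracles, deliberately naive: every formula
## is spelled out element by element, never vectorised the way the
## implementation is.

oracle_richness <- function(x) {
  n <- 0L
  for (v in x) if (v > 0) n <- n + 1L
  n
}

oracle_shannon <- function(x) {
  tot <- sum(x)
  h <- 0
  for (v in x) {
    if (v > 0) {
      p <- v / tot
      h <- h - p * log(p)
    }
  }
  h
}

oracle_pielou <- function(x) {
  s <- oracle_richness(x)
  if (s < 2) return(NA_real_)
  oracle_shannon(x) / log(s)
}

oracle_trait_matrix <- function(counts, spFamily, traits) {
  trait_ids <- unique(traits$trait)
  out <- matrix(0, ncol(counts), length(trait_ids),
                dimnames = list(colnames(counts), trait_ids))
  for (j in seq_len(ncol(counts))) {
    for (i in seq_len(nrow(counts))) {
      if (counts[i, j] == 0) next
      fam <- spFamily[i]
      for (tr in trait_ids) {
        sc <- traits$score[traits$family == fam & traits$trait == tr]
        out[j, tr] <- out[j, tr] + sc * counts[i, j]
      }
    }
  }
  out
}

oracle_bpc <- function(famAb, mbar, params, sqrt_variant = FALSE) {
  total <- 0
  for (f in names(famAb)) {
    if (famAb[[f]] <= 0) next
    i <- which(params$family == f)
    b <- if (sqrt_variant) sqrt(mbar) else mbar
    total <- total + b * famAb[[f]] * params$Mi[i] * params$Ri[i]
  }
  total
}

oracle_calc <- function(famAb, params) {
  total <- 0
  for (f in names(famAb)) {
    if (famAb[[f]] <= 0) next
    total <- total + famAb[[f]] *
      params$calc_score[which(params$family == f)]
  }
  total
}

## terrain oracles on interior cells only (no edge policy involved)
oracle_slope_deg <- function(m, cs, i, j) {
  gx <- ((m[i - 1, j + 1] + 2 * m[i, j + 1] + m[i + 1, j + 1]) -
         (m[i - 1, j - 1] + 2 * m[i, j - 1] + m[i + 1, j - 1])) / (8 * cs)
  gy <- ((m[i + 1, j - 1] + 2 * m[i + 1, j] + m[i + 1, j + 1]) -
         (m[i - 1, j - 1] + 2 * m[i - 1, j] + m[i - 1, j + 1])) / (8 * cs)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

oracle_tri <- function(m, i, j) {
  s <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- s + abs(m[i + di, j + dj] - m[i, j])
  }
  s / 8
}

oracle_tpi <- function(m, i, j) {
  s <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- s + m[i + di, j + dj]
  }
  m[i, j] - s / 8
}

## PCA oracle: eigen-decomposition of the sample covariance
oracle_pca_varfrac <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(stats::cov(xc), symmetric = TRUE)$values
  ev / sum(ev)
}

## small random community fixture
random_seep <- function(seed, nSpecies = 8, nFamilies = 3, nSamples = 4) {
  set.seed(seed)
  counts <- matrix(rpois(nSpecies * nSamples, 4), nSpecies, nSamples,
                   dimnames = list(sprintf("sp%02d", 1:nSpecies),
                                   sprintf("s%02d", 1:nSamples)))
  fam <- sprintf("Fam%d", rep_len(1:nFamilies, nSpecies))
  sd <- data.frame(
    habitat = rep_len(c("active", "transition", "background"), nSamples),
    n_cores = 2, core_diameter_m = 0.064,
    biomass_g = runif(nSamples, 0.01, 0.2))
  SeepExperiment(counts, family = fam, sampleData = sd)
}

random_family_params <- function(families, seed) {
  set.seed(seed)
  data.frame(family = families,
             Mi = sample(1:4, length(families), replace = TRUE),
             Ri = sample(1:4, length(families), replace = TRUE),
             calc_score = sample(0:5, length(families), replace = TRUE))
}
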