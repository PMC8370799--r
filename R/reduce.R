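#' Standardize a variable to z-scores
#'
#' Centring to mean 0 and scaling to sample standard deviation 1
#' (denominator n - 1). Missing values are ignored when estimating the
#' mean and sd and are preserved (they are imputed later, see
#' [imputeMissing()]).
#'
#' @param x numeric vector with at least two non-missing values.
#' @param name variable name used in error messages.
#' @return z-scored vector.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  .assert(sum(ok) >= 2L, "'%s' needs at least 2 non-missing values", name)
  s <- stats::sd(x[ok])
  .assert(is.finite(s) && s > 0, "'%s' has zero variance", name)
  (x - mean(x[ok])) / s
}

#' Replace missing values of a standardized table with 0
#'
#' After standardization, 0 is the variable mean; missing entries are set
#' to it. The number of imputations is attached as attribute
#' `"n_imputed"` and reported via message.
#'
#' @param z data.frame or matrix of z-scored variables.
#' @return same shape, no missing values.
#' @export
imputeMissing <- function(z) {
  n <- sum(is.na(as.matrix(z)))
  allMissing <- vapply(as.data.frame(z), function(v) all(is.na(v)),
                       logical(1))
  if (any(allMissing)) {
    warning("fully missing column(s) imputed to 0: ",
            paste(names(allMissing)[allMissing], collapse = ", "))
  }
  z[is.na(z)] <- 0
  if (n > 0) message(n, " missing value(s) imputed to 0")
  attr(z, "n_imputed") <- n
  z
}

#' PCABundle: loadings, scores and variance fractions of one grouping
#'
#' @slot loadings variables x components orthonormal matrix.
#' @slot scores samples x components matrix.
#' @slot varFrac variance fraction of every component (sums to 1).
#' @slot retained number of leading components consumed downstream.
#' @slot flips which components were sign-flipped by [orientAxes()].
#' @exportClass PCABundle
setClass("PCABundle",
         representation(loadings = "matrix", scores = "matrix",
                        varFrac = "numeric", retained = "integer",
                        flips = "logical"))

setValidity("PCABundle", function(object) {
  if (abs(sum(object@varFrac) - 1) > 1e-8)
    return("variance fractions must sum to 1")
  if (any(object@varFrac < -1e-12 | object@varFrac > 1 + 1e-12))
    return("variance fractions must lie in [0, 1]")
  TRUE
})

setMethod("show", "PCABundle", function(object) {
  cat("PCABundle:", nrow(object@loadings), "variables,",
      ncol(object@loadings), "components (", object@retained,
      "retained )\n  variance explained (%):",
      paste(sprintf("%.2f", 100 * object@varFrac), collapse = " "), "\n")
})

#' Principal component analysis of one variable grouping
#'
#' Singular-value decomposition PCA of a standardized samples x variables
#' table. Components are ordered by decreasing variance; scores are the
#' centred data projected on the loadings, so reconstruction with all
#' components is exact.
#'
#' @param x samples x variables numeric table (standardized, no missing
#'   values).
#' @param retain number of leading components consumed downstream.
#' @return a [PCABundle-class].
#' @export
pcaGrouping <- function(x, retain = 2L) {
  x <- as.matrix(x)
  .assert(nrow(x) >= 2L && ncol(x) >= 1L,
          "PCA needs at least 2 samples and 1 variable")
  .assert(!anyNA(x), "PCA input must not contain missing values")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  varFrac <- p$sdev^2 / sum(p$sdev^2)
  new("PCABundle", loadings = p$rotation, scores = p$x,
      varFrac = varFrac, retained = as.integer(min(retain, ncol(p$x))),
      flips = rep(FALSE, ncol(p$x)))
}

#' Fix PCA axis signs deterministically
#'
#' PCA component signs are arbitrary; for reproducible outputs each
#' component is flipped, if necessary, so that its largest-magnitude
#' loading is positive. Scores flip together with loadings, leaving the
#' reconstruction unchanged. Idempotent.
#'
#' @param bundle a [PCABundle-class].
#' @return the oriented [PCABundle-class], flips recorded.
#' @export
orientAxes <- function(bundle) {
  L <- bundle@loadings
  flips <- vapply(seq_len(ncol(L)), function(j) {
    L[which.max(abs(L[, j])), j] < 0
  }, logical(1))
  s <- ifelse(flips, -1, 1)
  new("PCABundle",
      loadings = sweep(L, 2L, s, "*"),
      scores = sweep(bundle@scores, 2L, s, "*"),
      varFrac = bundle@varFrac, retained = bundle@retained,
      flips = flips | bundle@flips)
}

#' Default variable groupings for dimensionality reduction
#'
#' The six groupings reduced ahead of the additive model, with the number
#' of principal components each contributes: functioning (2), taxonomic
#' biodiversity (2), trait biodiversity (2), oceanographic (2), terrain
#' (1); the terrain position index enters unreduced (0).
#'
#' @return named list with `vars` and `retain` per grouping.
#' @export
defaultGroupings <- function() {
  list(
    functioning = list(vars = c("density", "biomass_m2", "bpc",
                                "calcification"), retain = 2L),
    taxonomic_biodiversity = list(
      vars = c("species_richness", "species_shannon", "species_pielou"),
      retain = 2L),
    trait_biodiversity = list(
      vars = c("trait_richness", "trait_shannon", "trait_pielou"),
      retain = 2L),
    oceanographic = list(vars = c("depth", "temperature", "salinity",
                                  "oxygen", "export_flux"), retain = 2L),
    terrain = list(vars = c("slope", "tri"), retain = 1L),
    terrain_position_index = list(vars = "tpi", retain = 0L))
}

#' Reduce the merged per-sample table to model variables
#'
#' Applies the fixed preprocessing order — standardize every continuous
#' variable, impute missing values with 0, PCA per grouping, orient the
#' axes — and assembles the additive-model input table.
#'
#' @param tbl per-sample data.frame containing every variable named in
#'   `groupings` plus `sample` and `habitat`.
#' @param groupings as [defaultGroupings()].
#' @return list with `data` (model table: `FuncPC1`, `FuncPC2`, `TaxPC1`,
#'   `TaxPC2`, `TraitPC1`, `TraitPC2`, `OceanPC1`, `OceanPC2`,
#'   `TerrainPC1`, `TPI`, `habitat`, `sample`) and `bundles` (named list
#'   of [PCABundle-class], `NULL` for unreduced groupings).
#' @export
reduceVariables <- function(tbl, groupings = defaultGroupings()) {
  vars <- unlist(lapply(groupings, `[[`, "vars"), use.names = FALSE)
  miss <- setdiff(vars, names(tbl))
  .assert(length(miss) == 0L, "variables missing from table: %s",
          paste(miss, collapse = ", "))
  z <- tbl
  for (v in vars) {
    s <- stats::sd(tbl[[v]], na.rm = TRUE)
    if (!is.na(s) && s == 0) {
      ## a constant variable carries no information: its z-scores are set
      ## to the (post-standardization) mean, i.e. 0, rather than aborting
      ## the whole run
      warning("'", v, "' is constant; entering as all-zero z-scores")
      z[[v]] <- ifelse(is.na(tbl[[v]]), NA_real_, 0)
    } else {
      z[[v]] <- standardize(tbl[[v]], name = v)
    }
  }
  z[vars] <- imputeMissing(z[vars])

  bundles <- list()
  out <- data.frame(sample = tbl$sample, habitat = tbl$habitat)
  axisName <- c(functioning = "Func", taxonomic_biodiversity = "Tax",
                trait_biodiversity = "Trait", oceanographic = "Ocean",
                terrain = "Terrain")
  for (g in names(groupings)) {
    spec <- groupings[[g]]
    if (spec$retain == 0L) {
      bundles[g] <- list(NULL)
      out$TPI <- z[[spec$vars]]
      next
    }
    b <- orientAxes(pcaGrouping(z[spec$vars], retain = spec$retain))
    bundles[[g]] <- b
    for (k in seq_len(b@retained)) {
      out[[paste0(axisName[[g]], "PC", k)]] <- b@scores[, k]
    }
  }
  list(data = out, bundles = bundles)
}
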