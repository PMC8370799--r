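#' Ecosystem-functioning proxies
#'
#' Four complementary per-sample proxies of benthic ecosystem functioning:
#' faunal density (ind. m^-2), standing stock (g wet m^-2), community
#' bioturbation potential (BPc) and the abundance-weighted calcification
#' degree.
#'
#' @name functioning
NULL

#' @describeIn functioning seafloor area (m^2) represented by `n_cores`
#'   pooled push cores of the given internal diameter:
#'   `n_cores * pi * (d/2)^2`.
#' @param n_cores number of pooled cores per sample.
#' @param internal_diameter_m core internal diameter in metres.
#' @export
sampledArea <- function(n_cores, internal_diameter_m) {
  .assert(.is_count(n_cores), "n_cores must be a positive integer")
  .assert(.is_number(internal_diameter_m) && internal_diameter_m > 0,
          "core diameter must be > 0")
  n_cores * pi * (internal_diameter_m / 2)^2
}

#' @describeIn functioning individuals per square metre.
#' @param total_count total individuals in the sample.
#' @param area_m2 sampled area (m^2).
#' @export
densityPerM2 <- function(total_count, area_m2) {
  .assert(.is_number(area_m2) && area_m2 > 0, "area must be > 0")
  .assert(.is_number(total_count) && total_count >= 0,
          "count must be >= 0")
  total_count / area_m2
}

#' @describeIn functioning wet biomass per square metre (g m^-2).
#' @param total_wet_biomass_g total wet biomass of the sample (g).
#' @export
biomassPerM2 <- function(total_wet_biomass_g, area_m2) {
  .assert(.is_number(area_m2) && area_m2 > 0, "area must be > 0")
  .assert(.is_number(total_wet_biomass_g) && total_wet_biomass_g >= 0,
          "biomass must be >= 0")
  total_wet_biomass_g / area_m2
}

.check_family_params <- function(families, params) {
  miss <- setdiff(families, params$family)
  .assert(length(miss) == 0L,
          "no parameters for family: %s", paste(miss, collapse = ", "))
}

#' Community bioturbation potential (BPc)
#'
#' `BPc = sum_i (B_i / A_i) * A_i * M_i * R_i` over the families present,
#' with `A_i` the family abundance, `M_i` and `R_i` the family mobility
#' and sediment-reworking parameters, and the per-family mean individual
#' biomass `B_i / A_i` replaced by the sample-wide mean individual wet
#' biomass `mean_individual_biomass_g` (family-level biomass is rarely
#' recorded in bulk macrofaunal sorts). The `"sqrt"` variant uses
#' `sqrt(B_i / A_i)`, as in the classical formulation of the
#' bioturbation-potential index; the default `"linear"` variant uses the
#' biomass ratio untransformed.
#'
#' @param family_abundances named non-negative vector of counts per family.
#' @param mean_individual_biomass_g sample mean individual wet biomass (g).
#' @param params data.frame with columns `family`, `Mi`, `Ri`.
#' @param variant `"linear"` (default) or `"sqrt"`.
#' @return BPc index value (>= 0).
#' @examples
#' bpc(c(FamA = 10), 0.5,
#'     data.frame(family = "FamA", Mi = 3, Ri = 2))   # 30
#' @export
bpc <- function(family_abundances, mean_individual_biomass_g, params,
                variant = c("linear", "sqrt")) {
  variant <- match.arg(variant)
  .assert(.is_number(mean_individual_biomass_g) &&
            mean_individual_biomass_g >= 0,
          "mean individual biomass must be >= 0")
  a <- family_abundances[family_abundances > 0]
  if (!length(a)) return(0)
  .check_family_params(names(a), params)
  i <- match(names(a), params$family)
  m <- if (variant == "sqrt") sqrt(mean_individual_biomass_g)
       else mean_individual_biomass_g
  sum(m * a * params$Mi[i] * params$Ri[i])
}

#' Calcification degree of a community
#'
#' Family calcification scores (0-5) multiplied by family abundance and
#' totalled across all families present.
#'
#' @inheritParams bpc
#' @param params data.frame with columns `family`, `calc_score`.
#' @export
calcificationIndex <- function(family_abundances, params) {
  a <- family_abundances[family_abundances > 0]
  if (!length(a)) return(0)
  .check_family_params(names(a), params)
  .assert(all(params$calc_score >= 0 & params$calc_score <= 5),
          "calcification scores must lie in [0, 5]")
  i <- match(names(a), params$family)
  sum(a * params$calc_score[i])
}

#' Resolve family parameters from a registry
#'
#' Looks a family up in a parameter registry (columns `family`, `Mi`,
#' `Ri`, `calc_score`, optionally `species` and `provenance`). When the
#' registry scores several species of the family, their arithmetic mean is
#' returned. Absent families either raise an error (`policy = "error"`) or
#' fall back to a configured default.
#'
#' @param family family name to resolve.
#' @param registry the registry data.frame.
#' @param policy `"error"` or `"default"`.
#' @param default named list with `Mi`, `Ri`, `calc_score` used under
#'   `policy = "default"`.
#' @return one-row data.frame `family, Mi, Ri, calc_score, provenance`.
#' @export
familyParamFallback <- function(family, registry,
                                policy = c("error", "default"),
                                default = list(Mi = 2, Ri = 2,
                                               calc_score = 1)) {
  policy <- match.arg(policy)
  rows <- registry[registry$family == family, , drop = FALSE]
  if (nrow(rows) == 0L) {
    .assert(policy == "default", "no parameters for family: %s", family)
    return(data.frame(family = family, Mi = default$Mi, Ri = default$Ri,
                      calc_score = default$calc_score,
                      provenance = "default-policy"))
  }
  prov <- if (nrow(rows) > 1L) "species-mean" else
    (rows$provenance[1L] %||% "registry")
  data.frame(family = family, Mi = mean(rows$Mi), Ri = mean(rows$Ri),
             calc_score = mean(rows$calc_score), provenance = prov)
}

#' Per-sample functioning table
#'
#' Computes all four proxies for every sample of a survey. The mean
#' individual biomass entering BPc is the sample total wet biomass divided
#' by the sample total count (taken as 0 for empty samples).
#'
#' @param se a [SeepExperiment-class].
#' @param params family parameter table (`family`, `Mi`, `Ri`,
#'   `calc_score`); every family occurring in `se` must be present
#'   (resolve gaps first with [familyParamFallback()]).
#' @param bpc_variant passed to [bpc()].
#' @return data.frame keyed by sample: `density`, `biomass_m2`, `bpc`,
#'   `calcification`, `area_m2`.
#' @export
functioningTable <- function(se, params, bpc_variant = "linear") {
  cts <- seepCounts(se)
  fam <- speciesFamilies(se)
  area <- sampleArea(se)
  cd <- SummarizedExperiment::colData(se)
  famCounts <- rowsum(cts, fam)              # families x samples
  out <- lapply(seq_len(ncol(cts)), function(j) {
    tot <- sum(cts[, j])
    mbar <- if (tot > 0) cd$biomass_g[j] / tot else 0
    fa <- stats::setNames(famCounts[, j], rownames(famCounts))
    data.frame(
      sample = colnames(cts)[j],
      density = densityPerM2(tot, area[j]),
      biomass_m2 = biomassPerM2(cd$biomass_g[j], area[j]),
      bpc = bpc(fa, mbar, params, variant = bpc_variant),
      calcification = calcificationIndex(fa, params),
      area_m2 = area[j])
  })
  out <- do.call(rbind, out)
  rownames(out) <- out$sample
  out
}
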