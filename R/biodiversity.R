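#' Taxonomic and functional-trait biodiversity metrics
#'
#' Richness, Shannon diversity (natural log) and Pielou evenness computed
#' per sample from species abundances, and from the abundance-weighted
#' functional-trait matrix. Shannon and richness are delegated to
#' \pkg{vegan} (`diversity`, `specnumber`); Pielou is `H / ln(richness)`.
#'
#' @param x non-negative abundance vector (one sample).
#' @return `richness()` the number of strictly positive entries;
#'   `shannon()` the Shannon index in nats; `pielou()` evenness in [0, 1],
#'   `NA` for monocultures (richness < 2), where evenness is undefined.
#' @examples
#' shannon(c(5, 3, 2))        # 1.0297
#' pielou(c(5, 3, 2))         # 0.9373
#' richness(c(2, 0, 3))       # 2
#' @name biodiversity-metrics
NULL

#' @rdname biodiversity-metrics
#' @export
richness <- function(x) {
  .assert(is.numeric(x) && all(is.finite(x)) && all(x >= 0),
          "abundances must be finite and non-negative")
  as.integer(vegan::specnumber(x))
}

#' @rdname biodiversity-metrics
#' @export
shannon <- function(x) {
  .assert(is.numeric(x) && all(is.finite(x)) && all(x >= 0),
          "abundances must be finite and non-negative")
  .assert(any(x > 0), "Shannon index is undefined for an all-zero sample")
  unname(vegan::diversity(x, index = "shannon", base = exp(1)))
}

#' @rdname biodiversity-metrics
#' @export
pielou <- function(x) {
  s <- richness(x)
  if (s < 2) return(NA_real_)
  shannon(x) / log(s)
}

#' Build the abundance-weighted functional-trait matrix
#'
#' Each family carries a 0-5 association score for every functional trait.
#' Per sample, the trait "abundance" is the family score multiplied by the
#' abundance of each species of that family, totalled across all species:
#' `T[sample, trait] = sum_species score(family(species), trait) * count`.
#'
#' @param se a [SeepExperiment-class].
#' @param traits data.frame with columns `family`, `trait`, `grouping`,
#'   `score` (integers 0-5; one row per family x trait).
#' @return samples x traits numeric matrix (trait columns ordered as first
#'   encountered in `traits`).
#' @export
buildTraitMatrix <- function(se, traits) {
  .assert(all(c("family", "trait", "score") %in% names(traits)),
          "traits needs columns family, trait, score")
  .assert(all(traits$score >= 0 & traits$score <= 5),
          "trait scores must lie in [0, 5]")
  fam <- speciesFamilies(se)
  missing_fam <- setdiff(unique(fam), unique(traits$family))
  .assert(length(missing_fam) == 0L,
          "families missing from trait table: %s",
          paste(missing_fam, collapse = ", "))
  trait_ids <- unique(traits$trait)
  ## family x trait score matrix
  S <- matrix(0, length(unique(traits$family)), length(trait_ids),
              dimnames = list(unique(traits$family), trait_ids))
  S[cbind(match(traits$family, rownames(S)),
          match(traits$trait, colnames(S)))] <- traits$score
  cts <- seepCounts(se)                      # species x samples
  t(cts) %*% S[fam, , drop = FALSE]          # samples x traits
}

#' Diversity metrics of a trait (or any non-negative) matrix
#'
#' Applies richness/Shannon/Pielou row-wise, treating columns as the
#' "species" of the matrix.
#'
#' @param m samples x categories non-negative matrix.
#' @param prefix name prefix for the output columns.
#' @return data.frame with `<prefix>_richness`, `<prefix>_shannon`,
#'   `<prefix>_pielou`, one row per row of `m`. All-zero rows give
#'   richness 0 and `NA` diversity/evenness.
#' @export
matrixBiodiversity <- function(m, prefix = "trait") {
  m <- as.matrix(m)
  out <- data.frame(
    richness = apply(m, 1L, richness),
    shannon  = apply(m, 1L, function(r) if (any(r > 0)) shannon(r)
                                        else NA_real_),
    pielou   = apply(m, 1L, pielou),
    row.names = rownames(m))
  names(out) <- paste(prefix, names(out), sep = "_")
  out
}

#' Per-sample biodiversity table
#'
#' Species-level and trait-level richness, Shannon and Pielou for every
#' sample of a survey.
#'
#' @inheritParams buildTraitMatrix
#' @return data.frame keyed by sample with six metric columns
#'   (`species_*`, `trait_*`). Monoculture samples carry `NA` evenness;
#'   downstream reduction treats these as missing.
#' @export
biodiversityTable <- function(se, traits) {
  sp <- matrixBiodiversity(t(seepCounts(se)), prefix = "species")
  tr <- matrixBiodiversity(buildTraitMatrix(se, traits), prefix = "trait")
  cbind(sample = colnames(se), sp, tr)
}
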