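#' SeepExperiment: sample x species abundances with family map and metadata
#'
#' `SeepExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' to hold a benthic macrofaunal survey: a `counts` assay of non-negative
#' integer abundances (species in rows, samples in columns), a species-to-
#' family map in `rowData(x)$family`, and per-sample metadata in `colData`
#' (seep activity category, number of pooled cores, core internal diameter,
#' total wet biomass, and planar sampling coordinates).
#'
#' @slot .. no additional slots; all state lives in the inherited assay,
#'   rowData and colData.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass SeepExperiment
setClass("SeepExperiment", contains = "SummarizedExperiment")

.HABITATS <- c("active", "transition", "background")

setValidity("SeepExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != floor(cts))) {
      msg <- c(msg, "counts must be finite non-negative integers")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"family" %in% colnames(rd) || anyNA(rd$family)) {
    msg <- c(msg, "rowData must map every species to a family")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("habitat", "n_cores", "core_diameter_m", "biomass_g")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste("colData is missing:", paste(miss, collapse = ", ")))
  } else {
    if (!all(as.character(cd$habitat) %in% .HABITATS)) {
      msg <- c(msg, paste("habitat must be one of:",
                          paste(.HABITATS, collapse = ", ")))
    }
    if (any(cd$n_cores < 1) || any(cd$core_diameter_m <= 0)) {
      msg <- c(msg, "n_cores must be >= 1 and core_diameter_m > 0")
    }
    if (any(cd$biomass_g < 0)) msg <- c(msg, "biomass_g must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SeepExperiment
#'
#' @param counts species x samples matrix of non-negative integer counts
#'   (species ids as rownames, sample ids as colnames).
#' @param family character vector, one family per species (recycled names
#'   checked against `rownames(counts)` when named).
#' @param sampleData data.frame of per-sample metadata with columns
#'   `habitat` (one of `"active"`, `"transition"`, `"background"`),
#'   `n_cores`, `core_diameter_m`, `biomass_g` and optionally planar
#'   coordinates `x`, `y` and anything else; rows match `colnames(counts)`.
#' @return A [SeepExperiment-class] object.
#' @examples
#' cts <- matrix(c(4L, 0L, 1L, 3L), 2, 2,
#'               dimnames = list(c("sp1", "sp2"), c("s1", "s2")))
#' se <- SeepExperiment(cts, family = c("FamA", "FamA"),
#'   sampleData = data.frame(habitat = c("active", "background"),
#'                           n_cores = 2, core_diameter_m = 0.064,
#'                           biomass_g = c(0.05, 0.02)))
#' speciesFamilies(se)
#' @export
SeepExperiment <- function(counts, family, sampleData) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts needs species rownames and sample colnames")
  .assert(length(family) == nrow(counts),
          "need one family per species (%d != %d)",
          length(family), nrow(counts))
  .assert(nrow(sampleData) == ncol(counts),
          "sampleData must have one row per sample")
  cd <- S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  cd$habitat <- factor(as.character(cd$habitat), levels = .HABITATS)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(family = as.character(family),
                                   row.names = rownames(counts)),
    colData = cd)
  new("SeepExperiment", se)
}

#' @rdname SeepExperiment
#' @param x a `SeepExperiment`.
#' @export
speciesFamilies <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$family),
                  rownames(x))
}

#' @rdname SeepExperiment
#' @export
habitat <- function(x) {
  SummarizedExperiment::colData(x)$habitat
}

#' @rdname SeepExperiment
#' @details `sampleArea()` returns the seafloor area (m^2) represented by
#'   each sample: `n_cores * pi * (diameter / 2)^2`.
#' @export
sampleArea <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(
    mapply(sampledArea, cd$n_cores, cd$core_diameter_m),
    colnames(x))
}

#' @rdname SeepExperiment
#' @export
seepCounts <- function(x) {
  SummarizedExperiment::assay(x, "counts")
}

setMethod("show", "SeepExperiment", function(object) {
  cts <- seepCounts(object)
  cat("SeepExperiment:", nrow(object), "species x", ncol(object),
      "samples\n")
  cat("  families:", length(unique(speciesFamilies(object))), "\n")
  cat("  habitats:", paste(sprintf("%s=%d", levels(habitat(object)),
                                   table(habitat(object))),
                           collapse = " "), "\n")
  cat("  total individuals:", sum(cts), "\n")
})
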