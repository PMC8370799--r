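#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs. Exactly one of `sim`
#' (a [simConfig()], for a synthetic run) or `inputDir` (a directory of
#' CSV/ASCII-grid inputs in the schemas written by [writeDataset()]) must
#' be given.
#'
#' @param sim a [simConfig()] or `NULL`.
#' @param inputDir input directory or `NULL`.
#' @param outputDir where to write outputs (`NULL` for in-memory only).
#' @param responses functioning PC axes modelled as responses.
#' @param flavors biodiversity flavours modelled (axis-name prefixes:
#'   `"Tax"`, `"Trait"`).
#' @param kCandidates,alpha,aicTol model-selection settings (see
#'   [selectKnots()], [backwardSelect()]).
#' @param familyCandidates candidate error families for
#'   [selectFamilyLink()].
#' @param interpolation `"idw"` or `"nearest"` for environmental points.
#' @param nppConvention see [annualNpp()].
#' @param lutz export-flux attenuation parameters, see [exportFlux()].
#' @param bpcVariant see [bpc()].
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(sim = NULL, inputDir = NULL, outputDir = NULL,
                      responses = c("FuncPC1", "FuncPC2"),
                      flavors = c("Tax", "Trait"),
                      kCandidates = 4:6, alpha = 0.05, aicTol = 2,
                      familyCandidates = list(stats::gaussian(),
                                              stats::Gamma(link = "log")),
                      interpolation = c("idw", "nearest"),
                      nppConvention = "totals",
                      lutz = list(prd = 0.1, rld = 800, prr = 0.015),
                      bpcVariant = "linear") {
  .assert(xor(is.null(sim), is.null(inputDir)),
          "give exactly one of sim= or inputDir=")
  structure(list(sim = sim, inputDir = inputDir, outputDir = outputDir,
                 responses = responses, flavors = flavors,
                 kCandidates = kCandidates, alpha = alpha,
                 aicTol = aicTol, familyCandidates = familyCandidates,
                 interpolation = match.arg(interpolation),
                 nppConvention = nppConvention, lutz = lutz,
                 bpcVariant = bpcVariant),
            class = "RunConfig")
}

#' Read a dataset directory
#'
#' Reads the CSV/ASCII-grid schemas written by [writeDataset()] back into
#' the in-memory dataset structure consumed by [analyzeDataset()].
#'
#' @param dir directory path.
#' @return list with `se`, `familyParams`, `traits`, `envPoints`,
#'   `nppMonthly`, `bathymetry` (and `truth = NULL`; ground truth is not
#'   an input).
#' @export
readDataset <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    .assert(file.exists(p), "missing input file: %s", f)
    read.csv(p)
  }
  ab <- rd("abundance.csv")
  fams <- rd("families.csv")
  samples <- rd("samples.csv")
  orphan <- setdiff(unique(ab$species), fams$species)
  .assert(length(orphan) == 0L, "species without family mapping: %s",
          paste(orphan, collapse = ", "))
  cts <- matrix(0L, nrow(fams), nrow(samples),
                dimnames = list(fams$species, samples$sample))
  cts[cbind(match(ab$species, rownames(cts)),
            match(ab$sample, colnames(cts)))] <- ab$count
  sd <- samples[setdiff(names(samples), "sample")]
  rownames(sd) <- samples$sample
  se <- SeepExperiment(cts, family = fams$family, sampleData = sd)
  list(se = se, familyParams = rd("family_params.csv"),
       traits = rd("traits.csv"), envPoints = rd("env_points.csv"),
       nppMonthly = rd("npp_monthly.csv"),
       bathymetry = readAsciiGrid(file.path(dir, "bathymetry.asc")),
       truth = NULL)
}

#' Validate a dataset directory
#'
#' Structural checks on the input schemas: required files, non-negative
#' integer counts, trait and calcification scores within 0-5, a complete
#' species-to-family map, twelve NPP months, and a rectangular readable
#' bathymetry grid.
#'
#' @param dir directory path.
#' @return list with `pass` (logical) and `issues` (data.frame `file`,
#'   `message`).
#' @export
validateInputs <- function(dir) {
  issues <- list()
  note <- function(file, message) {
    issues[[length(issues) + 1L]] <<- data.frame(file = file,
                                                 message = message)
  }
  need <- c("abundance.csv", "families.csv", "traits.csv",
            "family_params.csv", "samples.csv", "env_points.csv",
            "npp_monthly.csv", "bathymetry.asc")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) note(f, "file is missing")
  }
  have <- function(f) file.exists(file.path(dir, f))
  if (have("abundance.csv")) {
    ab <- read.csv(file.path(dir, "abundance.csv"))
    bad <- ab$count < 0 | ab$count != floor(ab$count)
    if (any(bad)) {
      note("abundance.csv",
           paste("non-integer or negative count at row(s):",
                 paste(head(which(bad), 5L), collapse = ", ")))
    }
    if (have("families.csv")) {
      fams <- read.csv(file.path(dir, "families.csv"))
      orphan <- setdiff(unique(ab$species), fams$species)
      if (length(orphan)) {
        note("families.csv", paste("species without family:",
                                   paste(orphan, collapse = ", ")))
      }
    }
  }
  if (have("traits.csv")) {
    tr <- read.csv(file.path(dir, "traits.csv"))
    bad <- tr$score < 0 | tr$score > 5
    if (any(bad)) {
      note("traits.csv", paste("score outside [0,5] for trait(s):",
                               paste(unique(tr$trait[bad]),
                                     collapse = ", ")))
    }
  }
  if (have("family_params.csv")) {
    fp <- read.csv(file.path(dir, "family_params.csv"))
    if (any(fp$calc_score < 0 | fp$calc_score > 5)) {
      note("family_params.csv", "calc_score outside [0,5]")
    }
    if (any(fp$Mi <= 0 | fp$Ri <= 0)) {
      note("family_params.csv", "Mi and Ri must be positive")
    }
  }
  if (have("npp_monthly.csv")) {
    npp <- read.csv(file.path(dir, "npp_monthly.csv"))
    if (nrow(npp) != 12L) {
      note("npp_monthly.csv",
           sprintf("expected 12 monthly rows, found %d", nrow(npp)))
    }
  }
  if (have("bathymetry.asc")) {
    ok <- tryCatch({ readAsciiGrid(file.path(dir, "bathymetry.asc"));
                     TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) note("bathymetry.asc", "not a readable rectangular grid")
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(), message = character())
  list(pass = nrow(issues) == 0L, issues = issues)
}

#' Derive the per-sample environmental table
#'
#' Interpolates point measurements onto the bathymetry geometry, derives
#' slope/TRI/TPI from the depth grid, extracts everything at the sample
#' coordinates, and adds annual NPP and its depth-attenuated export flux.
#'
#' @param dataset dataset list (see [generateDataset()]/[readDataset()]).
#' @param config a [runConfig()].
#' @return data.frame keyed by sample: `depth`, `temperature`,
#'   `salinity`, `oxygen`, `npp_annual`, `export_flux`, `slope`, `tri`,
#'   `tpi`.
#' @export
buildEnvTable <- function(dataset, config) {
  bathy <- dataset$bathymetry
  grids <- list(depth = bathy, slope = terrainSlope(bathy),
                tri = terrainTri(bathy), tpi = terrainTpi(bathy))
  for (v in unique(dataset$envPoints$variable)) {
    pts <- dataset$envPoints[dataset$envPoints$variable == v, ]
    grids[[v]] <- interpolateToGrid(pts, bathy,
                                    method = config$interpolation)
  }
  cd <- SummarizedExperiment::colData(dataset$se)
  coords <- data.frame(sample = colnames(dataset$se),
                       x = cd$x, y = cd$y)
  env <- extractAtSamples(grids, coords)
  env$npp_annual <- annualNpp(dataset$nppMonthly$npp,
                              convention = config$nppConvention)
  env$export_flux <- exportFlux(env$npp_annual, env$depth,
                                params = config$lutz)
  env
}

#' Analyse a dataset in memory
#'
#' The full analysis chain on an in-memory dataset: biodiversity and
#' functioning tables, environmental derivation, standardize/impute/PCA
#' reduction, then per response x biodiversity-flavour: basis-dimension
#' selection, family/link selection, backward stepwise refinement, and
#' shape classification of every per-habitat biodiversity smooth.
#'
#' @param dataset dataset list (see [generateDataset()]/[readDataset()]).
#' @param config a [runConfig()].
#' @return list: `biodiversity`, `functioning`, `env`, `reduced` (from
#'   [reduceVariables()]), `models` (per model: `fit`, `selection`
#'   details), `terms` (stacked term table), `shapes` (stacked shape
#'   calls).
#' @export
analyzeDataset <- function(dataset, config = runConfig(sim = simConfig())) {
  biod <- biodiversityTable(dataset$se, dataset$traits)
  func <- functioningTable(dataset$se, dataset$familyParams,
                           bpc_variant = config$bpcVariant)
  env <- buildEnvTable(dataset, config)
  tbl <- Reduce(function(a, b) merge(a, b, by = "sample"),
                list(func, biod, env))
  tbl$habitat <- habitat(dataset$se)[match(tbl$sample,
                                           colnames(dataset$se))]
  red <- reduceVariables(tbl)

  models <- list()
  termRows <- list()
  shapeRows <- list()
  for (resp in config$responses) {
    for (fl in config$flavors) {
      id <- paste(resp, fl, sep = ".")
      bio <- paste0(fl, c("PC1", "PC2"))
      spec0 <- gamSpec(response = resp, biodiversity = bio)
      ks <- selectKnots(spec0, red$data,
                        kCandidates = config$kCandidates)
      specK <- ks$fit@spec
      famSel <- selectFamilyLink(specK, red$data,
                                 candidates = config$familyCandidates)
      fit <- backwardSelect(famSel$fit, red$data,
                            alpha = config$alpha,
                            aicTol = config$aicTol)
      models[[id]] <- list(fit = fit, k = ks$k,
                           family = famSel$table, trace = fit@trace)
      tt <- termTable(fit)
      if (nrow(tt)) {
        tt$response <- resp
        tt$model <- id
        termRows[[id]] <- tt
      }
      for (b in bio) {
        for (h in .HABITATS) {
          sc <- classifyShape(fit, b, h, alpha = config$alpha)
          shapeRows[[paste(id, b, h)]] <- data.frame(
            model = id, response = resp, biodiversity = b, habitat = h,
            shape = sc$label, extremum = sc$extremum, p = sc$p)
        }
      }
    }
  }
  list(biodiversity = biod, functioning = func, env = env,
       reduced = red, models = models,
       terms = .rbindAll(termRows), shapes = .rbindAll(shapeRows))
}

#' Per-habitat headline shape calls
#'
#' The pipeline's summary of the biodiversity-functioning relationship
#' per habitat: the shape call of the taxonomic-biodiversity PC1 smooth
#' in the functioning PC1 model.
#'
#' @param result an [analyzeDataset()] result.
#' @return named character vector over habitats.
#' @export
habitatShapeCalls <- function(result) {
  sh <- result$shapes
  sel <- sh[sh$model == "FuncPC1.Tax" & sh$biodiversity == "TaxPC1", ]
  stats::setNames(sel$shape, sel$habitat)[.HABITATS]
}

#' Run the pipeline end to end
#'
#' Generates (or reads) the inputs, validates them, analyses them, and
#' writes machine-readable outputs plus a `manifest.json` with input and
#' output hashes; reruns under the same configuration are bit-identical.
#'
#' @param config a [runConfig()] with `outputDir` set.
#' @return the [analyzeDataset()] result, invisibly, with `manifest`
#'   attached.
#' @export
runPipeline <- function(config) {
  .assert(inherits(config, "RunConfig"), "config must come from runConfig()")
  if (!is.null(config$sim)) {
    dataset <- generateDataset(config$sim)
  } else {
    rep <- validateInputs(config$inputDir)
    if (!rep$pass) {
      stop("input validation failed:\n",
           paste(sprintf("  %s: %s", rep$issues$file,
                         rep$issues$message), collapse = "\n"))
    }
    dataset <- readDataset(config$inputDir)
  }
  res <- analyzeDataset(dataset, config)
  out <- config$outputDir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) write.csv(x, file.path(out, f),
                                  row.names = FALSE)
    w(res$biodiversity, "biodiversity.csv")
    w(res$functioning, "functioning.csv")
    w(cbind(sample = rownames(res$env), res$env), "env.csv")
    red <- res$reduced
    w(red$data, "pca_scores.csv")
    loadRows <- list()
    varRows <- list()
    for (g in names(red$bundles)) {
      b <- red$bundles[[g]]
      if (is.null(b)) next
      L <- b@loadings
      loadRows[[g]] <- data.frame(grouping = g,
                                  variable = rownames(L),
                                  component = rep(colnames(L),
                                                  each = nrow(L)),
                                  loading = as.vector(L))
      varRows[[g]] <- data.frame(grouping = g,
                                 component = colnames(L),
                                 variance_pct = 100 * b@varFrac)
    }
    w(do.call(rbind, loadRows), "pca_loadings.csv")
    w(do.call(rbind, varRows), "pca_variance.csv")
    w(res$terms, "terms.csv")
    w(res$shapes, "shapes.csv")
    smRows <- list()
    for (id in names(res$models)) {
      fit <- res$models[[id]]$fit
      for (tm in fit@spec$terms) {
        if (is.na(tm$by)) next
        for (h in .HABITATS) {
          ev <- evaluateSmooth(fit, tm$variable, h, gridSize = 100L)
          ev$model <- id
          ev$term <- sprintf("s(%s):habitat%s", tm$variable, h)
          smRows[[paste(id, tm$variable, h)]] <- ev
        }
      }
    }
    if (length(smRows)) w(.rbindAll(smRows), "smooths.csv")
    files <- sort(list.files(out, pattern = "\\.csv$"))
    manifest <- list(
      package = as.character(utils::packageVersion("seepBEF")),
      seed = if (!is.null(config$sim)) config$sim$seed else NA,
      n_samples = ncol(dataset$se),
      hashes = as.list(tools::md5sum(file.path(out, files))))
    names(manifest$hashes) <- files
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  invisible(res)
}

.rbindAll <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
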