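#' DepthGrid: a single-band cell-centred raster
#'
#' Minimal regular-grid container for bathymetry and derived terrain
#' layers: a numeric matrix whose first row is the northernmost row
#' (row-major from the top-left), a cell size in metres, and the planar
#' coordinates of the lower-left grid corner. Depth is stored positive
#' down.
#'
#' @slot values numeric matrix (rows north to south).
#' @slot cellSize cell edge length (m).
#' @slot xll,yll coordinates of the lower-left corner of the grid.
#' @slot nodata missing-value sentinel used on disk.
#' @exportClass DepthGrid
setClass("DepthGrid",
         representation(values = "matrix", cellSize = "numeric",
                        xll = "numeric", yll = "numeric",
                        nodata = "numeric"))

setValidity("DepthGrid", function(object) {
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    return("grid must be non-empty")
  TRUE
})

#' @rdname DepthGrid-class
#' @param values,cellSize,xll,yll,nodata see slots.
#' @export
DepthGrid <- function(values, cellSize = 1, xll = 0, yll = 0,
                      nodata = -9999) {
  new("DepthGrid", values = as.matrix(values), cellSize = cellSize,
      xll = xll, yll = yll, nodata = nodata)
}

#' @rdname DepthGrid-class
#' @param x a `DepthGrid`.
#' @export
gridValues <- function(x) x@values

#' @rdname DepthGrid-class
#' @export
cellSize <- function(x) x@cellSize

setMethod("show", "DepthGrid", function(object) {
  v <- object@values
  cat("DepthGrid:", nrow(v), "x", ncol(v), "cells @", object@cellSize,
      "m\n  range:", paste(signif(range(v), 5), collapse = " .. "), "\n")
})

## cell-centre coordinates; row 1 is the northern edge
.cellCenters <- function(g) {
  v <- gridValues(g)
  cs <- cellSize(g)
  list(x = g@xll + (seq_len(ncol(v)) - 0.5) * cs,
       y = g@yll + (nrow(v) - seq_len(nrow(v)) + 0.5) * cs)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text `.asc` raster I/O (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header followed by row-major values, north row first).
#'
#' @param path file path.
#' @return `readAsciiGrid()` a [DepthGrid-class]; `writeAsciiGrid()` the
#'   path, invisibly.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  DepthGrid(m, cellSize = hdr$cellsize, xll = hdr$xllcorner,
            yll = hdr$yllcorner, nodata = nodata)
}

#' @rdname readAsciiGrid
#' @param grid a [DepthGrid-class].
#' @export
writeAsciiGrid <- function(grid, path) {
  v <- gridValues(grid)
  v[is.na(v)] <- grid@nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", grid@xll), paste("yllcorner", grid@yll),
           paste("cellsize", grid@cellSize),
           paste("NODATA_value", grid@nodata))
  body <- apply(v, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Interpolate point measurements onto a grid
#'
#' Assigns a value to every cell of `grid` from scattered (x, y, value)
#' points, by nearest neighbour or inverse-distance weighting (power 2
#' over the `k` nearest points). A point coinciding with a cell centre
#' fixes that cell to the point's value.
#'
#' @param points data.frame with columns `x`, `y`, `value`.
#' @param grid a [DepthGrid-class] supplying the target geometry.
#' @param method `"nearest"` or `"idw"`.
#' @param k number of neighbours for IDW (capped at the point count).
#' @return a [DepthGrid-class] of interpolated values on the same
#'   geometry.
#' @export
interpolateToGrid <- function(points, grid, method = c("nearest", "idw"),
                              k = 12L) {
  method <- match.arg(method)
  .assert(nrow(points) >= 1L, "need at least one point")
  cc <- .cellCenters(grid)
  xy <- expand.grid(y = cc$y, x = cc$x)    # column-major over matrix
  d2 <- outer(xy$x, points$x, "-")^2 + outer(xy$y, points$y, "-")^2
  if (method == "nearest") {
    vals <- points$value[max.col(-d2, ties.method = "first")]
  } else {
    k <- min(k, nrow(points))
    vals <- vapply(seq_len(nrow(xy)), function(i) {
      di <- d2[i, ]
      near <- order(di)[seq_len(k)]
      if (di[near[1]] == 0) return(points$value[near[1]])
      w <- 1 / di[near]                    # power-2 weights on distance
      sum(w * points$value[near]) / sum(w)
    }, numeric(1))
  }
  DepthGrid(matrix(vals, nrow = nrow(gridValues(grid))),
            cellSize = cellSize(grid), xll = grid@xll, yll = grid@yll,
            nodata = grid@nodata)
}

#' Annual net primary productivity
#'
#' Sums twelve monthly NPP values into an annual figure. Under the
#' default `"totals"` convention the inputs are taken as monthly totals
#' and summed directly; under `"mean_times_days"` each monthly mean rate
#' is first multiplied by the days in that month (non-leap calendar).
#'
#' @param monthly numeric vector of exactly 12 non-negative values,
#'   January first.
#' @param convention `"totals"` or `"mean_times_days"`.
#' @return annual NPP in the input units (per year).
#' @export
annualNpp <- function(monthly, convention = c("totals",
                                              "mean_times_days")) {
  convention <- match.arg(convention)
  .assert(length(monthly) == 12L && !anyNA(monthly),
          "need exactly 12 non-missing monthly values")
  .assert(all(monthly >= 0), "NPP cannot be negative")
  if (convention == "totals") return(sum(monthly))
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  sum(monthly * days)
}

#' Depth-attenuated export flux of surface productivity
#'
#' Exponential-plus-baseline attenuation of annual NPP with water depth:
#' `flux = npp * (prd * exp(-depth / rld) + prr)`, with `prd` the
#' export-able fraction at the surface, `rld` the remineralization length
#' depth (m) and `prr` the refractory fraction reaching arbitrary depth.
#' Strictly decreasing in depth; tends to `npp * prr` as depth grows.
#'
#' @param npp_annual annual NPP (e.g. mg C m^-2 yr^-1).
#' @param depth_m water depth (m, >= 0).
#' @param params list with `prd`, `rld`, `prr`.
#' @return export flux at the seafloor, same units as `npp_annual`.
#' @export
exportFlux <- function(npp_annual, depth_m,
                       params = list(prd = 0.1, rld = 800, prr = 0.015)) {
  .assert(all(depth_m >= 0), "depth must be >= 0")
  .assert(params$rld > 0, "rld must be > 0")
  .assert(params$prd >= 0 && params$prr >= 0,
          "prd and prr must be >= 0")
  npp_annual * (params$prd * exp(-depth_m / params$rld) + params$prr)
}

## pad a matrix by replicating its border (edge policy for 3x3 windows)
.padEdges <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
}

.terrainApply <- function(grid, fun) {
  v <- gridValues(grid)
  .assert(nrow(v) >= 3L && ncol(v) >= 3L, "grid must be at least 3x3")
  p <- .padEdges(v)
  nr <- nrow(v); nc <- ncol(v)
  ## 3x3 neighbourhood layers around each original cell
  nb <- lapply(-1:1, function(di) lapply(-1:1, function(dj)
    p[seq_len(nr) + 1L + di, seq_len(nc) + 1L + dj, drop = FALSE]))
  out <- fun(nb, cellSize(grid))
  DepthGrid(out, cellSize = cellSize(grid), xll = grid@xll,
            yll = grid@yll, nodata = grid@nodata)
}

#' Terrain derivatives of a bathymetry grid
#'
#' Whole-grid slope, Terrain Ruggedness Index and Topographic Position
#' Index over 3x3 neighbourhoods, with border cells handled by
#' replicating the grid edge (values there are reported but approximate).
#'
#' * `terrainSlope()` — Horn's weighted finite differences; the slope
#'   angle `atan(sqrt(gx^2 + gy^2))` in degrees.
#' * `terrainTri()` — mean absolute difference between a cell and its 8
#'   neighbours (Wilson variant), in metres.
#' * `terrainTpi()` — cell value minus the mean of its 8 neighbours (m).
#'
#' @param grid a [DepthGrid-class].
#' @return a [DepthGrid-class] of the derived quantity.
#' @export
terrainSlope <- function(grid) {
  .terrainApply(grid, function(nb, cs) {
    z <- function(i, j) nb[[i + 2L]][[j + 2L]]   # offsets -1..1
    gx <- ((z(-1, 1) + 2 * z(0, 1) + z(1, 1)) -
           (z(-1, -1) + 2 * z(0, -1) + z(1, -1))) / (8 * cs)
    gy <- ((z(1, -1) + 2 * z(1, 0) + z(1, 1)) -
           (z(-1, -1) + 2 * z(-1, 0) + z(-1, 1))) / (8 * cs)
    atan(sqrt(gx^2 + gy^2)) * 180 / pi
  })
}

#' @rdname terrainSlope
#' @export
terrainTri <- function(grid) {
  .terrainApply(grid, function(nb, cs) {
    ctr <- nb[[2L]][[2L]]
    acc <- 0
    for (i in -1:1) for (j in -1:1) if (i || j)
      acc <- acc + abs(nb[[i + 2L]][[j + 2L]] - ctr)
    acc / 8
  })
}

#' @rdname terrainSlope
#' @export
terrainTpi <- function(grid) {
  .terrainApply(grid, function(nb, cs) {
    ctr <- nb[[2L]][[2L]]
    acc <- 0
    for (i in -1:1) for (j in -1:1) if (i || j)
      acc <- acc + nb[[i + 2L]][[j + 2L]]
    ctr - acc / 8
  })
}

#' Extract grid values at sample coordinates
#'
#' Looks up, for each sample, the value of the grid cell containing its
#' planar coordinate (no sub-cell interpolation).
#'
#' @param grids named list of [DepthGrid-class] objects sharing one
#'   geometry.
#' @param coords data.frame with columns `sample`, `x`, `y`.
#' @return data.frame keyed by sample with one column per grid.
#' @export
extractAtSamples <- function(grids, coords) {
  g1 <- grids[[1L]]
  v1 <- gridValues(g1)
  cs <- cellSize(g1)
  col <- floor((coords$x - g1@xll) / cs) + 1L
  rowFromBottom <- floor((coords$y - g1@yll) / cs) + 1L
  row <- nrow(v1) - rowFromBottom + 1L
  bad <- col < 1L | col > ncol(v1) | row < 1L | row > nrow(v1)
  .assert(!any(bad), "coordinates outside grid for sample: %s",
          paste(coords$sample[bad], collapse = ", "))
  out <- data.frame(sample = coords$sample)
  for (nm in names(grids)) {
    out[[nm]] <- gridValues(grids[[nm]])[cbind(row, col)]
  }
  rownames(out) <- out$sample
  out
}
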