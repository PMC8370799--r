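#' Evaluate a fitted smooth with pointwise intervals
#'
#' Evaluates one smooth term of a [BefGamFit-class] (and its first
#' derivative, by central finite differences on the linear-predictor
#' matrix) on a regular grid over the predictor's observed range; for
#' by-factor smooths the range observed within that activity level.
#' Pointwise standard errors come from the coefficient covariance of the
#' penalized fit.
#'
#' @param fit a [BefGamFit-class].
#' @param variable smoothed variable name.
#' @param level activity level for by-factor smooths, `NA` for global
#'   smooths.
#' @param gridSize number of grid points (>= 10).
#' @return data.frame: `x`, `fit`, `se`, `deriv`, `deriv_se`.
#' @export
evaluateSmooth <- function(fit, variable, level = NA_character_,
                           gridSize = 200L) {
  .assert(gridSize >= 10L, "gridSize must be at least 10")
  model <- fit@model
  label <- if (is.na(level)) sprintf("s(%s)", variable) else
    sprintf("s(%s):habitat%s", variable, level)
  labs <- vapply(model$smooth, `[[`, character(1), "label")
  i <- match(label, labs)
  .assert(!is.na(i), "no smooth term '%s' in the model", label)
  sm <- model$smooth[[i]]
  mf <- model$model
  xobs <- mf[[variable]]
  if (!is.na(level)) xobs <- xobs[mf$habitat == level]
  xr <- range(xobs)
  xg <- seq(xr[1], xr[2], length.out = gridSize)

  nd <- mf[rep(1L, gridSize), , drop = FALSE]
  for (v in names(nd)) if (is.numeric(nd[[v]])) nd[[v]] <- 0
  lev <- if (is.na(level)) levels(mf$habitat)[1L] else level
  nd$habitat <- factor(rep(lev, gridSize), levels = levels(mf$habitat))
  cols <- sm$first.para:sm$last.para
  beta <- stats::coef(model)[cols]
  Vp <- model$Vp[cols, cols, drop = FALSE]
  lp <- function(x) {
    nd[[variable]] <- x
    predict(model, newdata = nd, type = "lpmatrix")[, cols, drop = FALSE]
  }
  X <- lp(xg)
  h <- diff(xr) / 1000
  Xd <- (lp(xg + h) - lp(xg - h)) / (2 * h)
  data.frame(
    x = xg,
    fit = drop(X %*% beta),
    se = sqrt(pmax(rowSums((X %*% Vp) * X), 0)),
    deriv = drop(Xd %*% beta),
    deriv_se = sqrt(pmax(rowSums((Xd %*% Vp) * Xd), 0)))
}

#' Classify the shape of a fitted biodiversity-functioning smooth
#'
#' Formalizes the visual reading of a fitted smooth. A term that was
#' dropped during selection, or whose approximate p-value is at or above
#' `alpha`, is `"null"`. Otherwise the first derivative and its pointwise
#' 95% interval are evaluated on a grid: where the interval excludes
#' zero the derivative has a credible sign. A single credible sign is
#' `"monotone_increasing"`/`"monotone_decreasing"`; exactly one credible
#' sign change is `"unimodal"`, with the interior extremum located at the
#' grid optimum of the fitted smooth; anything else is `"complex"`.
#'
#' @inheritParams evaluateSmooth
#' @param alpha significance level for the null call.
#' @return list of class `"ShapeCall"`: `label`, `extremum` (`NA` unless
#'   unimodal; predictor units), `term`, `p`.
#' @export
classifyShape <- function(fit, variable, level = NA_character_,
                          gridSize = 200L, alpha = 0.05) {
  .assert(gridSize >= 10L, "gridSize must be at least 10")
  term <- if (is.na(level)) sprintf("s(%s)", variable) else
    sprintf("s(%s):habitat%s", variable, level)
  tt <- fit@termTable
  row <- tt[tt$term == term, , drop = FALSE]
  mk <- function(label, extremum = NA_real_, p = NA_real_) {
    structure(list(label = label, extremum = extremum, term = term,
                   p = p), class = "ShapeCall")
  }
  if (nrow(row) == 0L) return(mk("null"))         # dropped in selection
  p <- row$p[1L]
  if (p >= alpha) return(mk("null", p = p))
  ev <- evaluateSmooth(fit, variable, level, gridSize)
  z <- stats::qnorm(0.975)
  credSign <- ifelse(ev$deriv - z * ev$deriv_se > 0, 1L,
                     ifelse(ev$deriv + z * ev$deriv_se < 0, -1L, 0L))
  runs <- rle(credSign[credSign != 0L])$values
  if (length(runs) == 0L) return(mk("complex", p = p))
  if (length(runs) == 1L) {
    return(mk(if (runs == 1L) "monotone_increasing"
              else "monotone_decreasing", p = p))
  }
  if (length(runs) == 2L) {
    return(mk("unimodal",
              extremum = .locateExtremum(ev, maximize =
                                           identical(runs, c(1L, -1L))),
              p = p))
  }
  mk("complex", p = p)
}

## Interior extremum of an evaluated smooth. The raw grid optimum
## inherits basis-scale wiggle, so the location is refined by an
## (inverse-variance weighted) quadratic approximation of the fitted
## curve within 1.5 predictor-sd of the optimum; if the local quadratic
## is not curved the right way the grid optimum is kept.
.locateExtremum <- function(ev, maximize = TRUE) {
  i <- if (maximize) which.max(ev$fit) else which.min(ev$fit)
  w <- abs(ev$x - ev$x[i]) <= 1.5
  if (sum(w) >= 5L) {
    fit <- stats::lm(fit ~ x + I(x^2), data = ev[w, ],
                     weights = 1 / (ev$se[w]^2 + 1e-8))
    cf <- stats::coef(fit)
    if (is.finite(cf[3L]) && ((maximize && cf[3L] < 0) ||
                              (!maximize && cf[3L] > 0))) {
      vertex <- -cf[2L] / (2 * cf[3L])
      return(min(max(vertex, min(ev$x)), max(ev$x)))
    }
  }
  ev$x[i]
}

#' @export
print.ShapeCall <- function(x, ...) {
  cat("ShapeCall:", x$label)
  if (!is.na(x$extremum)) cat(sprintf(" (extremum at %.3f)", x$extremum))
  if (!is.na(x$p)) cat(sprintf("  [%s, p = %.4g]", x$term, x$p))
  cat("\n")
  invisible(x)
}
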