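#' Specification of the habitat-stratified additive model
#'
#' Describes one model: a functioning principal-component response, the
#' seep-activity factor as a parametric term, a by-factor smooth of each
#' biodiversity axis (one centred smooth per activity level, each with
#' its own penalty, test statistic and p-value), and single smooths of
#' the environmental covariates.
#'
#' @param response response variable name (a functioning PC axis).
#' @param biodiversity biodiversity axis names smoothed per habitat.
#' @param covariates covariate names smoothed globally.
#' @param k basis dimension of every smooth (cubic regression splines).
#' @param family error family + link (an R [stats::family] object).
#' @param criterion smoothing-parameter criterion: `"GCV.Cp"` (default)
#'   or `"REML"`.
#' @param gamma inflation of the effective dof in the smoothing
#'   criterion; values around 1.4 counter the well-known tendency of GCV
#'   to undersmooth at small sample sizes.
#' @return list of class `"GamSpec"`.
#' @export
gamSpec <- function(response = "FuncPC1",
                    biodiversity = c("TaxPC1", "TaxPC2"),
                    covariates = c("OceanPC1", "OceanPC2", "TerrainPC1",
                                   "TPI"),
                    k = 5L, family = stats::gaussian(),
                    criterion = c("GCV.Cp", "REML"), gamma = 1.4) {
  criterion <- match.arg(criterion)
  .assert(k >= 3 && k <= 10, "basis dimension k must lie in [3, 10]")
  terms <- list()
  for (b in biodiversity) {
    terms[[length(terms) + 1L]] <- list(
      variable = b, by = "habitat", k = k,
      label = sprintf("s(%s):habitat", b))
  }
  for (v in covariates) {
    terms[[length(terms) + 1L]] <- list(
      variable = v, by = NA_character_, k = k,
      label = sprintf("s(%s)", v))
  }
  structure(list(response = response, biodiversity = biodiversity,
                 covariates = covariates, terms = terms, k = k,
                 family = family, criterion = criterion, gamma = gamma),
            class = "GamSpec")
}

## mgcv formula for a (possibly reduced) term set
.gamFormula <- function(spec, terms = spec$terms) {
  frag <- vapply(terms, function(tm) {
    if (is.na(tm$by)) {
      sprintf("s(%s, k = %d, bs = 'cr')", tm$variable, tm$k)
    } else {
      sprintf("s(%s, k = %d, bs = 'cr', by = %s)", tm$variable, tm$k,
              tm$by)
    }
  }, character(1))
  rhs <- if (length(frag)) paste("habitat +",
                                 paste(frag, collapse = " + "))
         else "habitat"
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' BefGamFit: a fitted habitat-stratified additive model
#'
#' @slot model the underlying \pkg{mgcv} fit.
#' @slot spec the [gamSpec()] used (possibly with terms removed).
#' @slot termTable one row per fitted smooth (by-factor terms contribute
#'   one row per activity level): effective dof, F, approximate p.
#' @slot aic model AIC.
#' @slot adjR2 adjusted R-squared.
#' @slot trace backward-selection trace (empty for a direct fit).
#' @exportClass BefGamFit
setClass("BefGamFit",
         representation(model = "ANY", spec = "ANY",
                        termTable = "data.frame", aic = "numeric",
                        adjR2 = "numeric", trace = "list"))

setMethod("show", "BefGamFit", function(object) {
  cat("BefGamFit:", deparse(stats::formula(object@model)), "\n")
  cat(sprintf("  AIC %.2f  adj-R2 %.3f  n %d\n", object@aic,
              object@adjR2, stats::nobs(object@model)))
  print(object@termTable, digits = 3)
})

#' @rdname BefGamFit-class
#' @param fit a `BefGamFit`.
#' @export
termTable <- function(fit) fit@termTable

## map a summary.gam s.table row name back to the GamSpec term and level
.parseRow <- function(rowname, spec) {
  for (tm in spec$terms) {
    if (is.na(tm$by)) {
      if (rowname == tm$label) {
        return(list(formulaTerm = tm$label, variable = tm$variable,
                    level = NA_character_))
      }
    } else {
      pre <- sprintf("s(%s):%s", tm$variable, tm$by)
      if (startsWith(rowname, pre)) {
        return(list(formulaTerm = tm$label, variable = tm$variable,
                    level = substring(rowname, nchar(pre) + 1L)))
      }
    }
  }
  list(formulaTerm = NA_character_, variable = NA_character_,
       level = NA_character_)
}

.summarizeFit <- function(model, spec, trace = list()) {
  sm <- mgcv::summary.gam(model)
  st <- sm$s.table
  if (is.null(st) || nrow(st) == 0L) {
    tt <- data.frame(term = character(), formulaTerm = character(),
                     variable = character(), level = character(),
                     edf = numeric(), F = numeric(), p = numeric())
  } else {
    info <- lapply(rownames(st), .parseRow, spec = spec)
    stat <- if ("F" %in% colnames(st)) st[, "F"] else st[, "Chi.sq"]
    tt <- data.frame(
      term = rownames(st),
      formulaTerm = vapply(info, `[[`, character(1), "formulaTerm"),
      variable = vapply(info, `[[`, character(1), "variable"),
      level = vapply(info, `[[`, character(1), "level"),
      edf = st[, "edf"], F = stat,
      p = pmin(pmax(st[, "p-value"], 0), 1), row.names = NULL)
  }
  new("BefGamFit", model = model, spec = spec, termTable = tt,
      aic = stats::AIC(model), adjR2 = sm$r.sq, trace = trace)
}

#' Fit the habitat-stratified additive model
#'
#' Penalized cubic regression splines with smoothing parameters chosen by
#' generalized cross-validation (or REML). Requires at least 5
#' observations per activity level and basis dimensions no larger than
#' the smallest per-level sample size for by-factor smooths.
#'
#' @param spec a [gamSpec()].
#' @param data model table as produced by [reduceVariables()] (`$data`).
#' @return a [BefGamFit-class].
#' @export
fitBefGam <- function(spec, data) {
  .assert(inherits(spec, "GamSpec"), "spec must come from gamSpec()")
  .assert(spec$response %in% names(data),
          "response '%s' not in data", spec$response)
  data$habitat <- factor(as.character(data$habitat), levels = .HABITATS)
  grp <- table(data$habitat)
  .assert(all(grp >= 5), "need at least 5 observations per habitat")
  vars <- unique(vapply(spec$terms, `[[`, character(1), "variable"))
  for (v in vars) {
    .assert(all(is.finite(data[[v]])), "non-finite values in '%s'", v)
  }
  for (tm in spec$terms) {
    if (!is.na(tm$by)) {
      .assert(tm$k <= min(grp),
              "k = %d exceeds the smallest habitat sample size (%d) for %s",
              tm$k, min(grp), tm$label)
    }
  }
  model <- mgcv::gam(.gamFormula(spec), data = data,
                     family = spec$family, method = spec$criterion,
                     gamma = spec$gamma %||% 1, select = FALSE)
  if (anyNA(stats::coef(model))) {
    bad <- unique(gsub("\\.\\d+$", "",
                       names(stats::coef(model))[is.na(stats::coef(model))]))
    stop("rank-deficient fit; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- .summarizeFit(model, spec)
  ## a GCV collapse to (near-)zero residual variance leaves no basis for
  ## inference: reject so selection falls back to a smaller basis
  .assert(sum(model$edf) <= stats::nobs(model) - 2,
          "saturated fit: effective dof leave no residual information")
  .assert(!any(is.nan(fit@termTable$p)),
          "degenerate fit: term tests undefined (zero residual variance)")
  fit
}

#' Select error family and link by AIC under residual diagnostics
#'
#' Fits the model under each candidate family/link; candidates whose
#' deviance residuals fail a Shapiro-Wilk normality check (p < 0.01) or
#' show a residual-versus-fitted trend (Spearman p < 0.05) are set aside.
#' Among the remainder (or among all converged candidates if none pass),
#' the smallest AIC wins; ties go to gaussian/identity.
#'
#' @param spec a [gamSpec()]; its `family` field is ignored.
#' @param data model table.
#' @param candidates list of [stats::family] objects.
#' @return list with `family` (the winner), `fit` (its [BefGamFit-class])
#'   and `table` (per-candidate AIC and diagnostics).
#' @export
selectFamilyLink <- function(spec, data,
                             candidates = list(stats::gaussian(),
                                               stats::Gamma(link = "log"))) {
  .assert(length(candidates) >= 1L, "need at least one candidate family")
  rows <- list()
  fits <- list()
  for (i in seq_along(candidates)) {
    fam <- candidates[[i]]
    s2 <- spec
    s2$family <- fam
    fit <- tryCatch(fitBefGam(s2, data), error = function(e) NULL)
    if (is.null(fit)) next
    r <- stats::residuals(fit@model, type = "deviance")
    swp <- tryCatch(stats::shapiro.test(r)$p.value,
                    error = function(e) NA_real_)
    trp <- tryCatch(
      suppressWarnings(stats::cor.test(r, stats::fitted(fit@model),
                                       method = "spearman")$p.value),
      error = function(e) NA_real_)
    pass <- isTRUE(swp >= 0.01) && isTRUE(trp > 0.05)
    key <- paste(fam$family, fam$link, sep = "/")
    fits[[key]] <- fit
    rows[[key]] <- data.frame(family = fam$family, link = fam$link,
                              aic = fit@aic, shapiro_p = swp,
                              trend_p = trp, diagnostics_pass = pass)
  }
  .assert(length(fits) > 0L, "no candidate family converged")
  tab <- do.call(rbind, rows)
  pool <- if (any(tab$diagnostics_pass)) tab[tab$diagnostics_pass, ]
          else tab
  ## ties (to 1e-8) resolve to gaussian/identity when present
  best <- pool[order(round(pool$aic, 8),
                     pool$family != "gaussian"), ][1L, ]
  key <- paste(best$family, best$link, sep = "/")
  list(family = fits[[key]]@spec$family, fit = fits[[key]], table = tab)
}

#' Choose the smooth basis dimension by AIC
#'
#' Refits the model over candidate basis dimensions (shared across
#' smooths) and returns the candidate minimizing AIC, subject to every
#' smooth's effective dof staying below `k - 1` (a guard against bases
#' too small for the fitted flexibility). Candidates larger than the
#' smallest per-habitat sample size are excluded.
#'
#' @param spec a [gamSpec()].
#' @param data model table.
#' @param kCandidates integer candidates within [3, 10].
#' @return list with `k` (the winner), `fit`, and `aic` per candidate.
#' @export
selectKnots <- function(spec, data, kCandidates = 4:6) {
  .assert(all(kCandidates >= 3 & kCandidates <= 10),
          "knot candidates must lie in [3, 10]")
  nmin <- min(table(data$habitat))
  kCandidates <- kCandidates[kCandidates <= nmin]
  .assert(length(kCandidates) > 0L,
          "all knot candidates exceed the per-habitat sample size")
  aics <- stats::setNames(rep(NA_real_, length(kCandidates)),
                          kCandidates)
  fits <- list()
  for (k in kCandidates) {
    s2 <- spec
    s2$k <- k
    s2$terms <- lapply(s2$terms, function(tm) { tm$k <- k; tm })
    fit <- tryCatch(fitBefGam(s2, data), error = function(e) NULL)
    if (is.null(fit)) next
    if (any(fit@termTable$edf > k - 1 + 1e-6)) next
    fits[[as.character(k)]] <- fit
    aics[as.character(k)] <- fit@aic
  }
  .assert(length(fits) > 0L, "no knot candidate converged")
  kBest <- names(which.min(aics))
  list(k = as.integer(kBest), fit = fits[[kBest]], aic = aics)
}

#' Backward stepwise term selection
#'
#' Starting from a full fit, repeatedly removes the formula term whose
#' smallest per-smooth p-value is the largest above `alpha` (a by-factor
#' smooth is a removal candidate only when every activity level is
#' non-significant), provided the removal does not increase the AIC by
#' more than `aicTol`; stops when no term qualifies. The activity factor
#' and intercept are never removed. The trace records every step.
#'
#' @param fit a full-model [BefGamFit-class].
#' @param data the model table the fit was built from.
#' @param alpha p-value threshold above which a term is a removal
#'   candidate.
#' @param aicTol maximal tolerated AIC increase per removal.
#' @return the reduced [BefGamFit-class]; `@trace` holds one record per
#'   attempted removal.
#' @export
backwardSelect <- function(fit, data, alpha = 0.05, aicTol = 2) {
  cur <- fit
  trace <- list()
  frozen <- character()
  repeat {
    spec <- cur@spec
    tt <- cur@termTable
    if (nrow(tt) == 0L) break
    byTerm <- vapply(split(tt$p, tt$formulaTerm), min, numeric(1))
    cand <- byTerm[!is.na(byTerm) & byTerm > alpha &
                     !(names(byTerm) %in% frozen)]
    if (!length(cand)) break
    worst <- names(cand)[which.max(cand)]
    keep <- Filter(function(tm) tm$label != worst, spec$terms)
    s2 <- spec
    s2$terms <- keep
    red <- if (length(keep)) {
      tryCatch(fitBefGam(s2, data), error = function(e) NULL)
    } else {
      warning("all smooth terms removed; returning activity-factor model")
      data$habitat <- factor(as.character(data$habitat),
                             levels = .HABITATS)
      .summarizeFit(
        mgcv::gam(stats::as.formula(paste(spec$response, "~ habitat")),
                  data = data, family = spec$family,
                  method = spec$criterion, gamma = spec$gamma %||% 1),
        s2)
    }
    if (is.null(red)) {          # reduced model failed to fit: keep term
      frozen <- c(frozen, worst)
      next
    }
    accepted <- red@aic <= cur@aic + aicTol
    trace[[length(trace) + 1L]] <-
      list(dropped = worst, p = unname(cand[worst]),
           aic_before = cur@aic, aic_after = red@aic,
           accepted = accepted)
    if (accepted) {
      cur <- red
    } else {
      frozen <- c(frozen, worst)   # removal too costly; keep the term
    }
  }
  cur@trace <- trace
  cur
}
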