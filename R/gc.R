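#' @include quantify.R
NULL

.GC_RUN_MINUTES <- 58

#' Fit a GC-FAME calibration curve
#'
#' Ordinary least squares of amount on integrated peak area, from
#' standards of known amount. The fitted range is kept so predictions
#' outside it can be flagged as extrapolations.
#'
#' @param points data.frame with columns `area` and `amount` (>= 2
#'   distinct areas).
#' @param fame Optional FAME name carried on the curve.
#' @return [CalibrationCurve-class] object.
#' @examples
#' fitCalibration(data.frame(area = c(1, 2, 3), amount = c(2, 4, 6)))
#' @export
fitCalibration <- function(points, fame = NA_character_) {
  if (!all(c("area", "amount") %in% names(points)))
    stop("calibration points need columns 'area' and 'amount'", call. = FALSE)
  if (length(unique(points$area)) < 2)
    stop("calibration needs at least 2 distinct areas", call. = FALSE)
  fit <- stats::lm(amount ~ area, data = points)
  slope <- unname(coef(fit)["area"])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  new("CalibrationCurve", fame = fame, slope = slope,
      intercept = unname(coef(fit)["(Intercept)"]),
      fitRange = range(points$area),
      residuals = unname(residuals(fit)))
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve%s: amount = %.4g * area %+.4g (areas %.3g-%.3g)\n",
              if (is.na(object@fame)) "" else paste0(" [", object@fame, "]"),
              object@slope, object@intercept,
              object@fitRange[1], object@fitRange[2]))
  invisible(NULL)
})

#' Predict amounts from a calibration curve
#'
#' @param curve [CalibrationCurve-class].
#' @param area Numeric areas.
#' @return Numeric amounts; a warning flags areas outside the fitted
#'   range (extrapolation).
#' @export
predictAmount <- function(curve, area) {
  outside <- area < curve@fitRange[1] | area > curve@fitRange[2]
  if (any(outside))
    warning(sprintf("%d area(s) outside the calibration range (extrapolation)",
                    sum(outside)), call. = FALSE)
  curve@slope * area + curve@intercept
}

#' Assign GC peaks to FAMEs by retention time
#'
#' Each peak is assigned to the unique library FAME within `window`
#' minutes; the nearer entry wins on overlap, with ties broken toward the
#' lower retention time (logged). Unassigned peaks are logged and
#' dropped. A library whose retention times collide within `2 * window`
#' is rejected.
#'
#' @param peaks data.frame with columns `rt_min`, `area`.
#' @param rtLibrary data.frame with columns `fame`, `rt_min` (plus
#'   optional `carbons`, `doubleBonds`).
#' @param window Half-width of the retention-time match window (minutes).
#' @return Named numeric vector of summed areas per assigned FAME.
#' @export
identifyFames <- function(peaks, rtLibrary, window = 0.1) {
  if (any(peaks$rt_min < 0 | peaks$rt_min > .GC_RUN_MINUTES))
    stop(sprintf("peak retention time outside the 0-%d min run",
                 .GC_RUN_MINUTES), call. = FALSE)
  if (any(peaks$area < 0)) stop("negative peak area", call. = FALSE)
  lib <- rtLibrary[order(rtLibrary$rt_min), , drop = FALSE]
  if (nrow(lib) > 1 && any(diff(lib$rt_min) < 2 * window))
    stop("retention-time library has collisions within 2*window",
         call. = FALSE)
  areas <- setNames(numeric(nrow(lib)), lib$fame)
  for (k in seq_len(nrow(peaks))) {
    d <- abs(lib$rt_min - peaks$rt_min[k])
    hits <- which(d <= window)
    if (length(hits) == 0) {
      message(sprintf("peak at %.2f min matches no library FAME",
                      peaks$rt_min[k]))
      next
    }
    if (length(hits) > 1) {
      best <- hits[which.min(d[hits])]  # which.min takes the first: lower RT
      message(sprintf("peak at %.2f min between %s; assigned to nearer %s",
                      peaks$rt_min[k],
                      paste(lib$fame[hits], collapse = " and "),
                      lib$fame[best]))
      hits <- best
    }
    areas[lib$fame[hits]] <- areas[lib$fame[hits]] + peaks$area[k]
  }
  areas[areas > 0]
}

.fameKey <- function(fame) {
  m <- regmatches(fame, regexec("([0-9]+):([0-9]+)", fame))
  cd <- vapply(m, function(x) {
    if (length(x) == 0) c(NA_integer_, NA_integer_)
    else c(as.integer(x[2]), as.integer(x[3]))
  }, integer(2))
  list(carbons = cd[1, ], doubleBonds = cd[2, ])
}

#' FA percentages from assigned FAME areas and calibration curves
#'
#' Converts each assigned area to an amount through its calibration
#' curve, normalizes over all quantified FAMEs, and reports
#' saturated/unsaturated totals (zero vs more than zero double bonds).
#' Percentages are mole-based by default; `basis = "weight"` weights each
#' amount by the free acid molecular mass.
#'
#' @param fameAreas Named areas from [identifyFames()].
#' @param curves Named list of [CalibrationCurve-class] objects covering
#'   every assigned FAME.
#' @param basis `"mole"` or `"weight"`.
#' @return List with `amounts`, `percentages` (both named by FAME),
#'   `saturated` and `unsaturated` totals (percent).
#' @export
faPercentages <- function(fameAreas, curves, basis = c("mole", "weight")) {
  basis <- match.arg(basis)
  missing <- setdiff(names(fameAreas), names(curves))
  if (length(missing))
    stop(sprintf("no calibration curve for %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  amounts <- vapply(names(fameAreas), function(f)
    predictAmount(curves[[f]], fameAreas[[f]]), 0)
  key <- .fameKey(names(fameAreas))
  w <- amounts
  if (basis == "weight") {
    mw <- vapply(seq_along(amounts), function(k)
      monoisotopicMass(acylFormula(key$carbons[k], key$doubleBonds[k])), 0)
    w <- amounts * mw
  }
  pct <- 100 * w / sum(w)
  sat <- sum(pct[key$doubleBonds == 0])
  list(amounts = amounts, percentages = pct,
       saturated = sat, unsaturated = 100 - sat)
}

#' One-way ANOVA with Fisher's least significant difference test
#'
#' Standard one-way ANOVA over the groups followed by all pairwise LSD
#' t-tests using the pooled mean squared error, flagged at `alpha`
#' (default 0.01).
#'
#' @param groups Named list of replicate value vectors (>= 2 groups, each
#'   with >= 2 replicates).
#' @param alpha Significance level for the pairwise flags.
#' @return List with `F`, `p`, `dfBetween`, `dfWithin`, `mse`, and
#'   `pairs`, a data.frame of all pairwise comparisons (difference, t,
#'   p-value, significance flag).
#' @export
anovaFisherLsd <- function(groups, alpha = 0.01) {
  if (length(groups) < 2)
    stop("at least 2 groups are required", call. = FALSE)
  n <- vapply(groups, length, 0L)
  if (any(n < 2))
    stop(sprintf("group '%s' has fewer than 2 replicates",
                 names(groups)[which(n < 2)[1]]), call. = FALSE)
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(names(groups), n),
                                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = dat)
  tab <- stats::anova(fit)
  mse <- tab["Residuals", "Mean Sq"]
  dfW <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, 0)
  combs <- utils::combn(names(groups), 2)
  diff <- means[combs[1, ]] - means[combs[2, ]]
  se <- sqrt(mse * (1 / n[combs[1, ]] + 1 / n[combs[2, ]]))
  tval <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf))
  pval <- 2 * stats::pt(-abs(tval), dfW)
  list(F = unname(tab["group", "F value"]),
       p = unname(tab["group", "Pr(>F)"]),
       dfBetween = tab["group", "Df"], dfWithin = dfW, mse = mse,
       pairs = data.frame(groupA = combs[1, ], groupB = combs[2, ],
                          difference = unname(diff), t = unname(tval),
                          p = unname(pval),
                          significant = unname(pval <= alpha),
                          row.names = NULL))
}

#' Packaged FAME retention-time library
#'
#' Seventeen FAMEs from 10 to 22 carbons with retention times on a 58-min
#' temperature-programmed run; positional/cis-trans suffixes (e.g.
#' `n-9c`) are carried verbatim from the standard mix naming and are
#' opaque to the MS side, which collapses to carbons:double-bonds.
#'
#' @return data.frame with columns `fame`, `carbons`, `doubleBonds`,
#'   `rt_min`.
#' @export
defaultRtLibrary <- function() {
  utils::read.delim(system.file("extdata", "fame_rt_library.tsv",
                                package = "milkLipidomics"),
                    stringsAsFactors = FALSE)
}

#' Packaged GC calibration curves
#'
#' One linear curve per library FAME (slopes near unity varying by FAME,
#' zero intercept), standing in for curves fitted from a dilution series
#' of the FAME standard mix.
#'
#' @return Named list of [CalibrationCurve-class] objects.
#' @export
defaultCalibration <- function() {
  lib <- defaultRtLibrary()
  curves <- lapply(seq_len(nrow(lib)), function(k) {
    slope <- 1 + 0.03 * (((k * 7) %% 11) - 5)  # deterministic 0.85-1.15
    new("CalibrationCurve", fame = lib$fame[k], slope = slope,
        intercept = 0, fitRange = c(0, 1e6), residuals = numeric())
  })
  setNames(curves, lib$fame)
}

#' Read GC inputs from TSV
#'
#' `readGcPeaks()` expects columns `rt_min`, `area`; `readRtLibrary()`
#' expects `fame`, `rt_min` (optional `carbons`, `doubleBonds`);
#' `readCalibrationTable()` expects `fame`, `area`, `amount` and fits one
#' curve per FAME.
#'
#' @param path Input file.
#' @return data.frame, or a named list of curves for
#'   `readCalibrationTable()`.
#' @export
readGcPeaks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rt_min", "area") %in% names(tab)))
    stop("GC peak table needs columns 'rt_min' and 'area'", call. = FALSE)
  tab
}

#' @rdname readGcPeaks
#' @export
readRtLibrary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("fame", "rt_min") %in% names(tab)))
    stop("RT library needs columns 'fame' and 'rt_min'", call. = FALSE)
  tab
}

#' @rdname readGcPeaks
#' @export
readCalibrationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("fame", "area", "amount") %in% names(tab)))
    stop("calibration table needs columns 'fame', 'area', 'amount'",
         call. = FALSE)
  curves <- lapply(split(tab, tab$fame), function(d)
    fitCalibration(d, fame = d$fame[1]))
  curves
}
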