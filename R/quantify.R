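#' @include identify.R
NULL

# evidence sum relevant for quantification: structure-specific fragment
# intensities only (FA neutral losses / FA anions / headgroup), never the
# serine-loss or residual-precursor confirmation fragments
.evidenceSum <- function(evidence, route) {
  if (route == "hg") return(sum(evidence[names(evidence) == "headgroup"]))
  sum(evidence[startsWith(names(evidence), "FA ")])
}

.routeOf <- function(lipidClass, level) {
  if (lipidClass == "TAG") "nl"
  else if (level == "molecular") "fa"
  else "hg"
}

#' Internal-standard quantification to pmol and mol%
#'
#' Converts fragment evidence to molar amounts against the spiked
#' class-specific internal standards:
#' `pmol(species) = spike_pmol(std) * sum(evidence(species)) / sum(evidence(std))`,
#' where the evidence sum runs over the species' structure-specific
#' fragment intensities (neutral-loss intensities for TAG, FA anion
#' intensities for molecular glycerophospholipids, the headgroup intensity
#' for sum-level PC/SM). Standards are matched within lipid class and
#' identification route, and are excluded from the output table and all
#' composition denominators.
#'
#' @param identifications Identification data.frame from
#'   [identifyLipids()].
#' @param spikes Spike sheet data.frame (columns `annotation`, `pmol`).
#' @param onMissingStandard `"error"` (default) stops when a class lacks
#'   an identified standard on a route its sample species used;
#'   `"drop"` removes that class/route's identifications with a warning
#'   (composition is then reported over the quantifiable remainder).
#' @return QuantTable data.frame with columns `species`, `lipidClass`,
#'   `level`, `pmol`, `molPctTotal`, `molPctClass`.
#' @export
quantify <- function(identifications, spikes,
                     onMissingStandard = c("error", "drop")) {
  onMissingStandard <- match.arg(onMissingStandard)
  if (nrow(identifications) == 0)
    stop("no identifications to quantify", call. = FALSE)
  if (is.null(spikes) || nrow(spikes) == 0)
    stop("quantification requires a spike sheet", call. = FALSE)
  spikes$lipidClass <- vapply(spikes$annotation, function(a)
    lipidClass(parseAnnotation(a)), "")

  ids <- identifications
  ids$route <- mapply(.routeOf, ids$lipidClass, ids$level)
  ids$evSum <- mapply(function(ev, route) .evidenceSum(ev, route),
                      ids$evidence, ids$route)

  sample <- ids[!ids$internalStandard, , drop = FALSE]
  stds <- ids[ids$internalStandard, , drop = FALSE]
  if (nrow(sample) == 0)
    stop("no non-standard identifications to quantify", call. = FALSE)

  need <- unique(sample[, c("lipidClass", "route")])
  pmol <- numeric(nrow(sample))
  dropRows <- logical(nrow(sample))
  for (k in seq_len(nrow(need))) {
    cls <- need$lipidClass[k]; route <- need$route[k]
    rows <- sample$lipidClass == cls & sample$route == route
    stdRows <- which(stds$lipidClass == cls & stds$route == route)
    bad <- if (length(stdRows) == 0)
      sprintf("no internal standard identified for class %s (%s route)",
              cls, route)
    else if (length(stdRows) == 1 && stds$evSum[stdRows] <= 0)
      sprintf("internal standard for class %s has zero evidence", cls)
    else NULL
    if (!is.null(bad)) {
      if (onMissingStandard == "error") stop(bad, call. = FALSE)
      warning(paste0(bad, "; dropping its identifications"), call. = FALSE)
      dropRows[rows] <- TRUE
      next
    }
    if (length(stdRows) > 1)
      stop(sprintf("multiple internal standards identified for class %s", cls),
           call. = FALSE)
    spikeAmt <- spikes$pmol[spikes$lipidClass == cls]
    if (length(spikeAmt) != 1)
      stop(sprintf("spike sheet must contain exactly one %s standard", cls),
           call. = FALSE)
    pmol[rows] <- spikeAmt * sample$evSum[rows] / stds$evSum[stdRows]
  }
  sample <- sample[!dropRows, , drop = FALSE]
  pmol <- pmol[!dropRows]

  out <- data.frame(species = sample$species,
                    lipidClass = sample$lipidClass,
                    level = sample$level,
                    pmol = pmol,
                    stringsAsFactors = FALSE)
  total <- sum(out$pmol)
  if (total <= 0) stop("all quantified amounts are zero", call. = FALSE)
  out$molPctTotal <- 100 * out$pmol / total
  classTotals <- tapply(out$pmol, out$lipidClass, sum)
  out$molPctClass <- 100 * out$pmol / as.numeric(classTotals[out$lipidClass])
  out <- out[order(out$lipidClass, -out$pmol), ]
  rownames(out) <- NULL
  out
}

#' Lipid class composition in mol%
#'
#' @param quant QuantTable from [quantify()] (internal standards already
#'   excluded).
#' @return Named numeric vector, class -> mol% of total, summing to 100.
#' @export
classComposition <- function(quant) {
  if (nrow(quant) == 0) stop("empty quantification table", call. = FALSE)
  total <- sum(quant$pmol)
  if (total <= 0) stop("all quantified amounts are zero", call. = FALSE)
  pct <- 100 * tapply(quant$pmol, quant$lipidClass, sum) / total
  sort(setNames(as.numeric(pct), names(pct)), decreasing = TRUE)
}

#' FA index of TAG sum compositions
#'
#' For each TAG sum composition, the proportion of each fatty acyl among
#' its neutral-loss fragment intensities:
#' `index(FA) = NL intensity(FA) / sum of NL intensities`. Rows sum to 1.
#'
#' @param identifications Identification data.frame (TAG rows are used).
#' @return Numeric matrix, one row per TAG sum composition, one column per
#'   FA label; zero-evidence species are excluded with a message.
#' @export
tagFaIndex <- function(identifications) {
  tags <- identifications[identifications$lipidClass == "TAG", , drop = FALSE]
  if (nrow(tags) == 0)
    stop("no TAG identifications", call. = FALSE)
  tot <- vapply(tags$evidence, sum, 0)
  if (any(tot <= 0)) {
    message(sprintf("excluding %d TAG species with zero evidence",
                    sum(tot <= 0)))
    tags <- tags[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  fas <- sort(unique(unlist(lapply(tags$evidence, names))))
  idx <- matrix(0, nrow = nrow(tags), ncol = length(fas),
                dimnames = list(tags$species, fas))
  for (k in seq_len(nrow(tags)))
    idx[k, names(tags$evidence[[k]])] <- tags$evidence[[k]] / tot[k]
  idx
}

#' Overall FA profile of TAG molecules
#'
#' The percentage of individual fatty acyls across all quantified TAG
#' species, weighting each species' FA index row by its molar amount:
#' `pct(FA) = 100 * sum_s pmol(s) * index_s(FA) / sum_s pmol(s)`.
#'
#' @param quant QuantTable from [quantify()].
#' @param faIndex FA index matrix from [tagFaIndex()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
tagFaProfile <- function(quant, faIndex) {
  tags <- quant[quant$lipidClass == "TAG", , drop = FALSE]
  tags <- tags[tags$species %in% rownames(faIndex), , drop = FALSE]
  if (nrow(tags) == 0)
    stop("no quantified TAG species covered by the FA index", call. = FALSE)
  w <- tags$pmol / sum(tags$pmol)
  pct <- 100 * as.numeric(w %*% faIndex[tags$species, , drop = FALSE])
  setNames(pct, colnames(faIndex))
}

#' FA unsaturation index
#'
#' Aggregates an FA percentage profile by double-bond count:
#' `U(d) = sum of pct(FA) over FAs with d double bonds`, for d = 0..maxDb.
#'
#' @param faProfile Named percentage vector with `"FA c:d"` names (e.g.
#'   from [tagFaProfile()]).
#' @param maxDb Highest double-bond count expected (default 5); an FA
#'   beyond it is an error.
#' @return Named numeric vector over `"0"`..`"maxDb"` summing to the
#'   profile total (100 for a full profile).
#' @export
unsaturationIndex <- function(faProfile, maxDb = 5L) {
  db <- as.integer(sub("^FA [0-9]+:([0-9]+)$", "\\1", names(faProfile)))
  if (any(is.na(db)))
    stop("profile names must look like 'FA 16:0'", call. = FALSE)
  if (any(db > maxDb))
    stop(sprintf("FA with %d double bonds exceeds the supported range 0-%d",
                 max(db), maxDb), call. = FALSE)
  u <- vapply(0:maxDb, function(d) sum(faProfile[db == d]), 0)
  setNames(u, as.character(0:maxDb))
}

#' Export quantification outputs as TSV
#'
#' Percentages are written with two decimals and fixed column order.
#'
#' @param quant QuantTable from [quantify()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeQuantTable <- function(quant, path) {
  out <- quant
  out$pmol <- sprintf("%.4f", out$pmol)
  out$molPctTotal <- sprintf("%.2f", out$molPctTotal)
  out$molPctClass <- sprintf("%.2f", out$molPctClass)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeQuantTable
#' @param faIndex FA index matrix from [tagFaIndex()].
#' @export
writeFaIndex <- function(faIndex, path) {
  out <- data.frame(species = rownames(faIndex),
                    round(faIndex, 4), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeQuantTable
#' @param profile Named percentage vector (FA profile or unsaturation
#'   index).
#' @export
writeProfile <- function(profile, path) {
  out <- data.frame(key = names(profile),
                    percent = sprintf("%.2f", profile))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
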