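#' @include spectra.R
NULL

#' Construct fragment-matching settings
#'
#' @param toleranceMz Absolute m/z tolerance (default 0.01, TOF-like).
#' @param minTagFragments Minimum distinct neutral-loss fragments to accept
#'   a TAG sum composition (default 2; a single-fragment TAG is
#'   indistinguishable from noise). Spiked standards of known composition
#'   are exempt.
#' @param intensityFloor Matched intensities below this are dropped.
#' @return [MatchSettings-class] object.
#' @export
matchSettings <- function(toleranceMz = 0.01, minTagFragments = 2L,
                          intensityFloor = 0) {
  new("MatchSettings", toleranceMz = toleranceMz,
      minTagFragments = as.integer(minTagFragments),
      intensityFloor = intensityFloor)
}

#' Match predicted fragments against a spectrum
#'
#' Each predicted fragment is matched to the single nearest peak within
#' the tolerance; when two peaks are equidistant the lower-m/z peak is
#' chosen. One peak may serve several predictions only when the predicted
#' m/z values themselves are closer than the tolerance (a message is
#' logged). Matches below the intensity floor are dropped.
#'
#' @param spectrum [MsMsSpectrum-class] (peaks sorted ascending).
#' @param predicted data.frame with columns `label` and `fragmentMz` (or
#'   `mz`).
#' @param settings [MatchSettings-class].
#' @return Named numeric vector of matched intensities (possibly empty).
#' @export
matchFragments <- function(spectrum, predicted, settings = matchSettings()) {
  stopifnot(is(spectrum, "MsMsSpectrum"), is(settings, "MatchSettings"))
  mzCol <- if ("fragmentMz" %in% names(predicted)) "fragmentMz" else "mz"
  pmz <- predicted[[mzCol]]
  peaks <- spectrum@peaks
  if (nrow(peaks) == 0 || length(pmz) == 0)
    return(setNames(numeric(0), character(0)))
  idx <- findInterval(pmz, peaks$mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, nrow(peaks))
  dLo <- abs(pmz - peaks$mz[lo])
  dHi <- abs(peaks$mz[hi] - pmz)
  # ties at equal distance resolve to the lower-m/z peak
  pick <- ifelse(dHi < dLo, hi, lo)
  dist <- pmin(dLo, dHi)
  ok <- dist <= settings@toleranceMz &
    peaks$intensity[pick] >= settings@intensityFloor
  if (any(duplicated(pick[ok]))) {
    shared <- pick[ok][duplicated(pick[ok])]
    message(sprintf("peak(s) at m/z %s matched by multiple predictions",
                    paste(sprintf("%.4f", unique(peaks$mz[shared])),
                          collapse = ", ")))
  }
  setNames(peaks$intensity[pick[ok]], predicted$label[ok])
}

.emptyIdentifications <- function() {
  data.frame(species = character(), lipidClass = character(),
             level = character(), sumCarbons = integer(),
             sumDoubleBonds = integer(), step = integer(),
             polarity = character(), internalStandard = logical(),
             evidence = I(list()), stringsAsFactors = FALSE)
}

.identRow <- function(species, lipidClass, level, sumCarbons, sumDoubleBonds,
                      step, polarity, internalStandard, evidence) {
  data.frame(species = species, lipidClass = lipidClass, level = level,
             sumCarbons = as.integer(sumCarbons),
             sumDoubleBonds = as.integer(sumDoubleBonds),
             step = as.integer(step), polarity = polarity,
             internalStandard = internalStandard,
             evidence = I(list(evidence)), stringsAsFactors = FALSE)
}

# canonical molecular species string: moieties ordered by (carbons, db) so
# differently written equivalents (e.g. spike sheets) compare equal
.canonicalMolecular <- function(ann) {
  if (ann@level != "molecular" || ann@lipidClass == "SM")
    return(formatAnnotation(ann))
  m <- ann@moieties[order(ann@moieties$carbons, ann@moieties$doubleBonds), ]
  paste(ann@lipidClass,
        paste(sprintf("%d:%d", m$carbons, m$doubleBonds), collapse = "-"))
}

# spike-sheet lookup tables: molecular species strings and per-class sum keys
.spikeLookup <- function(spikes) {
  if (is.null(spikes) || nrow(spikes) == 0)
    return(list(molecular = character(), sums = character()))
  anns <- lapply(spikes$annotation, parseAnnotation)
  mol <- vapply(anns, .canonicalMolecular, "")
  sums <- vapply(anns, function(a)
    paste(a@lipidClass, a@sumCarbons, a@sumDoubleBonds), "")
  list(molecular = mol, sums = sums)
}

#' Build the identification search space
#'
#' Enumerates TAG sum compositions reachable as triples from the TAG acyl
#' pool (with the acyl-pair achievability table used to restrict
#' neutral-loss evidence to chemically consistent moieties), molecular
#' glycerophospholipid candidates as acyl pairs, and sum-level PC/SM
#' candidates for the positive-mode headgroup route. Spike-sheet species
#' are always included and marked `targeted` (their composition is known,
#' so they bypass the minimum-evidence threshold).
#'
#' @param tagPool,gplPool Fatty acyl pools (see [tagFaPool()],
#'   [gplFaPool()]).
#' @param classes Lipid classes to search.
#' @param mzRange Precursor m/z range (default the 400-1000 acquisition
#'   window).
#' @param spikes Optional spike sheet data.frame.
#' @param lcb Long-chain base (carbons, double bonds) used for SM sums.
#' @return [CandidateSet-class] object.
#' @export
candidateSet <- function(tagPool = tagFaPool(), gplPool = gplFaPool(),
                         classes = c("TAG", "PC", "PE", "PS", "PI", "SM"),
                         mzRange = c(400, 1000), spikes = NULL,
                         lcb = c(18L, 1L)) {
  spk <- if (!is.null(spikes) && nrow(spikes))
    lapply(spikes$annotation, parseAnnotation) else list()

  ## pair achievability over the TAG pool, indexed [carbons, doubleBonds + 1]
  maxC <- 2L * max(tagPool$carbons)
  maxD <- 2L * max(tagPool$doubleBonds)
  pairTable <- matrix(FALSE, nrow = maxC, ncol = maxD + 1L)
  pc <- outer(tagPool$carbons, tagPool$carbons, "+")
  pd <- outer(tagPool$doubleBonds, tagPool$doubleBonds, "+")
  pairTable[cbind(as.vector(pc), as.vector(pd) + 1L)] <- TRUE

  ## TAG sum compositions achievable as pool triples
  tagSums <- .emptyTagSums <- data.frame(
    species = character(), sumCarbons = integer(), sumDoubleBonds = integer(),
    mz = numeric(), step = integer(), targeted = logical())
  if ("TAG" %in% classes && nrow(tagPool)) {
    tc <- as.vector(outer(tagPool$carbons, as.vector(pc), "+"))
    td <- as.vector(outer(tagPool$doubleBonds, as.vector(pd), "+"))
    key <- !duplicated(paste(tc, td))
    sums <- data.frame(sumCarbons = tc[key], sumDoubleBonds = td[key])
    ## spiked TAG species may fall outside the pool triples
    for (a in spk) if (a@lipidClass == "TAG")
      sums <- rbind(sums, data.frame(sumCarbons = a@sumCarbons,
                                     sumDoubleBonds = a@sumDoubleBonds))
    sums <- sums[!duplicated(paste(sums$sumCarbons, sums$sumDoubleBonds)), ]
    mz <- vapply(seq_len(nrow(sums)), function(k)
      monoisotopicMz(elementalComposition(
        .newAnnotation("TAG", "sum", sums$sumCarbons[k],
                       sums$sumDoubleBonds[k])), "+NH4"), 0)
    keep <- mz >= mzRange[1] & mz <= mzRange[2]
    sums <- sums[keep, , drop = FALSE]; mz <- mz[keep]
    spkSums <- vapply(spk, function(a)
      if (a@lipidClass == "TAG") paste(a@sumCarbons, a@sumDoubleBonds) else "",
      "")
    tagSums <- data.frame(
      species = sprintf("TAG %d:%d", sums$sumCarbons, sums$sumDoubleBonds),
      sumCarbons = sums$sumCarbons, sumDoubleBonds = sums$sumDoubleBonds,
      mz = mz, step = as.integer(floor(mz + 0.5)),
      targeted = paste(sums$sumCarbons, sums$sumDoubleBonds) %in% spkSums)
  }

  ## molecular glycerophospholipid candidates
  gplClasses <- intersect(classes, .GPL_CLASSES)
  gpl <- enumerateCandidates(gplPool, gplClasses, mzRange)
  if (nrow(gpl) == 0)
    gpl <- data.frame(species = character(), lipidClass = character(),
                      adduct = character(), polarity = character(),
                      mz = numeric())
  for (a in spk) if (a@lipidClass %in% gplClasses) {
    sp <- .canonicalMolecular(a)
    if (!sp %in% gpl$species) {
      adduct <- .classAdduct(a@lipidClass, "-")
      gpl <- rbind(gpl, data.frame(
        species = sp, lipidClass = a@lipidClass, adduct = adduct,
        polarity = "-",
        mz = monoisotopicMz(elementalComposition(a), adduct)))
    }
  }
  gpl$step <- if (nrow(gpl)) as.integer(floor(gpl$mz + 0.5)) else integer()
  spkGpl <- vapply(spk, .canonicalMolecular, "")[
    vapply(spk, function(a) a@lipidClass %in% gplClasses, TRUE)]
  gpl$targeted <- gpl$species %in% spkGpl

  ## sum-level PC / SM candidates for the headgroup route
  hg <- data.frame(species = character(), lipidClass = character(),
                   sumCarbons = integer(), sumDoubleBonds = integer(),
                   mz = numeric(), step = integer(), targeted = logical())
  hgAdd <- function(df, cls, sc, sd, targeted) {
    key <- paste(cls, sc, sd)
    have <- paste(df$lipidClass, df$sumCarbons, df$sumDoubleBonds)
    fresh <- !key %in% have
    if (!any(fresh)) return(df)
    sc <- sc[fresh]; sd <- sd[fresh]
    ann <- lapply(seq_along(sc), function(k)
      .newAnnotation(cls, "sum", sc[k], sd[k],
                     if (cls == "SM") 2L else 0L))
    mz <- vapply(ann, function(a)
      monoisotopicMz(elementalComposition(a), "+H"), 0)
    keep <- mz >= mzRange[1] & mz <= mzRange[2]
    if (!any(keep)) return(df)
    rbind(df, data.frame(
      species = vapply(ann[keep], formatAnnotation, ""),
      lipidClass = cls, sumCarbons = sc[keep], sumDoubleBonds = sd[keep],
      mz = mz[keep], step = as.integer(floor(mz[keep] + 0.5)),
      targeted = targeted))
  }
  if ("PC" %in% classes && nrow(gplPool)) {
    ij <- which(upper.tri(diag(nrow(gplPool)), diag = TRUE), arr.ind = TRUE)
    sc <- gplPool$carbons[ij[, 1]] + gplPool$carbons[ij[, 2]]
    sd <- gplPool$doubleBonds[ij[, 1]] + gplPool$doubleBonds[ij[, 2]]
    key <- !duplicated(paste(sc, sd))
    hg <- hgAdd(hg, "PC", sc[key], sd[key], FALSE)
  }
  if ("SM" %in% classes && nrow(gplPool)) {
    hg <- hgAdd(hg, "SM", lcb[1] + gplPool$carbons,
                lcb[2] + gplPool$doubleBonds, FALSE)
  }
  for (a in spk) if (a@lipidClass %in% c("PC", "SM")) {
    key <- paste(a@lipidClass, a@sumCarbons, a@sumDoubleBonds)
    have <- paste(hg$lipidClass, hg$sumCarbons, hg$sumDoubleBonds)
    if (key %in% have) hg$targeted[have == key] <- TRUE
    else hg <- hgAdd(hg, a@lipidClass, a@sumCarbons, a@sumDoubleBonds, TRUE)
  }

  rownames(tagSums) <- rownames(gpl) <- rownames(hg) <- NULL
  new("CandidateSet", tagSums = tagSums, gplSpecies = gpl,
      headgroupSpecies = hg, tagPool = tagPool, gplPool = gplPool,
      pairTable = pairTable, mzRange = mzRange)
}

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf(paste0("CandidateSet: %d TAG sum compositions, %d molecular ",
                     "glycerophospholipids, %d PC/SM sum species ",
                     "(m/z %g-%g)\n"),
              nrow(object@tagSums), nrow(object@gplSpecies),
              nrow(object@headgroupSpecies), object@mzRange[1],
              object@mzRange[2]))
  invisible(NULL)
})

# acyls from the TAG pool that can be completed to (sumC, sumD) by a pool pair
.consistentFas <- function(candidates, sumCarbons, sumDoubleBonds) {
  pool <- candidates@tagPool
  remC <- sumCarbons - pool$carbons
  remD <- sumDoubleBonds - pool$doubleBonds
  ok <- remC >= 1L & remD >= 0L & remC <= nrow(candidates@pairTable) &
    remD <= ncol(candidates@pairTable) - 1L
  ok[ok] <- candidates@pairTable[cbind(remC[ok], remD[ok] + 1L)]
  pool[ok, , drop = FALSE]
}

#' Identify TAG sum compositions from neutral-loss evidence
#'
#' For every candidate TAG sum composition whose ammoniated precursor m/z
#' falls in an acquired positive-mode step window, neutral-loss fragments
#' are predicted for all chemically consistent acyl moieties (those that a
#' pool acyl pair can complete to the sum composition) and matched in that
#' step's spectrum. A composition is accepted when at least
#' `minTagFragments` distinct neutral losses match; spiked standards are
#' exempt from the threshold.
#'
#' @param experiment [MsMsExperiment-class].
#' @param candidates [CandidateSet-class].
#' @param settings [MatchSettings-class].
#' @return Identification data.frame (one row per accepted species) with
#'   an `evidence` list-column of named fragment intensities keyed by FA.
#' @export
identifyTag <- function(experiment, candidates, settings = matchSettings()) {
  stopifnot(is(experiment, "MsMsExperiment"), is(candidates, "CandidateSet"))
  spk <- .spikeLookup(experiment@spikeSheet)
  nh3 <- monoisotopicMass(.AMMONIA)
  out <- list()
  cand <- candidates@tagSums
  if (nrow(cand) == 0) return(.emptyIdentifications())
  keys <- .spectrumKeys(experiment)
  posSteps <- keys$step[keys$polarity == "+"]
  cand <- cand[cand$step %in% posSteps, , drop = FALSE]
  for (k in seq_len(nrow(cand))) {
    spec <- getSpectrum(experiment, cand$step[k], "+")
    fas <- .consistentFas(candidates, cand$sumCarbons[k],
                          cand$sumDoubleBonds[k])
    if (nrow(fas) == 0) next
    faMass <- monoisotopicMass(elementalFormula(O = 2)) +
      fas$carbons * monoisotopicMass(elementalFormula(C = 1, H = 2)) -
      fas$doubleBonds * monoisotopicMass(elementalFormula(H = 2))
    predicted <- data.frame(label = .faLabel(fas$carbons, fas$doubleBonds),
                            fragmentMz = cand$mz[k] - faMass - nh3)
    ev <- matchFragments(spec, predicted, settings)
    minReq <- if (cand$targeted[k]) 1L else settings@minTagFragments
    if (length(ev) < minReq) next
    isStd <- paste("TAG", cand$sumCarbons[k], cand$sumDoubleBonds[k]) %in%
      spk$sums
    out[[length(out) + 1L]] <- .identRow(
      cand$species[k], "TAG", "sum", cand$sumCarbons[k],
      cand$sumDoubleBonds[k], cand$step[k], "+", isStd, ev)
  }
  if (length(out) == 0) return(.emptyIdentifications())
  do.call(rbind, out)
}

#' Identify molecular glycerophospholipid species from FA anion pairs
#'
#' A molecular candidate FA1-FA2 is accepted iff every distinct FA anion
#' is matched in the spectrum of the step containing its negative-mode
#' precursor (the candidate's acyl sum equals the precursor sum
#' composition by construction). PS additionally requires the neutral
#' loss of the serine headgroup (precursor m/z - 87.0320).
#'
#' @inheritParams identifyTag
#' @return Identification data.frame; evidence is keyed by FA (plus
#'   `"NL serine"` for PS).
#' @export
identifyGpl <- function(experiment, candidates, settings = matchSettings()) {
  stopifnot(is(experiment, "MsMsExperiment"), is(candidates, "CandidateSet"))
  spk <- .spikeLookup(experiment@spikeSheet)
  cand <- candidates@gplSpecies
  if (nrow(cand) == 0) return(.emptyIdentifications())
  keys <- .spectrumKeys(experiment)
  negSteps <- keys$step[keys$polarity == "-"]
  cand <- cand[cand$step %in% negSteps, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(cand))) {
    spec <- getSpectrum(experiment, cand$step[k], "-")
    ann <- parseAnnotation(cand$species[k])
    predicted <- gplFragments(ann, "-")
    ev <- matchFragments(spec, predicted, settings)
    if (!all(predicted$label %in% names(ev))) next
    out[[length(out) + 1L]] <- .identRow(
      cand$species[k], cand$lipidClass[k], "molecular", ann@sumCarbons,
      ann@sumDoubleBonds, cand$step[k], "-",
      cand$species[k] %in% spk$molecular, ev)
  }
  if (length(out) == 0) return(.emptyIdentifications())
  .dropSubsetExplanations(do.call(rbind, out))
}

# parsimony arbitration for exactly co-isolating candidates (e.g. the
# formate adduct of a PC species is isobaric with the deprotonated PS
# species three carbons up and one double bond down): a candidate whose
# matched fragments are a strict subset of a co-identified candidate's
# fragments in the same spectrum adds no evidence of its own and is dropped
.dropSubsetExplanations <- function(ids) {
  drop <- logical(nrow(ids))
  for (st in unique(ids$step)) {
    rows <- which(ids$step == st & !drop)
    if (length(rows) < 2) next
    labs <- lapply(ids$evidence[rows], names)
    for (a in seq_along(rows)) for (b in seq_along(rows)) {
      if (a == b) next
      if (all(labs[[a]] %in% labs[[b]]) && !all(labs[[b]] %in% labs[[a]])) {
        drop[rows[a]] <- TRUE
        message(sprintf(
          "step %d: %s explained by %s's fragments alone; dropped",
          st, ids$species[rows[a]], ids$species[rows[b]]))
      }
    }
  }
  out <- ids[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify sum-level PC and SM species from the phosphocholine headgroup
#'
#' Every positive-mode step showing the m/z 184.0733 phosphocholine
#' fragment is searched for PC/SM sum candidates whose protonated
#' precursor falls in that step's isolation window. Because both classes
#' share the headgroup fragment, a candidate is only accepted when its
#' residual (unfragmented) precursor ion is matched at its exact m/z,
#' which resolves isobaric PC/SM ambiguity within a window. Steps with a
#' headgroup peak but no confirmed candidate are logged.
#'
#' @inheritParams identifyTag
#' @return Identification data.frame; evidence holds the `headgroup` and
#'   `precursor` intensities.
#' @export
identifyHeadgroupSpecies <- function(experiment, candidates,
                                     settings = matchSettings()) {
  stopifnot(is(experiment, "MsMsExperiment"), is(candidates, "CandidateSet"))
  spk <- .spikeLookup(experiment@spikeSheet)
  cand <- candidates@headgroupSpecies
  if (nrow(cand) == 0) return(.emptyIdentifications())
  hgMz <- .phosphocholineIonMz()
  keys <- .spectrumKeys(experiment)
  posSteps <- keys$step[keys$polarity == "+"]
  out <- list()
  for (st in posSteps) {
    spec <- getSpectrum(experiment, st, "+")
    hgEv <- matchFragments(spec, data.frame(label = "headgroup",
                                            fragmentMz = hgMz), settings)
    if (length(hgEv) == 0) next
    inWin <- cand[cand$step == st, , drop = FALSE]
    confirmed <- 0L
    for (k in seq_len(nrow(inWin))) {
      pEv <- matchFragments(spec, data.frame(label = "precursor",
                                             fragmentMz = inWin$mz[k]),
                            settings)
      # spiked standards are targeted lookups of known composition: the
      # headgroup fragment in their own precursor step suffices
      if (length(pEv) == 0 && !inWin$targeted[k]) next
      confirmed <- confirmed + 1L
      isStd <- paste(inWin$lipidClass[k], inWin$sumCarbons[k],
                     inWin$sumDoubleBonds[k]) %in% spk$sums
      out[[length(out) + 1L]] <- .identRow(
        inWin$species[k], inWin$lipidClass[k], "sum", inWin$sumCarbons[k],
        inWin$sumDoubleBonds[k], st, "+", isStd,
        c(hgEv, pEv))
    }
    if (confirmed == 0L)
      message(sprintf("step %d: headgroup fragment present but no PC/SM candidate confirmed",
                      st))
  }
  if (length(out) == 0) return(.emptyIdentifications())
  do.call(rbind, out)
}

#' Run all identification routes and merge the results
#'
#' Runs [identifyTag()], [identifyGpl()] and [identifyHeadgroupSpecies()]
#' and merges: a sum-level PC identification is dropped when a molecular
#' PC identification with the same sum composition exists (the molecular
#' level is preferred for species seen in both modes).
#'
#' @inheritParams identifyTag
#' @return Combined identification data.frame.
#' @export
identifyLipids <- function(experiment, candidates,
                           settings = matchSettings()) {
  ids <- rbind(identifyTag(experiment, candidates, settings),
               identifyGpl(experiment, candidates, settings),
               identifyHeadgroupSpecies(experiment, candidates, settings))
  mergeIdentifications(ids)
}

#' @describeIn identifyLipids Merge rule on an identification table: drop
#'   sum-level PC rows whose sum composition is covered at molecular level.
#' @param identifications Identification data.frame.
#' @export
mergeIdentifications <- function(identifications) {
  if (nrow(identifications) == 0) return(identifications)
  pcMol <- identifications$lipidClass == "PC" &
    identifications$level == "molecular"
  covered <- unique(paste(identifications$sumCarbons[pcMol],
                          identifications$sumDoubleBonds[pcMol]))
  drop <- identifications$lipidClass == "PC" &
    identifications$level == "sum" &
    paste(identifications$sumCarbons,
          identifications$sumDoubleBonds) %in% covered
  out <- identifications[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export identifications as TSV
#'
#' Evidence maps are flattened to `label=intensity` pairs separated by
#' `;`.
#'
#' @param identifications Identification data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeIdentifications <- function(identifications, path) {
  flat <- identifications
  flat$evidence <- vapply(identifications$evidence, function(ev)
    paste(sprintf("%s=%.1f", names(ev), ev), collapse = ";"), "")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
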