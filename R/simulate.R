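#' @include gc.R
NULL

# evaluate expr under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a noise model for the simulator
#'
#' @param intensityCv Relative intensity coefficient of variation
#'   (multiplicative log-normal noise per peak).
#' @param mzJitterPpm Gaussian m/z jitter scale in ppm, per peak.
#' @param baselineRate Expected random baseline peaks per spectrum
#'   (Poisson).
#' @param baselineIntensity Mean intensity of baseline peaks
#'   (exponential), in the same arbitrary units as signal peaks.
#' @param seed Integer seed; identical seeds reproduce the experiment
#'   byte-for-byte.
#' @return [NoiseModel-class] object.
#' @export
noiseModel <- function(intensityCv = 0.05, mzJitterPpm = 5,
                       baselineRate = 3, baselineIntensity = 5,
                       seed = 1L) {
  new("NoiseModel", intensityCv = intensityCv, mzJitterPpm = mzJitterPpm,
      baselineRate = baselineRate, baselineIntensity = baselineIntensity,
      seed = as.integer(seed))
}

#' @rdname noiseModel
#' @export
zeroNoise <- function(seed = 1L) {
  noiseModel(intensityCv = 0, mzJitterPpm = 0, baselineRate = 0,
             baselineIntensity = 0, seed = seed)
}

#' The packaged internal-standard spike mixture
#'
#' One molecular-level standard per lipid class with the spiked amounts
#' used for milk extracts: 93 pmol TAG 17:1-17:1-17:1, 94 pmol
#' PE 17:0-14:1, 94 pmol PS 17:0-14:1, 96 pmol PC 17:0-14:1, 98 pmol
#' PI 17:0-14:1 and 100 pmol SM 18:1;2/17:0. Odd-chain moieties keep the
#' standards free of endogenous interference.
#'
#' @return data.frame with columns `annotation`, `pmol`.
#' @export
defaultSpikeSheet <- function() {
  data.frame(
    annotation = c("TAG 17:1-17:1-17:1", "PE 17:0-14:1", "PS 17:0-14:1",
                   "PC 17:0-14:1", "PI 17:0-14:1", "SM 18:1;2/17:0"),
    pmol = c(93, 94, 94, 96, 98, 100),
    stringsAsFactors = FALSE)
}

.HUMAN_TAG <- data.frame(
  species = c("TAG 16:0-18:1-18:1", "TAG 16:0-18:0-18:2",
              "TAG 16:0-18:1-18:2", "TAG 16:0-16:0-18:1",
              "TAG 16:0-16:0-18:2", "TAG 18:1-18:1-18:1",
              "TAG 14:0-16:0-18:1", "TAG 14:0-16:0-16:0",
              "TAG 10:0-16:0-18:1", "TAG 18:0-18:1-18:2"),
  pmol = 20 * c(30, 8, 14, 12, 6, 12, 8, 2, 4, 3),
  stringsAsFactors = FALSE)

.COW_TAG <- data.frame(
  species = c("TAG 4:0-16:0-18:1", "TAG 4:0-16:0-16:0",
              "TAG 6:0-16:0-18:0", "TAG 8:0-14:0-16:0",
              "TAG 16:0-16:0-18:1", "TAG 16:0-18:1-18:1",
              "TAG 14:0-16:0-18:1", "TAG 14:0-16:0-16:0",
              "TAG 16:0-18:0-18:1", "TAG 16:0-18:1-18:2"),
  pmol = 21 * c(15, 8, 5, 5, 12, 20, 12, 2, 6, 7),
  stringsAsFactors = FALSE)

.LACPRODAN_GPL <- data.frame(
  species = c(
    # PE, 700 pmol: dominated by PE 18:1-18:1 (34 mol% of class)
    "PE 18:1-18:1", "PE 16:0-18:1", "PE 18:0-18:1", "PE 18:1-18:2",
    "PE 16:0-18:2", "PE 18:0-20:4", "PE 18:0-22:5",
    # PC, 360 pmol: dominated by PC 16:0-18:1 (23 mol% of class)
    "PC 16:0-18:1", "PC 16:0-16:0", "PC 16:0-18:2", "PC 18:0-18:1",
    "PC 18:1-18:2", "PC 14:0-16:0", "PC 18:0-18:2",
    # PS, 180 pmol: dominated by PS 18:0-18:1 (38 mol% of class)
    "PS 18:0-18:1", "PS 18:0-18:2", "PS 16:0-18:1", "PS 18:0-20:4",
    "PS 18:0-22:5",
    # PI, 100 pmol: dominated by PI 18:0-18:1 (39 mol% of class)
    "PI 18:0-18:1", "PI 16:0-18:1", "PI 18:0-18:2", "PI 18:0-20:4",
    # SM, 160 pmol (sum compositions 34:1, 36:1, 34:2, 38:2)
    "SM 18:1;2/16:0", "SM 18:1;2/18:0", "SM 18:1;2/16:1",
    "SM 18:1;2/20:1"),
  pmol = c(238, 140, 120, 90, 60, 30, 22,
           82.8, 60, 55, 50, 40, 35, 37.2,
           68.4, 40, 35, 20, 16.6,
           39, 25, 21, 15,
           88, 40, 20, 12),
  stringsAsFactors = FALSE)

#' Ground-truth milk-like lipidome fixtures
#'
#' Deterministic compositions emulating the study samples: `human1` and
#' `human2` are TAG-dominated (about 97.8 mol% TAG) with long-chain
#' unsaturated TAG species rich in FA 16:0/18:1/18:2 and only traces of
#' short-chain moieties; `human2` differs from `human1` by a seeded
#' +/-10 percent perturbation of TAG abundances mimicking
#' inter-individual variation. `cow` is TAG-dominated with a short-chain
#' arm (butyryl/caproyl/caprylyl moieties on TAG 36:0 / 38:0 / 38:1-like
#' species, about 12 percent of TAG acyl positions) and a more saturated
#' profile. `lacprodan` is phospholipid-enriched with class fractions
#' 25/35/18/8/9/5 mol% (TAG/PE/PC/SM/PS/PI) and glycerophospholipid
#' classes dominated by PC 16:0-18:1, PE 18:1-18:1, PI 18:0-18:1 and
#' PS 18:0-18:1.
#'
#' @param name One of `"human1"`, `"human2"`, `"cow"`, `"lacprodan"`.
#' @return [GroundTruthComposition-class] object.
#' @export
makeFixture <- function(name = c("human1", "human2", "cow", "lacprodan")) {
  name <- match.arg(name)
  minorGpl <- function(pc, pe, sm) {
    data.frame(species = c("PC 16:0-18:1", "PE 18:1-18:1", "SM 18:1;2/16:0"),
               pmol = c(pc, pe, sm), stringsAsFactors = FALSE)
  }
  comp <- switch(name,
    human1 = rbind(.HUMAN_TAG, minorGpl(22, 14, 8.5)),
    human2 = {
      tag <- .HUMAN_TAG
      tag$pmol <- .withSeed(20150224,
                            tag$pmol * (1 + 0.1 * runif(nrow(tag), -1, 1)))
      rbind(tag, minorGpl(20, 15, 9))
    },
    cow = rbind(.COW_TAG, minorGpl(12, 10, 8)),
    lacprodan = {
      tag <- .COW_TAG
      tag$pmol <- tag$pmol / sum(tag$pmol) * 500  # 25 mol% of 2000
      rbind(tag, .LACPRODAN_GPL)
    })
  rownames(comp) <- NULL
  new("GroundTruthComposition", composition = comp, profileName = name,
      responseFactors = c(TAG = 1, PC = 1, PE = 1, PS = 1, PI = 1, SM = 1))
}

setMethod("show", "GroundTruthComposition", function(object) {
  cls <- vapply(object@composition$species, function(s)
    lipidClass(parseAnnotation(s)), "")
  pct <- round(100 * tapply(object@composition$pmol, cls, sum) /
                 sum(object@composition$pmol), 1)
  cat(sprintf("GroundTruthComposition '%s': %d species, %.0f pmol total\n",
              object@profileName, nrow(object@composition),
              sum(object@composition$pmol)))
  cat("  class mol%:", paste(sprintf("%s %.1f", names(pct), pct),
                             collapse = ", "), "\n")
  invisible(NULL)
})

# per-species fragment template: where each ion species puts intensity.
# Total signal per polarity route is proportional to pmol; it is divided
# over the acyl positions (so neutral-loss / anion shares reflect moiety
# stoichiometry), with confirmation fragments (PS serine loss, PC/SM
# residual precursor) carrying a fixed 1/2 share.
.fragmentTemplate <- function(ann) {
  cls <- ann@lipidClass
  out <- list()
  if (cls == "TAG") {
    fr <- tagNeutralLossFragments(ann)
    out[[1]] <- data.frame(polarity = "+", precursorMz = fr$precursorMz,
                           label = fr$fa, mz = fr$fragmentMz,
                           share = fr$multiplicity / 3)
  } else if (cls %in% .GPL_CLASSES) {
    fr <- gplFragments(ann, "-")
    anion <- fr$label != "NL serine"
    share <- ifelse(anion, fr$multiplicity / 2, 1 / 2)
    out[[1]] <- data.frame(polarity = "-", precursorMz = fr$precursorMz,
                           label = fr$label, mz = fr$fragmentMz,
                           share = share)
    if (cls == "PC") {
      frp <- gplFragments(ann, "+")
      out[[2]] <- data.frame(polarity = "+", precursorMz = frp$precursorMz,
                             label = frp$label, mz = frp$fragmentMz,
                             share = 1 / 2)
    }
  } else if (cls == "SM") {
    fr <- gplFragments(ann, "+")
    out[[1]] <- data.frame(polarity = "+", precursorMz = fr$precursorMz,
                           label = fr$label, mz = fr$fragmentMz,
                           share = 1 / 2)
  } else {
    stop(sprintf("cannot simulate class '%s'", cls), call. = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a precursor-stepped MS/MS acquisition from a known lipidome
#'
#' Places the predicted structure-specific fragments of every composition
#' and spike species into the spectrum of its precursor's isolation step
#' (positive and negative mode as applicable), with total intensity
#' proportional to pmol times the class response factor, divided over the
#' acyl positions. Co-isolated species superimpose additively. Gaussian
#' ppm m/z jitter, multiplicative log-normal intensity noise and random
#' baseline peaks are then applied; everything is deterministic under the
#' noise model's seed.
#'
#' @param composition [GroundTruthComposition-class].
#' @param spikes Spike sheet data.frame (default [defaultSpikeSheet()]).
#' @param noise [NoiseModel-class] (default [zeroNoise()]).
#' @param intensityPerPmol Arbitrary-unit signal per pmol (default 10).
#' @return List with `experiment` ([MsMsExperiment-class]) and
#'   `groundTruth`, a sidecar data.frame (species, pmol, lipidClass,
#'   included flag; species whose precursors fall outside the 400-1000
#'   acquisition range are excluded with a warning).
#' @export
simulateMsmsAll <- function(composition, spikes = defaultSpikeSheet(),
                            noise = zeroNoise(), intensityPerPmol = 10) {
  stopifnot(is(composition, "GroundTruthComposition"),
            is(noise, "NoiseModel"))
  validObject(composition)
  rows <- rbind(
    data.frame(species = composition@composition$species,
               pmol = composition@composition$pmol, spike = FALSE),
    data.frame(species = spikes$annotation, pmol = spikes$pmol,
               spike = rep(TRUE, nrow(spikes))))
  rf <- composition@responseFactors

  peakAcc <- list()   # key "step pol" -> list of data.frames
  truth <- list()
  for (k in seq_len(nrow(rows))) {
    ann <- parseAnnotation(rows$species[k])
    cls <- ann@lipidClass
    templ <- .fragmentTemplate(ann)
    total <- rows$pmol[k] * intensityPerPmol *
      (if (cls %in% names(rf)) rf[[cls]] else 1)
    included <- FALSE
    for (pol in unique(templ$polarity)) {
      tp <- templ[templ$polarity == pol, , drop = FALSE]
      pmz <- tp$precursorMz[1]
      if (pmz < 400 || pmz > 1000) next
      included <- TRUE
      step <- stepOf(pmz)
      key <- paste(step, pol)
      peakAcc[[key]] <- c(peakAcc[[key]], list(
        data.frame(mz = tp$mz, intensity = total * tp$share)))
    }
    if (!included)
      warning(sprintf("species '%s' excluded: precursor outside 400-1000",
                      rows$species[k]), call. = FALSE)
    if (!rows$spike[k])
      truth[[length(truth) + 1L]] <- data.frame(
        species = rows$species[k], pmol = rows$pmol[k], lipidClass = cls,
        included = included, stringsAsFactors = FALSE)
  }

  spectraList <- .withSeed(noise@seed, {
    lapply(sort(names(peakAcc)), function(key) {
      parts <- strsplit(key, " ", fixed = TRUE)[[1]]
      peaks <- do.call(rbind, peakAcc[[key]])
      if (noise@mzJitterPpm > 0)
        peaks$mz <- peaks$mz *
          (1 + rnorm(nrow(peaks)) * noise@mzJitterPpm * 1e-6)
      if (noise@intensityCv > 0) {
        sdlog <- sqrt(log(1 + noise@intensityCv^2))
        peaks$intensity <- peaks$intensity *
          exp(rnorm(nrow(peaks), -sdlog^2 / 2, sdlog))
      }
      if (noise@baselineRate > 0) {
        nb <- rpois(1, noise@baselineRate)
        if (nb > 0)
          peaks <- rbind(peaks, data.frame(
            mz = runif(nb, 150, 1000),
            intensity = stats::rexp(nb, 1 / noise@baselineIntensity)))
      }
      peaks <- peaks[peaks$mz >= 150 & peaks$mz <= 1000, , drop = FALSE]
      peaks <- peaks[order(peaks$mz), , drop = FALSE]
      msmsSpectrum(as.integer(parts[1]), parts[2], peaks)
    })
  })

  experiment <- msmsExperiment(
    sampleId = composition@profileName,
    spectra = spectraList,
    spikeSheet = spikes[, c("annotation", "pmol")],
    metadata = list(collisionEnergyEv = 45, seed = noise@seed,
                    intensityCv = noise@intensityCv,
                    mzJitterPpm = noise@mzJitterPpm,
                    intensityPerPmol = intensityPerPmol))
  list(experiment = experiment,
       groundTruth = do.call(rbind, truth))
}

#' Aggregate a ground-truth composition to identifiable species
#'
#' Maps molecular ground-truth species to the annotation level the
#' identification reports: TAG and SM collapse to sum compositions
#' (isomeric molecular species pool their amounts), glycerophospholipids
#' stay molecular with canonically ordered moieties.
#'
#' @param composition [GroundTruthComposition-class] or its composition
#'   data.frame.
#' @return data.frame with columns `species`, `lipidClass`, `pmol`.
#' @export
groundTruthSpecies <- function(composition) {
  comp <- if (is(composition, "GroundTruthComposition"))
    composition@composition else composition
  mapped <- vapply(comp$species, function(s) {
    a <- parseAnnotation(s)
    if (a@lipidClass == "TAG")
      sprintf("TAG %d:%d", a@sumCarbons, a@sumDoubleBonds)
    else if (a@lipidClass == "SM")
      sprintf("SM %d:%d;2", a@sumCarbons, a@sumDoubleBonds)
    else {
      m <- a@moieties[order(a@moieties$carbons, a@moieties$doubleBonds), ]
      paste(a@lipidClass, paste(sprintf("%d:%d", m$carbons, m$doubleBonds),
                                collapse = "-"))
    }
  }, "")
  cls <- vapply(comp$species, function(s) lipidClass(parseAnnotation(s)), "")
  agg <- stats::aggregate(list(pmol = comp$pmol),
                          by = list(species = mapped, lipidClass = cls), sum)
  agg[order(agg$lipidClass, -agg$pmol), c("species", "lipidClass", "pmol")]
}

#' Simulate a GC-FAME peak table from a known lipidome
#'
#' Total FA amounts are accumulated from the acyl moieties of every
#' species (each esterified/amidated position contributes its species'
#' pmol; long-chain bases are not fatty acids and do not contribute).
#' FAs with fewer than `minCarbons` carbons are omitted -- the GC blind
#' spot for volatile short-chain FAMEs. Amounts are converted to areas by
#' inverting each FAME's calibration curve; retention times receive
#' uniform jitter within `+/- rtJitter` minutes and areas multiplicative
#' log-normal noise of CV `areaCv`.
#'
#' @param composition [GroundTruthComposition-class].
#' @param curves Named list of calibration curves covering every library
#'   FAME (default [defaultCalibration()]).
#' @param rtLibrary FAME retention-time library (default
#'   [defaultRtLibrary()]); an FA (>= `minCarbons`) absent from it is an
#'   error.
#' @param rtJitter Maximum retention-time jitter in minutes.
#' @param areaCv Relative area noise.
#' @param seed Integer seed (deterministic output).
#' @param minCarbons GC lower carbon limit (default 10).
#' @return data.frame with columns `rt_min`, `area`, sorted by retention
#'   time.
#' @export
simulateGc <- function(composition, curves = defaultCalibration(),
                       rtLibrary = defaultRtLibrary(), rtJitter = 0.02,
                       areaCv = 0, seed = 1L, minCarbons = 10L) {
  stopifnot(is(composition, "GroundTruthComposition"))
  comp <- composition@composition
  amounts <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(comp))) {
    a <- parseAnnotation(comp$species[k])
    m <- a@moieties[!a@moieties$isLcb, , drop = FALSE]
    for (j in seq_len(nrow(m))) {
      if (m$carbons[j] < minCarbons) next
      key <- sprintf("%d:%d", m$carbons[j], m$doubleBonds[j])
      amounts[[key]] <- (if (is.null(amounts[[key]])) 0 else amounts[[key]]) +
        comp$pmol[k]
    }
  }
  keys <- ls(amounts)
  if (length(keys) == 0)
    return(data.frame(rt_min = numeric(), area = numeric()))
  libKey <- sprintf("%d:%d", rtLibrary$carbons, rtLibrary$doubleBonds)
  missing <- setdiff(keys, libKey)
  if (length(missing))
    stop(sprintf("retention-time library lacks FA(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  rows <- match(keys, libKey)
  amount <- vapply(keys, function(k) amounts[[k]], 0)
  fame <- rtLibrary$fame[rows]
  area <- vapply(seq_along(keys), function(k) {
    cv <- curves[[fame[k]]]
    if (is.null(cv))
      stop(sprintf("no calibration curve for %s", fame[k]), call. = FALSE)
    (amount[k] - cv@intercept) / cv@slope
  }, 0)
  out <- .withSeed(seed, {
    rt <- rtLibrary$rt_min[rows] +
      (if (rtJitter > 0) runif(length(rows), -rtJitter, rtJitter) else 0)
    if (areaCv > 0) {
      sdlog <- sqrt(log(1 + areaCv^2))
      area <- area * exp(rnorm(length(area), -sdlog^2 / 2, sdlog))
    }
    data.frame(rt_min = rt, area = area)
  })
  out <- out[order(out$rt_min), ]
  rownames(out) <- NULL
  out
}
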