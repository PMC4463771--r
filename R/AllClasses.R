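#' @include milkLipidomics-package.R
NULL

.LIPID_CLASSES <- c("TAG", "PC", "PE", "PS", "PI", "SM", "FA")
.GPL_CLASSES <- c("PC", "PE", "PS", "PI")

#' LipidAnnotation: a parsed shorthand lipid name
#'
#' Represents a lipid species either at *sum* level (total acyl carbons and
#' double bonds, e.g. `TAG 52:2`) or at *molecular* level (individual fatty
#' acyl / long-chain base moieties, e.g. `PC 16:0-18:1`,
#' `SM 18:1;2/17:0`). The moiety separator carries no sn-position meaning.
#'
#' @slot lipidClass One of TAG, PC, PE, PS, PI, SM, FA.
#' @slot level `"sum"` or `"molecular"`.
#' @slot sumCarbons,sumDoubleBonds Integer totals over all moieties.
#' @slot sumHydroxyls Integer; number of hydroxyls on the long-chain base
#'   (sphingolipids only, 0 otherwise).
#' @slot moieties data.frame with columns `carbons`, `doubleBonds`,
#'   `hydroxyls`, `isLcb`; zero rows at sum level.
#' @seealso [parseAnnotation()], [formatAnnotation()]
#' @export
setClass("LipidAnnotation",
         representation(lipidClass = "character",
                        level = "character",
                        sumCarbons = "integer",
                        sumDoubleBonds = "integer",
                        sumHydroxyls = "integer",
                        moieties = "data.frame"))

setValidity("LipidAnnotation", function(object) {
  msg <- character()
  if (!object@lipidClass %in% .LIPID_CLASSES)
    msg <- c(msg, sprintf("unknown lipid class '%s'", object@lipidClass))
  if (!object@level %in% c("sum", "molecular"))
    msg <- c(msg, "level must be 'sum' or 'molecular'")
  m <- object@moieties
  if (object@level == "molecular") {
    expected <- switch(object@lipidClass,
                       TAG = 3L, PC = 2L, PE = 2L, PS = 2L, PI = 2L,
                       SM = 2L, FA = 1L)
    if (nrow(m) != expected)
      msg <- c(msg, sprintf("%s molecular annotation needs %d moieties, got %d",
                            object@lipidClass, expected, nrow(m)))
    if (nrow(m) > 0) {
      if (any(m$carbons < 2))
        msg <- c(msg, "moiety carbons must be >= 2")
      if (any(m$doubleBonds < 0 | m$doubleBonds > m$carbons / 2))
        msg <- c(msg, "moiety double bonds must be in [0, carbons/2]")
      if (any(m$hydroxyls < 0))
        msg <- c(msg, "moiety hydroxyls must be >= 0")
      if (object@lipidClass == "SM" && sum(m$isLcb) != 1L)
        msg <- c(msg, "SM molecular annotation needs exactly one LCB")
      if (object@lipidClass != "SM" && any(m$isLcb))
        msg <- c(msg, "only SM carries a long-chain base")
      if (sum(m$carbons) != object@sumCarbons ||
          sum(m$doubleBonds) != object@sumDoubleBonds)
        msg <- c(msg, "sum composition inconsistent with moieties")
    }
  }
  if (object@sumCarbons < 2L || object@sumDoubleBonds < 0L)
    msg <- c(msg, "invalid sum composition")
  if (length(msg)) msg else TRUE
})

#' MsMsSpectrum: one fragment spectrum of a precursor-stepped acquisition
#'
#' @slot precursorStep Integer nominal precursor m/z (400-1000).
#' @slot polarity `"+"` or `"-"`.
#' @slot peaks data.frame with columns `mz` (150-1000, strictly increasing)
#'   and `intensity` (>= 0).
#' @export
setClass("MsMsSpectrum",
         representation(precursorStep = "integer",
                        polarity = "character",
                        peaks = "data.frame"))

setValidity("MsMsSpectrum", function(object) {
  msg <- character()
  if (object@precursorStep < 400L || object@precursorStep > 1000L)
    msg <- c(msg, "precursor step outside acquisition range 400-1000")
  if (!object@polarity %in% c("+", "-"))
    msg <- c(msg, "polarity must be '+' or '-'")
  p <- object@peaks
  if (!all(c("mz", "intensity") %in% names(p)))
    msg <- c(msg, "peaks need columns mz and intensity")
  else {
    if (nrow(p) && (any(p$mz < 150) || any(p$mz > 1000)))
      msg <- c(msg, "peak m/z outside recorded range 150-1000")
    if (nrow(p) && any(p$intensity < 0))
      msg <- c(msg, "negative peak intensity")
    if (nrow(p) > 1 && any(diff(p$mz) <= 0))
      msg <- c(msg, "peaks must be strictly increasing in m/z")
  }
  if (length(msg)) msg else TRUE
})

#' MsMsExperiment: a full precursor-stepped MS/MS acquisition of one sample
#'
#' Holds at most one spectrum per (precursor step, polarity), the internal
#' standard spike sheet (molecular-level annotations with spiked pmol) and
#' free-form acquisition metadata.
#'
#' @slot sampleId Character sample identifier.
#' @slot spectra List of [MsMsSpectrum-class] objects.
#' @slot spikeSheet data.frame with columns `annotation`, `pmol`.
#' @slot metadata Named list (collision energy, dilution, seed, ...).
#' @export
setClass("MsMsExperiment",
         representation(sampleId = "character",
                        spectra = "list",
                        spikeSheet = "data.frame",
                        metadata = "list"))

setValidity("MsMsExperiment", function(object) {
  msg <- character()
  ok <- vapply(object@spectra, is, logical(1), class2 = "MsMsSpectrum")
  if (!all(ok)) msg <- c(msg, "all spectra must be MsMsSpectrum objects")
  else if (length(object@spectra)) {
    keys <- vapply(object@spectra,
                   function(s) paste(s@precursorStep, s@polarity),
                   character(1))
    if (anyDuplicated(keys))
      msg <- c(msg, sprintf("duplicate (step, polarity): %s",
                            paste(unique(keys[duplicated(keys)]),
                                  collapse = ", ")))
  }
  ss <- object@spikeSheet
  if (!all(c("annotation", "pmol") %in% names(ss)))
    msg <- c(msg, "spike sheet needs columns annotation and pmol")
  else if (nrow(ss)) {
    if (any(ss$pmol <= 0)) msg <- c(msg, "spike amounts must be positive")
    for (a in ss$annotation) {
      ann <- tryCatch(parseAnnotation(a), error = function(e) NULL)
      if (is.null(ann) || ann@level != "molecular")
        msg <- c(msg, sprintf("spike '%s' is not a molecular-level annotation", a))
    }
  }
  if (length(msg)) msg else TRUE
})

#' MatchSettings: fragment-matching tolerances and evidence thresholds
#'
#' @slot toleranceMz Absolute m/z matching tolerance (> 0). The default of
#'   0.01 reflects TOF-like mass accuracy.
#' @slot minTagFragments Minimum number of distinct neutral-loss fragments
#'   required to accept a TAG sum composition (spiked standards are looked
#'   up with known composition and are exempt).
#' @slot intensityFloor Matched peaks below this intensity are dropped.
#' @export
setClass("MatchSettings",
         representation(toleranceMz = "numeric",
                        minTagFragments = "integer",
                        intensityFloor = "numeric"))

setValidity("MatchSettings", function(object) {
  msg <- character()
  if (length(object@toleranceMz) != 1 || object@toleranceMz <= 0)
    msg <- c(msg, "toleranceMz must be a single positive number")
  if (object@minTagFragments < 1L)
    msg <- c(msg, "minTagFragments must be >= 1")
  if (object@intensityFloor < 0)
    msg <- c(msg, "intensityFloor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: acquisition noise for the simulator
#'
#' @slot mzJitterPpm Gaussian m/z jitter scale in ppm.
#' @slot intensityCv Relative intensity coefficient of variation
#'   (multiplicative log-normal noise).
#' @slot baselineRate Expected number of random baseline peaks per spectrum
#'   (Poisson).
#' @slot baselineIntensity Mean intensity of baseline peaks (exponential).
#' @slot seed Integer seed; identical seeds give identical experiments.
#' @export
setClass("NoiseModel",
         representation(mzJitterPpm = "numeric",
                        intensityCv = "numeric",
                        baselineRate = "numeric",
                        baselineIntensity = "numeric",
                        seed = "integer"))

setValidity("NoiseModel", function(object) {
  bad <- c(object@mzJitterPpm, object@intensityCv, object@baselineRate,
           object@baselineIntensity) < 0
  if (any(bad)) "noise parameters must be >= 0" else TRUE
})

#' GroundTruthComposition: a known lipidome used for simulation
#'
#' @slot composition data.frame with columns `species` (molecular-level
#'   annotations) and `pmol` (> 0).
#' @slot profileName Character label (e.g. `"lacprodan"`).
#' @slot responseFactors Named numeric, per-class detection response factor
#'   (default 1 for every class).
#' @export
setClass("GroundTruthComposition",
         representation(composition = "data.frame",
                        profileName = "character",
                        responseFactors = "numeric"))

setValidity("GroundTruthComposition", function(object) {
  msg <- character()
  comp <- object@composition
  if (!all(c("species", "pmol") %in% names(comp)))
    msg <- c(msg, "composition needs columns species and pmol")
  else {
    if (any(comp$pmol <= 0)) msg <- c(msg, "pmol must be positive")
    for (s in comp$species) {
      ann <- tryCatch(parseAnnotation(s), error = function(e) NULL)
      if (is.null(ann) || ann@level != "molecular")
        msg <- c(msg, sprintf("'%s' is not a molecular-level annotation", s))
    }
  }
  if (any(object@responseFactors <= 0))
    msg <- c(msg, "response factors must be positive")
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: GC-FAME amount-versus-area calibration line
#'
#' @slot fame FAME name the curve belongs to (may be `NA` for a generic fit).
#' @slot slope,intercept OLS coefficients of amount on area; slope must be
#'   positive.
#' @slot fitRange Range of areas covered by the calibration points;
#'   predictions outside it are extrapolations and are flagged.
#' @slot residuals Fit residuals.
#' @export
setClass("CalibrationCurve",
         representation(fame = "character",
                        slope = "numeric",
                        intercept = "numeric",
                        fitRange = "numeric",
                        residuals = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (length(object@slope) != 1 || object@slope <= 0)
    "calibration slope must be a single positive number" else TRUE
})

#' CandidateSet: the identification search space
#'
#' Precomputed candidate species with precursor m/z and nominal isolation
#' step, derived from fatty acyl pools: TAG sum compositions (with an
#' acyl-pair achievability table used to restrict neutral-loss evidence to
#' chemically consistent moieties), molecular glycerophospholipid species,
#' and sum-level PC/SM species for headgroup-based identification.
#'
#' @slot tagSums data.frame of TAG sum compositions.
#' @slot gplSpecies data.frame of molecular glycerophospholipid candidates.
#' @slot headgroupSpecies data.frame of sum-level PC/SM candidates.
#' @slot tagPool,gplPool Fatty acyl pools (columns `carbons`, `doubleBonds`).
#' @slot pairTable Logical matrix; `pairTable[c, d]` is TRUE when two pool
#'   acyls can sum to c carbons and d double bonds (1-based offsets).
#' @slot mzRange Precursor m/z range searched.
#' @export
setClass("CandidateSet",
         representation(tagSums = "data.frame",
                        gplSpecies = "data.frame",
                        headgroupSpecies = "data.frame",
                        tagPool = "data.frame",
                        gplPool = "data.frame",
                        pairTable = "matrix",
                        mzRange = "numeric"))
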