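#' @include fragments.R
NULL

#' Nominal precursor step of an m/z value
#'
#' The acquisition fragments precursors in 1-amu steps; each step isolates
#' `[step - 0.5, step + 0.5)`, i.e. the step of an m/z value is the nearest
#' integer with ties at .5 rounded up.
#'
#' @param mz Precursor m/z value(s), within the 400-1000 acquisition range.
#' @return Integer step(s).
#' @examples
#' stepOf(876.802)  # 877
#' @export
stepOf <- function(mz) {
  if (any(mz < 400 | mz > 1000))
    stop("precursor m/z outside acquisition range 400-1000", call. = FALSE)
  as.integer(floor(mz + 0.5))
}

# merge centroid peaks closer than `tol` (sums intensity, intensity-weighted
# mean m/z) and sort ascending
.mergeCentroids <- function(peaks, tol = 1e-4) {
  if (nrow(peaks) == 0) return(peaks)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(peaks$mz) > tol))
  if (max(grp) < nrow(peaks)) {
    mz <- vapply(split(seq_len(nrow(peaks)), grp), function(idx) {
      w <- peaks$intensity[idx]
      if (sum(w) == 0) mean(peaks$mz[idx]) else weighted.mean(peaks$mz[idx], w)
    }, 0)
    int <- vapply(split(peaks$intensity, grp), sum, 0)
    peaks <- data.frame(mz = unname(mz), intensity = unname(int))
  }
  rownames(peaks) <- NULL
  peaks
}

#' Construct an MsMsSpectrum
#'
#' @param precursorStep Integer nominal precursor m/z (400-1000).
#' @param polarity `"+"` or `"-"`.
#' @param peaks data.frame with columns `mz`, `intensity`. Unsorted input
#'   is sorted (with a warning) and centroids closer than 1e-4 m/z are
#'   merged.
#' @return [MsMsSpectrum-class] object.
#' @export
msmsSpectrum <- function(precursorStep, polarity, peaks) {
  peaks <- as.data.frame(peaks)[, c("mz", "intensity")]
  if (nrow(peaks) > 1 && is.unsorted(peaks$mz))
    warning("unsorted peak list; sorting on construction", call. = FALSE)
  peaks <- .mergeCentroids(peaks)
  new("MsMsSpectrum", precursorStep = as.integer(precursorStep),
      polarity = polarity, peaks = peaks)
}

#' Construct an MsMsExperiment
#'
#' @param sampleId Character sample identifier.
#' @param spectra List of [MsMsSpectrum-class] objects (at most one per
#'   step/polarity).
#' @param spikeSheet data.frame with columns `annotation` (molecular-level
#'   shorthand) and `pmol`; defaults to empty.
#' @param metadata Named list of free-form acquisition metadata.
#' @return [MsMsExperiment-class] object.
#' @export
msmsExperiment <- function(sampleId, spectra = list(),
                           spikeSheet = NULL, metadata = list()) {
  if (is.null(spikeSheet))
    spikeSheet <- data.frame(annotation = character(), pmol = numeric())
  new("MsMsExperiment", sampleId = sampleId, spectra = spectra,
      spikeSheet = spikeSheet, metadata = metadata)
}

#' @describeIn msmsExperiment Sample identifier accessor.
#' @param experiment An [MsMsExperiment-class] object.
#' @export
sampleId <- function(experiment) experiment@sampleId

#' @describeIn msmsExperiment List of spectra.
#' @export
spectra <- function(experiment) experiment@spectra

#' @describeIn msmsExperiment Internal-standard spike sheet.
#' @export
spikeSheet <- function(experiment) experiment@spikeSheet

#' @describeIn msmsExperiment Acquisition metadata list.
#' @export
experimentMetadata <- function(experiment) experiment@metadata

#' @describeIn msmsExperiment Retrieve the spectrum at one (step, polarity),
#'   or NULL if absent.
#' @param step Integer precursor step.
#' @param polarity `"+"` or `"-"`.
#' @export
getSpectrum <- function(experiment, step, polarity) {
  for (s in experiment@spectra)
    if (s@precursorStep == step && s@polarity == polarity) return(s)
  NULL
}

.spectrumKeys <- function(experiment) {
  data.frame(
    step = vapply(experiment@spectra, slot, 0L, "precursorStep"),
    polarity = vapply(experiment@spectra, slot, "", "polarity"))
}

setMethod("show", "MsMsSpectrum", function(object) {
  cat(sprintf("MsMsSpectrum: step %d [%s], %d peaks\n",
              object@precursorStep, object@polarity, nrow(object@peaks)))
  invisible(NULL)
})

setMethod("show", "MsMsExperiment", function(object) {
  keys <- if (length(object@spectra)) .spectrumKeys(object) else
    data.frame(polarity = character())
  cat(sprintf("MsMsExperiment '%s': %d spectra (%d +, %d -), %d spikes\n",
              object@sampleId, length(object@spectra),
              sum(keys$polarity == "+"), sum(keys$polarity == "-"),
              nrow(object@spikeSheet)))
  invisible(NULL)
})

.formatPeaks <- function(peaks) {
  if (nrow(peaks) == 0) return("[]")
  paste0("[", paste(sprintf("[%.4f,%.1f]", peaks$mz, peaks$intensity),
                    collapse = ","), "]")
}

#' Write an experiment to the JSON-lines fixture format
#'
#' One spectrum per line with fields `sample`, `step`, `polarity`, `peaks`
#' (array of [m/z, intensity] pairs; m/z to 4 decimals, intensity to 1).
#' Output bytes are deterministic for identical input: fixed key order,
#' fixed float formatting, spectra ordered by polarity then step.
#'
#' @param experiment [MsMsExperiment-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeExperiment <- function(experiment, path) {
  stopifnot(is(experiment, "MsMsExperiment"))
  ord <- if (length(experiment@spectra)) {
    keys <- .spectrumKeys(experiment)
    order(keys$polarity, keys$step)
  } else integer()
  lines <- vapply(experiment@spectra[ord], function(s) {
    sprintf('{"sample":%s,"step":%d,"polarity":"%s","peaks":%s}',
            jsonlite::toJSON(experiment@sampleId, auto_unbox = TRUE),
            s@precursorStep, s@polarity, .formatPeaks(s@peaks))
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an experiment from the JSON-lines fixture format or mzML
#'
#' The JSON-lines layout written by [writeExperiment()] is the canonical
#' fixture format. `format = "mzML"` ingests MS2 scans of a standard mzML
#' file through the mzR package (one spectrum per scan; the precursor step
#' is the nominal step of the selected-ion m/z).
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"mzML"`.
#' @param spikeSheet Optional spike sheet data.frame to attach (see
#'   [readSpikeSheet()]).
#' @param sampleId Sample id override (defaults to the file's `sample`
#'   field, or the file name for mzML).
#' @return [MsMsExperiment-class] object.
#' @export
readExperiment <- function(path, format = c("jsonl", "mzML"),
                           spikeSheet = NULL, sampleId = NULL) {
  format <- match.arg(format)
  if (format == "mzML") return(.readMzml(path, spikeSheet, sampleId))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyMatrix = TRUE)
  spectra <- list()
  seen <- character()
  sample <- sampleId
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    if (is.null(sample)) sample <- r$sample
    key <- paste(r$step, r$polarity)
    if (key %in% seen)
      stop(sprintf("duplicate (step, polarity) %s at line %d", key, k),
           call. = FALSE)
    seen <- c(seen, key)
    pk <- r$peaks
    peaks <- if (length(pk) == 0)
      data.frame(mz = numeric(), intensity = numeric())
    else
      data.frame(mz = pk[, 1], intensity = pk[, 2])
    spectra[[length(spectra) + 1L]] <-
      msmsSpectrum(r$step, r$polarity, peaks)
  }
  msmsExperiment(if (is.null(sample)) "unknown" else sample, spectra,
                 spikeSheet = spikeSheet)
}

.readMzml <- function(path, spikeSheet = NULL, sampleId = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML ingest requires the mzR package", call. = FALSE)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  ms2 <- which(h$msLevel == 2)
  spectra <- lapply(ms2, function(i) {
    pk <- mzR::peaks(f, i)
    pol <- if (!is.null(h$polarity) && h$polarity[i] == 0) "-" else "+"
    msmsSpectrum(stepOf(h$precursorMZ[i]), pol,
                 data.frame(mz = pk[, 1], intensity = pk[, 2]))
  })
  msmsExperiment(if (is.null(sampleId)) basename(path) else sampleId,
                 spectra, spikeSheet = spikeSheet)
}

#' Read/write an internal-standard spike sheet
#'
#' Tab-separated with columns `annotation` (molecular-level shorthand) and
#' `pmol`.
#'
#' @param path File path.
#' @return data.frame with columns `annotation`, `pmol`, `lipidClass`.
#' @export
readSpikeSheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("annotation", "pmol") %in% names(tab)))
    stop("spike sheet needs columns 'annotation' and 'pmol'", call. = FALSE)
  for (k in seq_len(nrow(tab))) {
    ann <- tryCatch(parseAnnotation(tab$annotation[k]), error = function(e) e)
    if (inherits(ann, "error") ||
        annotationLevel(ann) != "molecular")
      stop(sprintf("spike sheet row %d ('%s') is not a molecular-level annotation",
                   k, tab$annotation[k]), call. = FALSE)
    tab$lipidClass[k] <- lipidClass(ann)
  }
  tab
}

#' @rdname readSpikeSheet
#' @param spikes data.frame with columns `annotation`, `pmol`.
#' @export
writeSpikeSheet <- function(spikes, path) {
  utils::write.table(spikes[, c("annotation", "pmol")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
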