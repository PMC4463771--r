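#' @include simulate.R
NULL

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full MS/MS identification and quantification workflow
#'
#' Simulates (or accepts) a precursor-stepped MS/MS experiment, builds
#' the candidate search space from the experiment's spike sheet, runs all
#' identification routes, quantifies against the internal standards, and
#' derives class composition, the TAG FA index, the overall TAG FA
#' profile and the unsaturation index. Outputs are deterministic for a
#' fixed fixture and seed.
#'
#' @param fixture Fixture name for [makeFixture()], a
#'   [GroundTruthComposition-class], or `NULL` when `experiment` is
#'   given.
#' @param experiment Optional pre-built [MsMsExperiment-class]; skips
#'   simulation.
#' @param spikes Spike sheet (default [defaultSpikeSheet()]).
#' @param noise [NoiseModel-class] used for simulation (default
#'   [zeroNoise()]).
#' @param settings [MatchSettings-class].
#' @param candidates Optional prebuilt [CandidateSet-class] (rebuilt from
#'   the spike sheet when `NULL`).
#' @param outputDir When non-NULL, TSV outputs (identifications, quant
#'   table, class composition, FA index, FA profile, unsaturation index)
#'   are written there.
#' @param verbose Log per-stage counts via `message()`.
#' @return List with `experiment`, `groundTruth` (NULL for external
#'   experiments), `identifications`, `quant`, `classComposition`,
#'   `faIndex`, `faProfile`, `unsaturationIndex`.
#' @examples
#' res <- runMsWorkflow("lacprodan")
#' round(res$classComposition, 1)
#' @export
runMsWorkflow <- function(fixture = "lacprodan", experiment = NULL,
                          spikes = defaultSpikeSheet(), noise = zeroNoise(),
                          settings = matchSettings(), candidates = NULL,
                          outputDir = NULL, verbose = FALSE) {
  truth <- NULL
  if (is.null(experiment)) {
    comp <- if (is(fixture, "GroundTruthComposition")) fixture
      else .stageTry("simulate", makeFixture(fixture))
    sim <- .stageTry("simulate", simulateMsmsAll(comp, spikes, noise))
    experiment <- sim$experiment
    truth <- sim$groundTruth
  }
  if (is.null(candidates))
    candidates <- .stageTry("candidates",
                            candidateSet(spikes = spikeSheet(experiment)))
  if (verbose)
    message(sprintf("candidates: %d TAG sums, %d molecular GPL, %d PC/SM sums",
                    nrow(candidates@tagSums), nrow(candidates@gplSpecies),
                    nrow(candidates@headgroupSpecies)))
  ids <- .stageTry("identify",
                   identifyLipids(experiment, candidates, settings))
  if (verbose) {
    counts <- table(ids$lipidClass[!ids$internalStandard])
    message(sprintf("identified %d species (%s) + %d standards",
                    sum(!ids$internalStandard),
                    paste(sprintf("%s %d", names(counts), counts),
                          collapse = ", "),
                    sum(ids$internalStandard)))
  }
  quant <- .stageTry("quantify",
                     quantify(ids, spikeSheet(experiment),
                              onMissingStandard = "drop"))
  classes <- .stageTry("quantify", classComposition(quant))
  faIndex <- faProfile <- unsat <- NULL
  if (any(quant$lipidClass == "TAG")) {
    faIndex <- .stageTry("index", tagFaIndex(ids[!ids$internalStandard, ]))
    faProfile <- .stageTry("index", tagFaProfile(quant, faIndex))
    unsat <- .stageTry("index", unsaturationIndex(faProfile))
  }
  if (verbose)
    message(sprintf("quantified %d species in %d classes", nrow(quant),
                    length(classes)))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeIdentifications(ids, file.path(outputDir, "identifications.tsv"))
    writeQuantTable(quant, file.path(outputDir, "quant.tsv"))
    writeProfile(classes, file.path(outputDir, "class_composition.tsv"))
    if (!is.null(faIndex)) {
      writeFaIndex(faIndex, file.path(outputDir, "tag_fa_index.tsv"))
      writeProfile(faProfile, file.path(outputDir, "tag_fa_profile.tsv"))
      writeProfile(unsat, file.path(outputDir, "unsaturation_index.tsv"))
    }
  }
  list(experiment = experiment, groundTruth = truth,
       identifications = ids, quant = quant, classComposition = classes,
       faIndex = faIndex, faProfile = faProfile, unsaturationIndex = unsat)
}

#' Run the GC-FAME profiling workflow over replicate simulations
#'
#' Simulates replicate GC peak tables per fixture, assigns peaks by
#' retention time, quantifies through the calibration curves, and
#' compares samples per FAME with one-way ANOVA plus Fisher's LSD.
#'
#' @param fixtures Character vector of fixture names.
#' @param replicates Replicates per fixture (default 3).
#' @param seed Base seed; replicate r of fixture f uses
#'   `seed + 100 * f + r`.
#' @param areaCv Relative area noise per replicate.
#' @param alpha Significance level for the pairwise flags.
#' @param outputDir When non-NULL, profile and pairwise-comparison TSVs
#'   are written there.
#' @return List with `profiles` (mean FAME percentages per fixture),
#'   `replicates` (per-replicate percentage matrix), `comparisons`
#'   (per-FAME ANOVA/LSD results).
#' @export
runGcWorkflow <- function(fixtures = c("human1", "human2", "cow", "lacprodan"),
                          replicates = 3L, seed = 1L, areaCv = 0.05,
                          alpha = 0.01, outputDir = NULL) {
  curves <- defaultCalibration()
  lib <- defaultRtLibrary()
  reps <- list()
  for (f in seq_along(fixtures)) {
    comp <- makeFixture(fixtures[f])
    for (r in seq_len(replicates)) {
      peaks <- simulateGc(comp, curves, lib, areaCv = areaCv,
                          seed = seed + 100L * f + r)
      areas <- suppressMessages(identifyFames(peaks, lib))
      pct <- faPercentages(areas, curves)$percentages
      reps[[length(reps) + 1L]] <- data.frame(
        fixture = fixtures[f], replicate = r, fame = names(pct),
        percent = as.numeric(pct), stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, reps)
  profiles <- do.call(rbind, lapply(split(reps, reps$fixture), function(d)
    data.frame(fixture = d$fixture[1],
               fame = names(tapply(d$percent, d$fame, mean)),
               percent = as.numeric(tapply(d$percent, d$fame, mean)))))
  rownames(profiles) <- NULL

  comparisons <- list()
  for (fm in unique(reps$fame)) {
    d <- reps[reps$fame == fm, ]
    groups <- split(d$percent, d$fixture)
    groups <- groups[vapply(groups, length, 0L) >= 2]
    if (length(groups) >= 2)
      comparisons[[fm]] <- anovaFisherLsd(groups, alpha = alpha)
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(profiles, file.path(outputDir, "gc_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pairs <- do.call(rbind, lapply(names(comparisons), function(fm)
      cbind(fame = fm, comparisons[[fm]]$pairs)))
    utils::write.table(pairs, file.path(outputDir, "gc_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(profiles = profiles, replicates = reps, comparisons = comparisons)
}

.collapseFaKey <- function(names) {
  sub("^FA ([0-9]+:[0-9]+).*$", "\\1", names)
}

.normProfile <- function(p, keys) {
  out <- setNames(numeric(length(keys)), keys)
  k <- .collapseFaKey(names(p))
  for (i in seq_along(p)) out[k[i]] <- out[k[i]] + p[i]
  out
}

#' Compare GC and MS fatty acid profiles and attribute FA shares to classes
#'
#' Joins a GC-FAME percentage profile with the MS-side TAG and
#' glycerophospholipid FA profiles on the shared carbons:double-bonds key
#' space (GC positional suffixes such as `n-9c` are collapsed). Reports
#' the L1 distance between the GC profile and the pmol-weighted MS total
#' profile, per-source unsaturation shares, and a per-FA attribution
#' table showing which lipid class carries each FA's share. The
#' `attributionFlag` marks the situation where total profiles agree (L1
#' below `l1Threshold`) while the TAG and glycerophospholipid
#' unsaturation shares differ by more than `attributionThreshold` -- i.e.
#' agreement at the total-FA level masks a class-level difference.
#'
#' @param gcProfile Named GC percentage vector (FAME names or `"c:d"`).
#' @param msTagProfile Named TAG FA percentage vector from
#'   [tagFaProfile()].
#' @param msGplProfile Named glycerophospholipid FA percentage vector
#'   (moiety-weighted, e.g. from [gplFaProfileFromQuant()]).
#' @param tagWeight,gplWeight Molar weights of the two MS pools (e.g.
#'   summed pmol); default equal weights.
#' @param l1Threshold Percent L1 distance under which total profiles are
#'   called concordant.
#' @param attributionThreshold Minimum difference (percentage points)
#'   between TAG and GPL unsaturated shares to raise the flag.
#' @return List with `profiles` (matrix: gc, msTotal, tag, gpl),
#'   `l1GcMs`, `unsaturatedShares`, `attribution` (per-FA class shares),
#'   `totalsAgree`, `attributionFlag`.
#' @export
compareFaProfiles <- function(gcProfile, msTagProfile, msGplProfile,
                              tagWeight = 1, gplWeight = 1,
                              l1Threshold = 5, attributionThreshold = 10) {
  if (length(gcProfile) == 0 || (length(msTagProfile) == 0 &&
                                 length(msGplProfile) == 0))
    stop("profiles must be non-empty", call. = FALSE)
  keys <- sort(unique(c(.collapseFaKey(names(gcProfile)),
                        .collapseFaKey(names(msTagProfile)),
                        .collapseFaKey(names(msGplProfile)))))
  gc <- .normProfile(gcProfile, keys)
  tag <- .normProfile(msTagProfile, keys)
  gpl <- .normProfile(msGplProfile, keys)
  w <- c(tagWeight, gplWeight) / (tagWeight + gplWeight)
  msTotal <- w[1] * tag + w[2] * gpl
  l1 <- sum(abs(gc - msTotal))
  db <- as.integer(sub("^[0-9]+:", "", keys))
  unsat <- function(p) sum(p[db > 0]) / ifelse(sum(p) > 0, sum(p), 1) * 100
  shares <- c(gc = unsat(gc), msTotal = unsat(msTotal), tag = unsat(tag),
              gpl = unsat(gpl))
  contribTag <- w[1] * tag
  contribGpl <- w[2] * gpl
  tot <- contribTag + contribGpl
  attribution <- data.frame(
    fa = keys, doubleBonds = db,
    msTotalPct = as.numeric(tot),
    tagShare = ifelse(tot > 0, contribTag / tot, NA_real_),
    gplShare = ifelse(tot > 0, contribGpl / tot, NA_real_))
  totalsAgree <- l1 < l1Threshold
  # the attribution contrast is only meaningful when both MS pools carry mass
  flag <- totalsAgree && sum(tag) > 0 && sum(gpl) > 0 &&
    abs(shares["tag"] - shares["gpl"]) > attributionThreshold
  list(profiles = rbind(gc = gc, msTotal = msTotal, tag = tag, gpl = gpl),
       l1GcMs = l1, unsaturatedShares = shares, attribution = attribution,
       totalsAgree = totalsAgree, attributionFlag = unname(flag))
}

#' Moiety-weighted FA profile of quantified glycerophospholipids
#'
#' The percentage of individual FA moieties across all quantified
#' molecular glycerophospholipid species (PC, PE, PS, PI), each species
#' contributing its pmol to each of its two acyl positions.
#'
#' @param quant QuantTable from [quantify()].
#' @return Named percentage vector over `"FA c:d"` labels, or an empty
#'   vector if no molecular glycerophospholipids were quantified.
#' @export
gplFaProfileFromQuant <- function(quant) {
  rows <- quant[quant$lipidClass %in% .GPL_CLASSES &
                  quant$level == "molecular", , drop = FALSE]
  if (nrow(rows) == 0) return(setNames(numeric(0), character(0)))
  acc <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(rows))) {
    m <- moieties(parseAnnotation(rows$species[k]))
    for (j in seq_len(nrow(m))) {
      key <- .faLabel(m$carbons[j], m$doubleBonds[j])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        rows$pmol[k]
    }
  }
  keys <- ls(acc)
  v <- vapply(keys, function(k) acc[[k]], 0)
  100 * v / sum(v)
}
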