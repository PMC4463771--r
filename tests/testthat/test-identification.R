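test_that("fragment matching respects tolerance, floor and tie-breaks", {
  s <- makeTinySpectrum(877, "+", c(575.50, 603.5351, 603.60), c(5, 100, 40))
  pred <- data.frame(label = "FA 16:0", fragmentMz = 603.5347)
  ev <- matchFragments(s, pred, matchSettings(toleranceMz = 0.01))
  expect_equal(unname(ev["FA 16:0"]), 100)
  # out of tolerance
  ev <- matchFragments(s, data.frame(label = "x", fragmentMz = 603.57),
                       matchSettings(toleranceMz = 0.01))
  expect_length(ev, 0)
  # intensity floor drops weak matches
  ev <- matchFragments(s, data.frame(label = "w", fragmentMz = 575.50),
                       matchSettings(intensityFloor = 10))
  expect_length(ev, 0)
  # equidistant peaks resolve to the lower-m/z peak
  s2 <- makeTinySpectrum(500, "+", c(400.00, 400.02), c(7, 9))
  ev <- matchFragments(s2, data.frame(label = "t", fragmentMz = 400.01),
                       matchSettings(toleranceMz = 0.05))
  expect_equal(unname(ev["t"]), 7)
})

test_that("a composite TAG 52:2 yields one identification with 4 neutral losses", {
  comp <- new("GroundTruthComposition",
              composition = data.frame(
                species = c("TAG 16:0-18:1-18:1", "TAG 16:0-18:0-18:2"),
                pmol = c(300, 100)),
              profileName = "tag522", responseFactors = c(TAG = 1))
  sim <- simulateMsmsAll(comp, spikes = defaultSpikeSheet())
  cand <- candidateSet(spikes = defaultSpikeSheet())
  ids <- suppressMessages(identifyTag(sim$experiment, cand))
  sample <- ids[!ids$internalStandard, ]
  expect_equal(sample$species, "TAG 52:2")
  expect_setequal(names(sample$evidence[[1]]),
                  c("FA 16:0", "FA 18:0", "FA 18:1", "FA 18:2"))
  # the spiked standard is flagged
  expect_true(any(ids$internalStandard & ids$species == "TAG 51:3"))
})

test_that("a TAG with a single matched neutral loss is rejected", {
  # hand-built spectrum: only the 16:0 loss of TAG 52:2 present
  mz <- tagNeutralLossFragments("TAG 16:0-18:1-18:1")
  s <- makeTinySpectrum(877, "+",
                        mz$fragmentMz[mz$fa == "FA 16:0"], 100)
  expt <- makeTinyExperiment(list(s))
  cand <- candidateSet()
  ids <- suppressMessages(identifyTag(expt, cand))
  expect_equal(nrow(ids), 0L)
  # the same evidence passes at minTagFragments = 1
  ids <- suppressMessages(
    identifyTag(expt, cand, matchSettings(minTagFragments = 1L)))
  expect_true("TAG 52:2" %in% ids$species)
})

test_that("glycerophospholipids need both anions consistent with the precursor sum", {
  cand <- candidateSet()
  # PE 34:2 step containing only 16:0 and 18:1 anions: no candidate pairing
  # sums to 34:2, so nothing is assigned
  pe342 <- monoisotopicMz(elementalComposition("PE 16:0-18:2"), "-H")
  s <- makeTinySpectrum(stepOf(pe342), "-",
                        c(monoisotopicMz(acylFormula(16, 0), "-H"),
                          monoisotopicMz(acylFormula(18, 1), "-H")),
                        c(50, 50))
  ids <- suppressMessages(identifyGpl(makeTinyExperiment(list(s)), cand))
  expect_equal(nrow(ids), 0L)
  # adding the consistent 18:2 anion identifies PE 16:0-18:2
  s2 <- makeTinySpectrum(stepOf(pe342), "-",
                         c(monoisotopicMz(acylFormula(16, 0), "-H"),
                           monoisotopicMz(acylFormula(18, 2), "-H")),
                         c(50, 50))
  ids <- suppressMessages(identifyGpl(makeTinyExperiment(list(s2)), cand))
  expect_equal(ids$species, "PE 16:0-18:2")
  expect_equal(ids$level, "molecular")
})

test_that("PS requires the serine-loss fragment", {
  cand <- candidateSet()
  fr <- gplFragments("PS 18:0-18:1", "-")
  anions <- fr[fr$label != "NL serine", ]
  s <- makeTinySpectrum(stepOf(fr$precursorMz[1]), "-",
                        sort(anions$fragmentMz), c(40, 60))
  ids <- suppressMessages(identifyGpl(makeTinyExperiment(list(s)), cand))
  expect_false("PS 18:0-18:1" %in% ids$species)
  s2 <- makeTinySpectrum(stepOf(fr$precursorMz[1]), "-",
                         sort(fr$fragmentMz), c(40, 60, 30))
  ids <- suppressMessages(identifyGpl(makeTinyExperiment(list(s2)), cand))
  expect_true("PS 18:0-18:1" %in% ids$species)
})

test_that("headgroup identification needs 184.0733 plus the exact precursor", {
  cand <- candidateSet()
  smMz <- monoisotopicMz(elementalComposition("SM 34:1;2"), "+H")
  hg <- 184.0733
  # headgroup alone (no residual precursor): logged, nothing identified
  s <- makeTinySpectrum(stepOf(smMz), "+", hg, 100)
  expect_message(
    ids <- identifyHeadgroupSpecies(makeTinyExperiment(list(s)), cand),
    "no PC/SM candidate")
  expect_equal(nrow(ids), 0L)
  # with the residual precursor the SM species is identified at sum level
  s2 <- makeTinySpectrum(stepOf(smMz), "+", c(hg, smMz), c(100, 30))
  ids <- suppressMessages(
    identifyHeadgroupSpecies(makeTinyExperiment(list(s2)), cand))
  expect_equal(ids$species, "SM 34:1;2")
  expect_equal(unname(ids$evidence[[1]]["headgroup"]), 100)
})

test_that("PC found in both modes merges to a single molecular record", {
  comp <- new("GroundTruthComposition",
              composition = data.frame(species = "PC 16:0-18:1", pmol = 100),
              profileName = "pc", responseFactors = c(PC = 1))
  sim <- simulateMsmsAll(comp, spikes = defaultSpikeSheet())
  cand <- candidateSet(spikes = defaultSpikeSheet())
  ids <- suppressMessages(identifyLipids(sim$experiment, cand))
  pc <- ids[ids$lipidClass == "PC" & !ids$internalStandard, ]
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$level, "molecular")
  expect_equal(pc$species, "PC 16:0-18:1")
})

test_that("identification is invariant to peak order and intensity scaling", {
  comp <- makeFixture("lacprodan")
  sim <- simulateMsmsAll(comp)
  cand <- candidateSet(spikes = defaultSpikeSheet())
  base <- suppressMessages(identifyLipids(sim$experiment, cand))

  scramble <- lapply(spectra(sim$experiment), function(s) {
    p <- s@peaks[sample.int(nrow(s@peaks)), , drop = FALSE]
    p$intensity <- p$intensity * 7.5
    suppressWarnings(msmsSpectrum(s@precursorStep, s@polarity, p))
  })
  expt2 <- msmsExperiment(sampleId(sim$experiment), scramble,
                          spikeSheet = spikeSheet(sim$experiment))
  alt <- suppressMessages(identifyLipids(expt2, cand))
  expect_setequal(alt$species, base$species)
})

test_that("distinct molecular TAG species imply at least NL count / 3", {
  comp <- makeFixture("cow")
  sim <- simulateMsmsAll(comp)
  cand <- candidateSet(spikes = defaultSpikeSheet())
  ids <- suppressMessages(identifyTag(sim$experiment, cand))
  truthMol <- makeFixture("cow")@composition
  nMol <- sum(grepl("^TAG", truthMol$species))
  for (k in seq_len(nrow(ids))) {
    if (ids$internalStandard[k]) next
    nl <- length(ids$evidence[[k]])
    expect_gte(nMol, ceiling(nl / 3))
  }
})
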