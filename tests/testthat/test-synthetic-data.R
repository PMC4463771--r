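test_that("fixtures reproduce the intended class fractions", {
  lac <- makeFixture("lacprodan")
  cls <- vapply(lac@composition$species, function(s)
    lipidClass(parseAnnotation(s)), "")
  pct <- 100 * tapply(lac@composition$pmol, cls, sum) /
    sum(lac@composition$pmol)
  expect_equal(as.numeric(pct[c("TAG", "PE", "PC", "SM", "PS", "PI")]),
               c(25, 35, 18, 8, 9, 5), tolerance = 1e-9)

  for (fx in c("human1", "human2")) {
    h <- makeFixture(fx)
    cls <- vapply(h@composition$species, function(s)
      lipidClass(parseAnnotation(s)), "")
    tagPct <- 100 * sum(h@composition$pmol[cls == "TAG"]) /
      sum(h@composition$pmol)
    expect_gt(tagPct, 97)
  }
  # human2 is a perturbed human1, not a copy
  expect_false(isTRUE(all.equal(makeFixture("human1")@composition$pmol,
                                makeFixture("human2")@composition$pmol)))
  expect_identical(makeFixture("human2")@composition$pmol,
                   makeFixture("human2")@composition$pmol)
  expect_error(makeFixture("goat"), "arg")
})

test_that("the most abundant Lacprodan species per class match the profile", {
  lac <- makeFixture("lacprodan")@composition
  cls <- vapply(lac$species, function(s) lipidClass(parseAnnotation(s)), "")
  top <- vapply(split(lac, cls), function(d)
    d$species[which.max(d$pmol)], "")
  expect_equal(unname(top["PC"]), "PC 16:0-18:1")
  expect_equal(unname(top["PE"]), "PE 18:1-18:1")
  expect_equal(unname(top["PI"]), "PI 18:0-18:1")
  expect_equal(unname(top["PS"]), "PS 18:0-18:1")
})

test_that("simulation is deterministic under a fixed seed", {
  n <- noiseModel(intensityCv = 0.05, mzJitterPpm = 5, baselineRate = 3,
                  seed = 77L)
  a <- simulateMsmsAll(makeFixture("cow"), noise = n)
  b <- simulateMsmsAll(makeFixture("cow"), noise = n)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeExperiment(a$experiment, p1)
  writeExperiment(b$experiment, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the bytes
  c <- simulateMsmsAll(makeFixture("cow"),
                       noise = noiseModel(0.05, 5, 3, seed = 78L))
  p3 <- withr::local_tempfile()
  writeExperiment(c$experiment, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("isomeric TAG species superimpose into one composite step", {
  comp <- new("GroundTruthComposition",
              composition = data.frame(
                species = c("TAG 16:0-18:1-18:1", "TAG 16:0-18:0-18:2"),
                pmol = c(100, 100)),
              profileName = "t", responseFactors = c(TAG = 1))
  sim <- simulateMsmsAll(comp, spikes = defaultSpikeSheet()[1, ])
  step <- stepOf(monoisotopicMz(elementalComposition("TAG 52:2"), "+NH4"))
  s <- getSpectrum(sim$experiment, step, "+")
  expect_equal(nrow(s@peaks), 4L)
  expect_equal(round(sort(s@peaks$mz), 3),
               c(575.503, 577.519, 579.535, 603.535))
})

test_that("species outside the precursor range are excluded with a warning", {
  comp <- new("GroundTruthComposition",
              composition = data.frame(
                species = c("TAG 4:0-4:0-4:0", "TAG 16:0-18:1-18:1"),
                pmol = c(10, 100)),
              profileName = "t", responseFactors = c(TAG = 1))
  expect_warning(sim <- simulateMsmsAll(comp, spikes = defaultSpikeSheet()),
                 "outside 400-1000")
  expect_false(sim$groundTruth$included[
    sim$groundTruth$species == "TAG 4:0-4:0-4:0"])
  expect_true(sim$groundTruth$included[
    sim$groundTruth$species == "TAG 16:0-18:1-18:1"])
})

test_that("simulated GC peaks invert the calibration exactly at zero noise", {
  comp <- makeFixture("human1")
  tagOnly <- comp@composition[grepl("^TAG", comp@composition$species), ]
  gt <- new("GroundTruthComposition", composition = tagOnly,
            profileName = "t", responseFactors = c(TAG = 1))
  curves <- defaultCalibration()
  lib <- defaultRtLibrary()
  peaks <- simulateGc(gt, curves, lib, rtJitter = 0, seed = 1)
  areas <- suppressMessages(identifyFames(peaks, lib))
  got <- faPercentages(areas, curves)

  # expected: moiety-weighted FA percentages of the composition, >= 10 C
  acc <- list()
  for (k in seq_len(nrow(tagOnly))) {
    m <- moieties(parseAnnotation(tagOnly$species[k]))
    for (j in seq_len(nrow(m))) {
      if (m$carbons[j] < 10) next
      key <- sprintf("%d:%d", m$carbons[j], m$doubleBonds[j])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        tagOnly$pmol[k]
    }
  }
  want <- 100 * unlist(acc) / sum(unlist(acc))
  gotKey <- sub("^FA ([0-9]+:[0-9]+).*$", "\\1", names(got$percentages))
  expect_setequal(gotKey, names(want))
  expect_equal(unname(got$percentages[match(names(want), gotKey)]),
               unname(want), tolerance = 1e-9)
})

test_that("GC simulation is deterministic and omits short-chain FAs", {
  cow <- makeFixture("cow")
  a <- simulateGc(cow, seed = 5)
  b <- simulateGc(cow, seed = 5)
  expect_identical(a, b)
  # MS-side TAG composition contains 4-10 C moieties; the GC table cannot
  lib <- defaultRtLibrary()
  areas <- suppressMessages(identifyFames(a, lib))
  gcCarbons <- lib$carbons[match(names(areas), lib$fame)]
  expect_true(all(gcCarbons >= 10))
  msCarbons <- unlist(lapply(cow@composition$species, function(s) {
    m <- moieties(parseAnnotation(s))
    m$carbons[!m$isLcb]
  }))
  expect_true(any(msCarbons < 10))
  # an FA in range but missing from the library is an error
  expect_error(simulateGc(cow, rtLibrary = lib[lib$fame != "FA 14:0", ]),
               "14:0")
})

test_that("identification recall does not increase with m/z jitter", {
  cand <- candidateSet(spikes = defaultSpikeSheet())
  truth <- groundTruthSpecies(makeFixture("lacprodan"))
  recall <- vapply(c(0, 50, 300), function(ppm) {
    sim <- simulateMsmsAll(makeFixture("lacprodan"),
                           noise = noiseModel(0, ppm, 0, seed = 11L))
    ids <- suppressMessages(identifyLipids(sim$experiment, cand))
    mean(truth$species %in% ids$species[!ids$internalStandard])
  }, 0)
  expect_equal(recall[1], 1)
  expect_true(all(diff(recall) <= 0))
  expect_lt(recall[3], 1)
})
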