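# hand-built identification tables for direct ratio checks
.idTable <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

.row <- function(species, cls, level, ev, std = FALSE) {
  ann <- parseAnnotation(species)
  data.frame(species = species, lipidClass = cls, level = level,
             sumCarbons = ann@sumCarbons, sumDoubleBonds = ann@sumDoubleBonds,
             step = 500L, polarity = "+", internalStandard = std,
             evidence = I(list(ev)), stringsAsFactors = FALSE)
}

test_that("quantification is the spike-scaled evidence ratio", {
  spikes <- data.frame(annotation = "TAG 17:1-17:1-17:1", pmol = 93)
  ids <- .idTable(
    .row("TAG 52:2", "TAG", "sum",
         c("FA 16:0" = 40, "FA 18:1" = 60)),
    .row("TAG 51:3", "TAG", "sum", c("FA 17:1" = 100), std = TRUE))
  q <- quantify(ids, spikes)
  # evidence sum equals the standard's: ratio 1 -> 93 pmol
  expect_equal(q$pmol[q$species == "TAG 52:2"], 93)
  # doubling the evidence doubles the amount (exact linearity)
  ids2 <- ids
  ids2$evidence[[1]] <- ids2$evidence[[1]] * 2
  q2 <- quantify(ids2, spikes)
  expect_equal(q2$pmol[q2$species == "TAG 52:2"], 186)
})

test_that("quantification errors name the failing class", {
  spikes <- data.frame(annotation = "TAG 17:1-17:1-17:1", pmol = 93)
  noStd <- .idTable(.row("TAG 52:2", "TAG", "sum", c("FA 16:0" = 1)))
  expect_error(quantify(noStd, spikes), "TAG")
  zeroStd <- .idTable(
    .row("TAG 52:2", "TAG", "sum", c("FA 16:0" = 1)),
    .row("TAG 51:3", "TAG", "sum", c("FA 17:1" = 0), std = TRUE))
  expect_error(quantify(zeroStd, spikes), "zero")
})

test_that("zero-noise simulation recovers ground-truth amounts exactly", {
  res <- suppressMessages(runMsWorkflow("lacprodan"))
  truth <- groundTruthSpecies(makeFixture("lacprodan"))
  m <- merge(res$quant, truth, by = "species")
  expect_equal(nrow(m), nrow(truth))
  expect_lt(max(abs(m$pmol.x - m$pmol.y) / m$pmol.y), 1e-6)
})

test_that("global intensity scaling leaves pmol unchanged", {
  sim <- simulateMsmsAll(makeFixture("human1"))
  cand <- candidateSet(spikes = defaultSpikeSheet())
  q1 <- quantify(suppressMessages(identifyLipids(sim$experiment, cand)),
                 defaultSpikeSheet())
  scaled <- lapply(spectra(sim$experiment), function(s) {
    p <- s@peaks
    p$intensity <- p$intensity * 1234
    msmsSpectrum(s@precursorStep, s@polarity, p)
  })
  expt2 <- msmsExperiment("scaled", scaled,
                          spikeSheet = spikeSheet(sim$experiment))
  q2 <- quantify(suppressMessages(identifyLipids(expt2, cand)),
                 defaultSpikeSheet())
  m <- merge(q1, q2, by = "species")
  expect_equal(m$pmol.x, m$pmol.y, tolerance = 1e-12)
})

test_that("class composition behaves on trivial tables", {
  q <- data.frame(species = c("a", "b"), lipidClass = c("TAG", "PC"),
                  level = "sum", pmol = c(75, 25),
                  molPctTotal = c(75, 25), molPctClass = c(100, 100))
  cc <- classComposition(q)
  expect_equal(unname(cc["TAG"]), 75)
  expect_equal(unname(cc["PC"]), 25)
  expect_equal(sum(cc), 100)
  one <- classComposition(q[1, ])
  expect_equal(unname(one["TAG"]), 100)
  expect_error(classComposition(q[0, ]), "empty")
  qz <- q; qz$pmol <- 0
  expect_error(classComposition(qz), "zero")
})

test_that("the FA index is the within-species neutral-loss share", {
  ids <- .idTable(
    .row("TAG 52:2", "TAG", "sum", c("FA 16:0" = 1, "FA 18:1" = 2)),
    .row("TAG 51:3", "TAG", "sum", c("FA 17:1" = 5)))
  idx <- tagFaIndex(ids)
  expect_equal(unname(idx["TAG 52:2", "FA 16:0"]), 1 / 3)
  expect_equal(unname(idx["TAG 52:2", "FA 18:1"]), 2 / 3)
  expect_equal(unname(idx["TAG 51:3", "FA 17:1"]), 1)
  expect_equal(unname(rowSums(idx)), c(1, 1), tolerance = 1e-9)
  # zero-evidence species are excluded with a message
  ids0 <- .idTable(.row("TAG 52:2", "TAG", "sum", c("FA 16:0" = 1)),
                   .row("TAG 50:1", "TAG", "sum", c("FA 16:0" = 0)))
  expect_message(idx0 <- tagFaIndex(ids0), "zero evidence")
  expect_equal(rownames(idx0), "TAG 52:2")
})

test_that("FA index rows sum to 1 on every simulated fixture", {
  for (fx in c("human1", "cow", "lacprodan")) {
    res <- suppressMessages(runMsWorkflow(fx))
    expect_equal(unname(rowSums(res$faIndex)),
                 rep(1, nrow(res$faIndex)), tolerance = 1e-9)
  }
})

test_that("the TAG FA profile is the pmol-weighted index", {
  idx <- matrix(c(1, 0, 0, 1), 2, 2,
                dimnames = list(c("TAG 48:0", "TAG 54:3"),
                                c("FA 16:0", "FA 18:1")))
  q <- data.frame(species = c("TAG 48:0", "TAG 54:3"), lipidClass = "TAG",
                  level = "sum", pmol = c(10, 10),
                  molPctTotal = 50, molPctClass = 50)
  pr <- tagFaProfile(q, idx)
  expect_equal(unname(pr["FA 16:0"]), 50)
  expect_equal(unname(pr["FA 18:1"]), 50)
  # single species: profile equals its index row x 100
  pr1 <- tagFaProfile(q[1, ], idx)
  expect_equal(unname(pr1["FA 16:0"]), 100)
  expect_equal(sum(pr), 100)
})

test_that("the unsaturation index partitions the profile by double bonds", {
  pr <- c("FA 16:0" = 40, "FA 18:1" = 60)
  u <- unsaturationIndex(pr)
  expect_equal(unname(u["0"]), 40)
  expect_equal(unname(u["1"]), 60)
  expect_equal(sum(u), 100)
  allSat <- unsaturationIndex(c("FA 16:0" = 100))
  expect_equal(unname(allSat["0"]), 100)
  expect_equal(sum(allSat[-1]), 0)
  expect_error(unsaturationIndex(c("FA 22:6" = 100)), "double bonds")
  # configurable cap admits it
  expect_equal(unname(unsaturationIndex(c("FA 22:6" = 100),
                                        maxDb = 6)["6"]), 100)
})

test_that("quant and unsaturation percentages sum to 100 on fixtures", {
  for (fx in c("human2", "lacprodan")) {
    res <- suppressMessages(runMsWorkflow(fx))
    expect_equal(sum(res$quant$molPctTotal), 100, tolerance = 1e-9)
    for (cls in unique(res$quant$lipidClass))
      expect_equal(sum(res$quant$molPctClass[res$quant$lipidClass == cls]),
                   100, tolerance = 1e-9)
    expect_equal(sum(res$classComposition), 100, tolerance = 1e-9)
    expect_equal(sum(res$unsaturationIndex), 100, tolerance = 1e-9)
  }
})
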