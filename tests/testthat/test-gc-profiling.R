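test_that("calibration fitting recovers exact and noisy lines", {
  # exact line amount = 2 * area
  cv <- fitCalibration(data.frame(area = c(1, 2, 3), amount = c(2, 4, 6)))
  expect_equal(cv@slope, 2, tolerance = 1e-12)
  expect_equal(cv@intercept, 0, tolerance = 1e-12)
  # duplicate single point is degenerate
  expect_error(fitCalibration(data.frame(area = c(5, 5), amount = c(1, 2))),
               "distinct")
  expect_error(fitCalibration(data.frame(area = c(1, 2),
                                         amount = c(5, 1))), "positive")
  # hand-computed OLS on 3 points: x = 1,2,3, y = 1.9, 4.1, 5.9
  # slope = Sxy/Sxx = 4/2 = 2, intercept = ybar - slope * xbar = -2/30
  cv <- fitCalibration(data.frame(area = c(1, 2, 3),
                                  amount = c(1.9, 4.1, 5.9)))
  expect_equal(cv@slope, 2, tolerance = 1e-12)
  expect_equal(cv@intercept, 11.9 / 3 - 2 * 2, tolerance = 1e-9)
  # extrapolation outside the fitted range is flagged
  expect_warning(predictAmount(cv, 10), "extrapolation")
})

test_that("retention-time assignment picks unique in-window FAMEs", {
  lib <- data.frame(fame = c("FA 16:0", "FA 16:1"), rt_min = c(23.42, 24.10))
  areas <- identifyFames(data.frame(rt_min = 23.40, area = 100), lib,
                         window = 0.1)
  expect_equal(unname(areas["FA 16:0"]), 100)
  # outside every window: logged, unassigned
  expect_message(
    areas <- identifyFames(data.frame(rt_min = 30, area = 5), lib,
                           window = 0.1),
    "no library FAME")
  expect_length(areas, 0)
  # equidistant between two entries: nearer-by-tie-break lower RT, logged
  lib2 <- data.frame(fame = c("A", "B"), rt_min = c(10.0, 10.5))
  expect_message(
    areas <- identifyFames(data.frame(rt_min = 10.25, area = 7), lib2,
                           window = 0.25),
    "assigned to nearer")
  expect_equal(unname(areas["A"]), 7)
  # library collisions within 2*window are rejected
  lib3 <- data.frame(fame = c("A", "B"), rt_min = c(10.0, 10.1))
  expect_error(identifyFames(data.frame(rt_min = 10, area = 1), lib3,
                             window = 0.1), "collisions")
  expect_error(identifyFames(data.frame(rt_min = 60, area = 1), lib,
                             window = 0.1), "run")
})

test_that("FA percentages normalize amounts and split by saturation", {
  curves <- list(
    "FA 16:0" = fitCalibration(data.frame(area = c(0, 10),
                                          amount = c(0, 10))),
    "FA 18:1n-9c" = fitCalibration(data.frame(area = c(0, 10),
                                              amount = c(0, 10))))
  res <- faPercentages(c("FA 16:0" = 6, "FA 18:1n-9c" = 4), curves)
  expect_equal(unname(res$percentages["FA 16:0"]), 60)
  expect_equal(unname(res$percentages["FA 18:1n-9c"]), 40)
  expect_equal(res$saturated, 60)
  expect_equal(res$unsaturated, 40)
  # only saturated FAMEs: saturated total 100
  res <- faPercentages(c("FA 16:0" = 6), curves["FA 16:0"])
  expect_equal(res$saturated, 100)
  expect_error(faPercentages(c("FA 18:0" = 1), curves), "FA 18:0")
  # weight basis weights by the free-acid mass
  resW <- faPercentages(c("FA 16:0" = 5, "FA 18:1n-9c" = 5), curves,
                        basis = "weight")
  expect_lt(unname(resW$percentages["FA 16:0"]), 50)
})

test_that("ANOVA and Fisher's LSD match hand-computed sums of squares", {
  # printed 3x3 toy table: groups a = (1,2,3), b = (2,3,4), c = (6,7,8)
  # grand mean 4, SSB = 3*((2-4)^2 + (3-4)^2 + (7-4)^2) = 42, SSW = 6
  # F = (42/2) / (6/6) = 21
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res <- anovaFisherLsd(g, alpha = 0.01)
  expect_equal(res$F, 21, tolerance = 1e-12)
  expect_equal(res$mse, 1, tolerance = 1e-12)
  expect_equal(res$dfBetween, 2)
  expect_equal(res$dfWithin, 6)
  # LSD t for a-vs-c: diff -5, se = sqrt(1 * (1/3 + 1/3))
  ac <- res$pairs[res$pairs$groupA == "a" & res$pairs$groupB == "c", ]
  expect_equal(ac$t, -5 / sqrt(2 / 3), tolerance = 1e-12)
  expect_true(ac$significant)

  # identical groups: F = 0, nothing flagged
  same <- anovaFisherLsd(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_false(any(same$pairs$significant))

  # separated groups with tiny jitter are flagged at 0.01
  far <- anovaFisherLsd(list(a = c(0, 0.01, -0.01), b = c(10, 10.01, 9.99)),
                        alpha = 0.01)
  expect_true(all(far$pairs$significant))

  expect_error(anovaFisherLsd(list(a = 1, b = c(1, 2))), "replicates")
  expect_error(anovaFisherLsd(list(a = c(1, 2))), "2 groups")
})

test_that("ANOVA agrees with a brute-force oracle on random tables", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(2:5, 1), i, 1))
    names(groups) <- paste0("g", seq_len(k))
    res <- anovaFisherLsd(groups)
    # brute-force sums of squares
    all <- unlist(groups)
    gm <- mean(all)
    ssb <- sum(vapply(groups, function(g)
      length(g) * (mean(g) - gm)^2, 0))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    fOracle <- (ssb / (k - 1)) / (ssw / (length(all) - k))
    expect_equal(res$F, fOracle, tolerance = 1e-10)
  }
})

test_that("the packaged RT library and calibration cover each other", {
  lib <- defaultRtLibrary()
  curves <- defaultCalibration()
  expect_true(all(lib$fame %in% names(curves)))
  expect_true(all(diff(sort(lib$rt_min)) >= 0.2))
  expect_true(all(lib$carbons >= 4 & lib$carbons <= 24))
  expect_true(all(vapply(curves, function(cv) cv@slope > 0, TRUE)))
})

test_that("GC input readers validate their columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(rt_min = c(21.4, 25.8),
                                area = c(100, 50)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(readGcPeaks(path)), 2L)
  utils::write.table(data.frame(x = 1), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readGcPeaks(path), "rt_min")
  expect_error(readRtLibrary(path), "fame")
  utils::write.table(data.frame(fame = "FA 16:0", area = c(1, 2),
                                amount = c(2, 4)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- readCalibrationTable(path)
  expect_equal(curves[["FA 16:0"]]@slope, 2, tolerance = 1e-12)
})
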