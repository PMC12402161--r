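# synthetic-data generators: squeeze model truths, plate ground truth,
# traces, and seeded reproducibility

test_that("squeeze model obeys projected-area conservation and retention", {
  geom <- tinyGeometry()
  p <- squeezeModelParams(baselineDiameterMean = 15, baselineDiameterSd = 0,
                          retentionFraction = 0, seed = 1)
  out <- generateTransitSequence(geom, p, 4)
  tr <- out$truth
  # no contact in a 30 um channel for a 15 um cell
  expect_equal(tr$di[tr$region == "CC_30"], rep(1, 4))
  # w = 5: major = D0^2 / w = 45, DI = 3 (area conservation solved by hand)
  expect_equal(tr$major[tr$region == "CC_5"], rep(45, 4), tolerance = 1e-12)
  expect_equal(tr$di[tr$region == "CC_5"], rep(3, 4), tolerance = 1e-12)
  # rho = 0: full recovery in every relaxation chamber
  rc <- grepl("^RC_", tr$region)
  expect_equal(tr$di[rc], rep(1, sum(rc)))
  # area conserved in every region
  expect_equal(tr$major * tr$minor, rep(15^2, nrow(tr)), tolerance = 1e-9)
})

test_that("ground-truth DI in constriction channels is non-increasing in width", {
  geom <- tinyGeometry()
  p <- squeezeModelParams(baselineDiameterMean = 16, baselineDiameterSd = 1,
                          seed = 3)
  tr <- generateTransitSequence(geom, p, 10)$truth
  med <- sapply(c("CC_30", "CC_20", "CC_10", "CC_5"),
                function(r) median(tr$di[tr$region == r]))
  expect_true(all(diff(med) >= 0))
  # retention interpolates between recovery and retention
  p2 <- squeezeModelParams(baselineDiameterMean = 15, baselineDiameterSd = 0,
                           retentionFraction = 1, seed = 1)
  tr2 <- generateTransitSequence(geom, p2, 2)$truth
  expect_equal(tr2$di[tr2$region == "RC_5"],
               tr2$di[tr2$region == "CC_5"])
})

test_that("transit generation is bit-identical under the same seed", {
  geom <- tinyGeometry()
  p <- squeezeModelParams(seed = 42)
  a <- generateTransitSequence(geom, p, 3)
  b <- generateTransitSequence(geom, p, 3)
  expect_identical(a$truth, b$truth)
  expect_identical(imgData(a$stacks[["CC_5"]]), imgData(b$stacks[["CC_5"]]))
  # degenerate inputs
  empty <- generateTransitSequence(geom, p, 0)
  expect_identical(nrow(empty$truth), 0L)
  expect_length(empty$stacks, 0)
  expect_error(deviceGeometry(channelWidths = c(30, 20, -1)), "positive")
  expect_error(deviceGeometry(channelWidths = c(30, 20, 10, 5),
                              pixelSize = 7), "pixel")
})

test_that("IF plate ground truth matches the requested design", {
  spec <- plateSpec(nWells = 4, cellsPerWell = 5, seed = 2)
  plate <- generateIFPlate(spec)
  expect_equal(nrow(plate$truth), 20)   # 5 cells/well x 4 wells
  # effect size 1 for all markers: true treated/control ratio ~ 1
  big <- generateIFPlate(plateSpec(nWells = 8, cellsPerWell = 30, seed = 4))
  tr <- big$truth
  rat <- mean(tr$true_nuc_CD44[tr$condition == "squeeze"]) /
    mean(tr$true_nuc_CD44[tr$condition == "control"])
  expect_equal(rat, 1, tolerance = 0.2)  # cell-to-cell CV at n = 120/group
  # compartment design: nuclear mean 120, cytoplasmic 60 -> true N:C = 2
  expect_equal(median(tr$true_nuc_CD44 / tr$true_cyto_CD44), 2,
               tolerance = 1e-9)
  expect_error(plateSpec(effectSize = c(CD44 = -1, ABCB5 = 1)),
               "effect size")
  # seeded reproducibility
  p2 <- generateIFPlate(spec)
  expect_identical(imgData(plate$wells[[1]]), imgData(p2$wells[[1]]))
})

test_that("flatfield-corrupted images average back to the truth (Monte-Carlo)", {
  n <- 48
  truthImg <- ellipseImage(n, n, 14, 14, 8, 8, fg = 150, bg = 0) +
    ellipseImage(n, n, 34, 30, 7, 9, fg = 90, bg = 0)
  ff <- makeFF <- {
    ctr <- (n - 1) / 2
    r2 <- outer(((0:(n - 1)) - ctr)^2, ((0:(n - 1)) - ctr)^2, "+")
    f <- 1 - 0.4 * r2 / max(r2); f / mean(f)
  }
  dk <- matrix(6, n, n)
  set.seed(9)
  acc <- matrix(0, n, n)
  nDraws <- 150
  for (i in seq_len(nDraws)) {
    obs <- CellSqueeze:::addCameraNoise(truthImg * ff + dk,
                                        readSd = 3, photonScale = 0.5)
    acc <- acc + obs
  }
  recovered <- (acc / nDraws - dk) / ff
  # within Monte-Carlo noise tolerance of the true image
  sdMax <- sqrt(3^2 + 0.5 * max(truthImg)) / sqrt(nDraws)
  expect_lt(max(abs(recovered - truthImg)), 6 * sdMax + 0.5)
})

test_that("calcium, permeability and sphere generators encode their truths", {
  # flat amplitude 1 -> flat trace (noise-free) with fold change 1
  sim <- generateCalciumSeries(baseline = 100,
                               regionAmplitudes = c(CC_10 = 1, CC_5 = 1),
                               noiseSd = 0, seed = 1)
  expect_true(all(sim$traces[[1]]$intensity == 100))
  expect_true(all(sim$truth$foldChange == 1))
  # baseline 100, amplitude 1.5 -> peak 150, piecewise-constant
  sim2 <- generateCalciumSeries(baseline = 100,
                                regionAmplitudes = c(CC_5 = 1.5),
                                noiseSd = 0, seed = 1)
  expect_equal(max(sim2$traces[[1]]$intensity), 150)
  expect_setequal(unique(sim2$traces[[1]]$intensity), c(100, 150))
  expect_error(generateCalciumSeries(regionAmplitudes = c(CC_5 = -1)),
               "amplitude")
  # permeability: P = 0 -> identically zero; linear regime ~ P*S/V*Iv*t
  z <- generatePermeabilitySeries(0, sOverV = 2, iVessel = 1000)
  expect_true(all(z$intensity == 0))
  lin <- generatePermeabilitySeries(1e-6, sOverV = 2, iVessel = 1000)
  k <- 1e-6 * 2
  approxLin <- 1000 * k * lin$time * 60
  expect_equal(lin$intensity, approxLin,
               tolerance = 0.02)     # first-order expansion of 1 - exp(-kt)
  expect_error(generatePermeabilitySeries(1e-6, duration = -5), "duration")
  # spheres: linear growth arithmetic and degenerate rate
  sp <- generateTumorsphereSeries(1000, 500, days = 7, noiseSd = 0, seed = 1)
  expect_equal(sp$trueAreas$area[sp$trueAreas$day == 7], 4500)
  flat <- generateTumorsphereSeries(1000, 0, days = 3, noiseSd = 0, seed = 1)
  expect_true(all(flat$trueAreas$area == 1000))
  expect_error(generateTumorsphereSeries(1000, -200, days = 7), "area")
})
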