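# imaging: thresholding, illumination, segmentation, feature extraction

test_that("mceThreshold separates a bimodal histogram and rejects constants", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- mceThreshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_error(mceThreshold(matrix(5, 4, 4)), "constant")
})

test_that("mceThreshold equals the exhaustive-search oracle on 8-bit images", {
  set.seed(7)
  for (i in 1:20) {
    v <- c(pmin(pmax(round(rnorm(200, 40, 15)), 0), 255),
           pmin(pmax(round(rnorm(100, 180, 25)), 0), 255))
    img <- matrix(sample(v), 20, 15)
    thr <- mceThreshold(img)
    oracle <- mceOracle(as.numeric(img))
    # identical foreground partition
    expect_identical(img > thr, img > oracle)
  }
})

test_that("illumination correction inverts the forward model exactly", {
  set.seed(3)
  truthImg <- matrix(runif(400, 0, 100), 20, 20)
  ff <- matrix(runif(400, 0.6, 1.4), 20, 20); ff <- ff / mean(ff)
  dk <- matrix(4, 20, 20)
  obs <- imageStack(truthImg * ff + dk)
  model <- illuminationModel(flatfield = list(ch1 = ff),
                             darkfield = list(ch1 = dk))
  corr <- correctIllumination(obs, model)
  expect_equal(imgData(corr)[, , 1, 1], truthImg, tolerance = 1e-12)
  # identity model passes input through; shape mismatch errors
  idm <- illuminationModel(flatfield = list(ch1 = matrix(1, 20, 20)),
                           darkfield = list(ch1 = matrix(0, 20, 20)))
  expect_identical(imgData(correctIllumination(obs, idm)), imgData(obs))
  small <- illuminationModel(flatfield = list(ch1 = matrix(1, 5, 5)),
                             darkfield = list(ch1 = matrix(0, 5, 5)))
  expect_error(correctIllumination(obs, small), "shape")
  # negative residuals clamp at zero and are counted
  dk2 <- illuminationModel(flatfield = list(ch1 = matrix(1, 20, 20)),
                           darkfield = list(ch1 = matrix(1000, 20, 20)))
  cc <- correctIllumination(obs, dk2)
  expect_true(all(imgData(cc) >= 0))
  expect_equal(cc@metadata$clampedPixels, 400L)
})

test_that("estimateIllumination recovers injected vignetting and darkfield", {
  plate <- generateIFPlate(plateSpec(nWells = 48, cellsPerWell = 40,
                                     vignettingStrength = 0.5, seed = 11))
  mod <- estimateIllumination(plateChannelStack(plate, c("ACTIN", "CD44")))
  for (ch in c("ACTIN", "CD44")) {
    ffE <- flatfield(mod)[[ch]]
    # injected 2x corner vignetting: corner/centre ratio 0.5 +- 5%
    expect_equal(ffE[1, 1] / ffE[128, 128], 0.5, tolerance = 0.05 / 0.5)
    expect_equal(mean(ffE), 1, tolerance = 1e-6)
  }
  # darkfield level 5 recovered to within the coverage-induced bias
  expect_equal(mean(darkfield(mod)$ACTIN), 5, tolerance = 0.4)
})

test_that("estimateIllumination is ~1 under uniform illumination and handles degenerate input", {
  plate <- generateIFPlate(plateSpec(nWells = 48, cellsPerWell = 40,
                                     vignettingStrength = 0, seed = 12))
  mod <- estimateIllumination(plateChannelStack(plate, "ACTIN"))
  expect_lt(max(abs(flatfield(mod)$ACTIN - 1)), 0.01)
  # darkfield 10, content 0 -> darkfield ~ 10, identity flatfield + warning
  set.seed(1)
  d <- array(10 + rnorm(32 * 32 * 12, 0, 1), c(32, 32, 1, 12))
  st <- imageStack(d, channelNames = "empty")
  expect_warning(m0 <- estimateIllumination(st), "foreground")
  expect_equal(mean(darkfield(m0)$empty), 10, tolerance = 0.2)
  expect_true(all(flatfield(m0)$empty == 1))
  # all-zero channel -> identity model with warning
  z <- imageStack(array(0, c(16, 16, 1, 9)), channelNames = "zero")
  expect_warning(mz <- estimateIllumination(z), "zero")
  expect_true(all(flatfield(mz)$zero == 1))
  # single frame -> warning
  s1 <- imageStack(array(runif(256, 1, 2), c(16, 16, 1, 1)))
  expect_warning(estimateIllumination(s1), "frame")
})

test_that("segmentNuclei finds disjoint nuclei and splits touching ones", {
  img <- ellipseImage(60, 80, 15, 20, 8, 8) +
    ellipseImage(60, 80, 40, 55, 8, 8, bg = 0)
  mask <- segmentNuclei(img, minArea = 20)
  expect_equal(nLabels(mask), 2L)
  f <- extractFeatures(mask)
  expect_lt(max(abs(sort(f$centroid_y_px) - c(15, 40))), 1)
  expect_lt(max(abs(sort(f$centroid_x_px) - c(20, 55))), 1)
  # blank image -> zero labels, not an error
  blank <- matrix(0, 30, 30)
  expect_equal(nLabels(segmentNuclei(blank)), 0L)
  # touching peanut splits into two with the watershed
  peanut <- ellipseImage(40, 60, 20, 20, 9, 9) +
    ellipseImage(40, 60, 20, 34, 9, 9, bg = 0)
  expect_equal(nLabels(segmentNuclei(peanut, splitTouching = TRUE)), 2L)
  expect_equal(nLabels(segmentNuclei(peanut, splitTouching = FALSE)), 1L)
})

test_that("segmentCells partitions foreground around nucleus seeds", {
  dapi <- ellipseImage(60, 80, 20, 20, 5, 5) +
    ellipseImage(60, 80, 40, 60, 5, 5, bg = 0)
  body <- ellipseImage(60, 80, 20, 20, 11, 11) +
    ellipseImage(60, 80, 40, 60, 11, 11, bg = 0)
  nuc <- segmentNuclei(dapi, minArea = 10)
  cells <- segmentCells(body, nuc)
  expect_equal(nLabels(cells), 2L)
  # every nucleus lives inside its own cell label
  nm <- maskData(nuc); cm <- maskData(cells)
  expect_true(all(cm[nm > 0] == nm[nm > 0]))
  # labels partition the body foreground
  thr <- mceThreshold(body)
  expect_true(all((cm > 0) == (body > thr | nm > 0)))
  # zero seeds -> zero cells
  empty <- segmentCells(body, segmentNuclei(matrix(0, 60, 80)))
  expect_equal(nLabels(empty), 0L)
  # nucleus outside the body foreground is its own flagged cell
  dapi2 <- ellipseImage(60, 80, 20, 20, 5, 5)
  body2 <- matrix(0, 60, 80)
  nuc2 <- segmentNuclei(dapi2, minArea = 10)
  cells2 <- segmentCells(body2, nuc2)
  expect_equal(maskFlags(cells2)$nucleusOnly, 1L)
})

test_that("cytoplasm subtraction satisfies the exact set identity", {
  dapi <- ellipseImage(50, 50, 25, 25, 6, 6)
  body <- ellipseImage(50, 50, 25, 25, 12, 12)
  nuc <- segmentNuclei(dapi, minArea = 10)
  cells <- segmentCells(body, nuc)
  cyto <- deriveCytoplasm(cells, nuc)
  cm <- maskData(cells); nm <- maskData(nuc); ym <- maskData(cyto)
  # pixelwise set-difference oracle: cyto = cell minus nucleus, disjoint
  expect_identical(ym > 0, cm > 0 & nm == 0)
  expect_equal(sum(cm == 1), sum(nm == 1) + sum(ym == 1))
  # nucleus == cell -> empty cytoplasm, flagged
  cyN <- deriveCytoplasm(nuc, nuc)
  expect_equal(nLabels(cyN), 0L)
  expect_equal(maskFlags(cyN)$emptyCytoplasm, 1L)
})

test_that("segmentSpheres measures disk areas in physical units", {
  img <- ellipseImage(140, 140, 70, 70, 50, 50, fg = 80, bg = 200) # dark disk
  res <- segmentSpheres(img, pixelSize = 1, polarity = "dark")
  expect_equal(nrow(res$areas), 1)
  expect_equal(res$areas$area_um2, pi * 50^2, tolerance = 0.02)
  # blank -> no spheres
  expect_equal(nrow(segmentSpheres(matrix(200, 50, 50))$areas), 0)
  # two disks with correct area ordering
  two <- matrix(200, 160, 300)
  rr <- row(two) - 1; cc <- col(two) - 1
  two[(rr - 80)^2 + (cc - 75)^2 <= 50^2] <- 80
  two[(rr - 80)^2 + (cc - 225)^2 <= 30^2] <- 80
  r2 <- segmentSpheres(two, pixelSize = 2)
  expect_equal(nrow(r2$areas), 2)
  expect_equal(sort(r2$areas$area_um2),
               sort(c(pi * 100^2, pi * 60^2)), tolerance = 0.03)
})

test_that("moment-ellipse features recover axes, intensities, and units", {
  img <- ellipseImage(80, 100, 40, 50, 10, 20, fg = 7, bg = 0)
  mask <- labelMask((img > 0) * 1L, pixelSize = 0.5)
  f <- extractFeatures(mask, channels = list(marker = img))
  # semi-axes (20, 10) px -> major 40 px, minor 20 px (+- 1 px)
  expect_equal(f$major_um / 0.5, 40, tolerance = 1 / 40)
  expect_equal(f$minor_um / 0.5, 20, tolerance = 1 / 20)
  # uniform intensity 7 -> mean 7, integrated 7 * area
  expect_equal(f$mean_marker_cell, 7)
  expect_equal(f$integrated_marker_cell, 7 * f$area_cell_um2 / 0.5^2)
  # circle: major == minor, eccentricity ~ 0
  circ <- ellipseImage(50, 50, 25, 25, 12, 12, fg = 1, bg = 0)
  fc <- extractFeatures(labelMask((circ > 0) * 1L), channels = NULL)
  expect_equal(fc$major_um, fc$minor_um, tolerance = 0.01)
  expect_lt(fc$eccentricity, 0.1)
})

test_that("features are invariant to translation and 90-degree rotation", {
  img <- ellipseImage(90, 90, 40, 45, 9, 17, fg = 13, bg = 0)
  base <- extractFeatures(labelMask((img > 0) * 1L),
                          channels = list(ch = img))
  shifted <- matrix(0, 90, 90)
  shifted[11:90, 3:90] <- img[1:80, 1:88]
  fs <- extractFeatures(labelMask((shifted > 0) * 1L),
                        channels = list(ch = shifted))
  rot <- t(img)[ncol(img):1, ]
  fr <- extractFeatures(labelMask((rot > 0) * 1L),
                        channels = list(ch = rot))
  for (col in c("area_cell_um2", "major_um", "minor_um", "mean_ch_cell")) {
    expect_equal(fs[[col]], base[[col]], tolerance = 0.01)
    expect_equal(fr[[col]], base[[col]], tolerance = 0.01)
  }
})
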