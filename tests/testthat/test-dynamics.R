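# calcium fold change and permeability estimation

test_that("calciumFoldChange is max over response / mean baseline", {
  flat <- data.frame(time = 0:9, intensity = rep(50, 10),
                     region = rep(c("BASELINE", "CC_5"), each = 5))
  expect_equal(calciumFoldChange(flat), 1)
  tr <- data.frame(time = 0:9,
                   intensity = c(rep(100, 5), 120, 150, 130, 110, 100),
                   region = rep(c("BASELINE", "CC_5"), each = 5))
  expect_equal(calciumFoldChange(tr), 1.5)
  # scale invariance
  tr2 <- tr; tr2$intensity <- tr$intensity * 7.3
  expect_equal(calciumFoldChange(tr2), calciumFoldChange(tr))
  # baseline must precede the response and be positive
  expect_error(calciumFoldChange(tr, baselineWindow = 6:10,
                                 responseWindow = 1:5), "precede")
  zero <- tr; zero$intensity[1:5] <- 0
  expect_error(calciumFoldChange(zero), "baseline")
})

test_that("injected calcium amplitudes are recovered under noise (Monte-Carlo)", {
  fcs <- vapply(1:100, function(s) {
    sim <- generateCalciumSeries(baseline = 100,
                                 regionAmplitudes = c(CC_10 = 1.2, CC_5 = 1.8),
                                 noiseSd = 1, seed = s)
    calciumFoldChange(sim$traces[[1]], responseWindow = "CC_5")
  }, numeric(1))
  expect_equal(mean(fcs), 1.8, tolerance = 0.05 / 1.8)
})

test_that("permeability estimator is accurate in the linear regime", {
  tr <- generatePermeabilitySeries(1e-5, sOverV = 2, iVessel = 1000,
                                   noiseSd = 0)
  rec <- estimatePermeability(tr, iVessel = 1000, sOverV = 2)
  expect_equal(rec$P, 1e-5, tolerance = 0.02)
  # constant tissue intensity -> P = 0
  const <- data.frame(time = seq(0, 20, 2), intensity = rep(5, 11))
  expect_equal(estimatePermeability(const, 1000, 2)$P, 0)
  # decreasing trace clamps at zero with a flag
  dec <- data.frame(time = seq(0, 20, 2), intensity = seq(50, 0, -5))
  r <- estimatePermeability(dec, 1000, 2)
  expect_equal(r$P, 0)
  expect_match(r$flag, "clamped")
  expect_error(estimatePermeability(dec, iVessel = 10, sOverV = 2), "iVessel")
})

test_that("permeability estimate is monotone over a 100-fold sweep", {
  ps <- 10^seq(-7, -5, length.out = 7)
  est <- vapply(ps, function(p) {
    tr <- generatePermeabilitySeries(p, sOverV = 2, iVessel = 1000)
    estimatePermeability(tr, 1000, 2)$P
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  # documented graceful degradation: bias grows but stays negative
  big <- generatePermeabilitySeries(2e-4, sOverV = 2, iVessel = 1000)
  recBig <- estimatePermeability(big, 1000, 2)
  expect_lt(recBig$P, 2e-4)
  expect_gt(recBig$P, 2e-4 * 0.5)
})
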