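# single-cell profiling statistics

test_that("ncRatio computes log10 N:C with QC for bad denominators", {
  expect_equal(ncRatio(100, 10), 1)
  expect_equal(ncRatio(50, 50), 0)
  expect_equal(ncRatio(50, 200), log10(0.25))
  expect_equal(round(ncRatio(50, 200), 3), -0.602)
  out <- ncRatio(c(10, 10), c(5, 0))
  expect_true(is.na(out[2]))
  expect_match(attr(out, "qc"), "cytoplasmic")
})

test_that("iqrOutlierFilter applies the k*IQR rule per stratum", {
  tab <- data.frame(cell = 1:10, f = c(1:9, 100),
                    condition = "control", timepoint = "0h")
  res <- iqrOutlierFilter(tab, features = "f")
  # Q1 = 3.25, Q3 = 7.75, IQR = 4.5, R = [-3.5, 14.5] -> 100 removed
  expect_equal(res$removed, 10L)
  expect_equal(nrow(res$table), 9)
  expect_equal(res$report$lower, -3.5)
  expect_equal(res$report$upper, 14.5)
  # identical values: IQR 0, nothing removed
  same <- data.frame(cell = 1:6, f = rep(4, 6),
                     condition = "c", timepoint = "t")
  expect_equal(nrow(iqrOutlierFilter(same, features = "f")$table), 6)
  # k = Inf removes nothing
  expect_equal(nrow(iqrOutlierFilter(tab, features = "f", k = Inf)$table), 10)
  # union across features; strata computed independently
  tab2 <- data.frame(cell = 1:12,
                     f1 = c(1:5, 50, 1:6), f2 = c(1:6, 1:5, -40),
                     condition = rep(c("a", "b"), each = 6),
                     timepoint = "t")
  r2 <- iqrOutlierFilter(tab2, features = c("f1", "f2"))
  expect_setequal(r2$removed, c(6L, 12L))
  expect_error(iqrOutlierFilter(data.frame(cell = 1:4, f = c(1, 1, 1, 99),
                                           condition = "c", timepoint = "t"),
                                features = "f", k = 0),
               NA)  # removing some is fine; only removing all is degenerate
})

test_that("robustZ matches the hand-computed convention and is affine invariant", {
  z <- robustZ(c(-1, 0, 1))
  expect_equal(z, c(-1, 0, 1) / 1.4826, tolerance = 1e-9)
  expect_equal(round(z[3], 4), 0.6745)
  x <- rnorm(50)
  expect_equal(robustZ(3 * x + 7), robustZ(x), tolerance = 1e-12)
  expect_warning(zc <- robustZ(rep(2, 10)), "MAD")
  expect_true(all(is.na(zc)))
})

test_that("pcaReduce keeps the smallest component set reaching the variance target", {
  # variance along one axis only -> a single component
  one <- cbind(rnorm(50), 0, 0)
  expect_equal(attr(pcaReduce(one), "nComponents"), 1L)
  # isotropic 3-feature Gaussian -> all 3 needed for 97%
  set.seed(2)
  iso <- matrix(rnorm(900), 300, 3)
  s <- pcaReduce(iso)
  expect_equal(attr(s, "nComponents"), 3L)
  expect_gte(sum(attr(s, "explained")), 0.97)
  # deterministic sign convention
  s2 <- pcaReduce(iso)
  expect_identical(s, s2)
})

test_that("embed2d separates clusters and is seed-deterministic", {
  set.seed(8)
  x <- rbind(matrix(rnorm(120, 0), 60, 2),
             matrix(rnorm(120, 8), 60, 2))
  lab <- rep(1:2, each = 60)
  e1 <- embed2d(x, seed = 4)
  e2 <- embed2d(x, seed = 4)
  expect_identical(e1, e2)
  # silhouette of the true labels in the embedding
  sil <- vapply(seq_len(nrow(e1)), function(i) {
    d <- sqrt(rowSums((e1 - matrix(e1[i, ], nrow(e1), 2, byrow = TRUE))^2))
    a <- mean(d[lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_warning(embed2d(matrix(rnorm(24), 12, 2), seed = 1), "shrinking")
  expect_error(embed2d(matrix(rnorm(10), 5, 2)), "10 rows")
})

test_that("normalizeToControl centers on the control median per stratum", {
  tab <- data.frame(value = c(1, 2, 3, 5), condition = c("control", "control",
                                                         "control", "squeeze"),
                    marker = "CD44", timepoint = "4h")
  out <- normalizeToControl(tab)
  expect_equal(out$value_centered[4], 3)   # control median 2
  # control values center to median zero per stratum
  expect_equal(median(out$value_centered[out$condition == "control"]), 0)
  bad <- data.frame(value = 1, condition = "squeeze",
                    marker = "CD44", timepoint = "4h")
  expect_error(normalizeToControl(bad), "missing control stratum")
})

test_that("markerFoldChange uses the mean-of-means estimator", {
  ctrl <- data.frame(mean_CD44_cell = c(10, 20, 30))
  expect_equal(markerFoldChange(ctrl, ctrl, "CD44"), 1)
  trt <- data.frame(mean_CD44_cell = 2 * c(10, 20, 30))
  expect_equal(markerFoldChange(ctrl, trt, "CD44"), 2)
  expect_error(markerFoldChange(data.frame(mean_CD44_cell = c(0, 0)),
                                trt, "CD44"), "control mean")
})

test_that("injected marker effects are recovered from the sampling layer", {
  tab <- simulateFeatureTable(nCellsPerGroup = 200,
                              markers = "CD44",
                              effectSize = c(CD44 = 1.6), seed = 31)
  fc <- markerFoldChange(tab[tab$condition == "control", ],
                         tab[tab$condition == "squeeze", ],
                         "CD44", compartment = "nucleus")
  expect_equal(fc, 1.6, tolerance = 0.1 / 1.6)
})

test_that("compareGroups adjusts across timepoints within each feature", {
  tab <- simulateFeatureTable(nCellsPerGroup = 40, markers = c("CD44", "ABCB5"),
                              effectSize = c(CD44 = 2, ABCB5 = 1),
                              timepoints = c("1h", "4h", "24h"), seed = 7)
  res <- compareGroups(tab, features = c("mean_CD44_nucleus",
                                         "mean_ABCB5_nucleus"))
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  # the injected CD44 effect is detected at every timepoint
  expect_true(all(res$p_adj[res$feature == "mean_CD44_nucleus"] < 0.01))
  # per-feature family equals BH applied within the feature
  cd44 <- res[res$feature == "mean_CD44_nucleus", ]
  expect_equal(cd44$p_adj, bhAdjust(cd44$p))
})
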