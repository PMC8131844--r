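test_that("nativeBD follows the linear GC relation and checks its domain", {
  expect_equal(nativeBD(0), 1.660)
  expect_equal(nativeBD(0.5), 1.709)
  expect_equal(nativeBD(1), 1.758)
  expect_error(nativeBD(-0.1), "\\[0, 1\\]")
  expect_error(nativeBD(1.2), "\\[0, 1\\]")
})

test_that("labelShift is linear in atom fraction excess", {
  expect_equal(labelShift(1, 0), 0.036)
  expect_equal(labelShift(0, 0), 0)
  expect_equal(labelShift(0.15, 0.09), 0.00684)     # PAOM-type labeling
  expect_equal(labelShift(0, 1), 0.016)
  expect_error(labelShift(1.5, 0), "\\[0, 1\\]")
})

test_that("band profiles conserve mass and respect symmetry", {
  cfg <- gradientConfig()
  mid <- (cfg$bdMin + cfg$bdMax) / 2
  p <- bandProfile(mid, cfg)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(p, rev(p), tolerance = 1e-12)
  for (c0 in c(1.66, 1.70, 1.72, 1.80))
    expect_equal(sum(bandProfile(c0, cfg)), 1, tolerance = 1e-9)
  expect_error(bandProfile(1.70, gradientConfig(bandSd = 0)), "bandSd")
})

test_that("heavier band centers put more mass above 1.70 g/ml", {
  cfg <- gradientConfig(bandSd = 0.005)
  dens <- fractionDensities(cfg)
  heavy <- dens > 1.70
  # independent oracle: fine Riemann sum of the Gaussian over each bin
  riemann <- function(center) {
    edges <- seq(cfg$bdMin, cfg$bdMax, length.out = cfg$nFractions + 1)
    mass <- vapply(seq_len(cfg$nFractions), function(k) {
      xs <- seq(edges[k], edges[k + 1], length.out = 2001)
      sum(dnorm(xs, center, cfg$bandSd)) * diff(xs[1:2])
    }, numeric(1))
    rev(mass / sum(mass))
  }
  for (center in c(1.70, 1.72)) {
    expect_lt(max(abs(bandProfile(center, cfg) - riemann(center))), 1e-4)
  }
  expect_gt(sum(bandProfile(1.72, cfg)[heavy]),
            sum(bandProfile(1.70, cfg)[heavy]))
})

test_that("scenario presets carry the substrate labeling degrees", {
  expect_equal(scenarioPreset("PAOM"), list(afe13C = 0.15, afe15N = 0.09))
  expect_equal(scenarioPreset("protein"), list(afe13C = 0.18, afe15N = 0.07))
  expect_equal(scenarioPreset("acetate"), list(afe13C = 0.50, afe15N = 0.00))
  expect_error(scenarioPreset("glucose"), "PAOM.*protein.*acetate")
})

test_that("community truth sums to 1 and zeroes afe for unlabeled OTUs", {
  tr <- simulateCommunity(100, 0.2, "protein", seed = 5)
  expect_equal(sum(tr$rel_abundance), 1, tolerance = 1e-9)
  expect_true(all(tr$afe_13C[!tr$is_labeled] == 0))
  expect_true(all(tr$afe_15N[!tr$is_labeled] == 0))
  expect_equal(sum(tr$is_labeled), 20)
  expect_true(all(tr$afe_13C[tr$is_labeled] == 0.18))
})

test_that("identical seeds give identical experiments", {
  tr <- simulateCommunity(40, 0.1, seed = 9)
  cfg <- gradientConfig(depthPerFraction = 2000)
  a <- simulateExperiment(tr, cfg, seed = 7)
  b <- simulateExperiment(tr, cfg, seed = 7)
  expect_identical(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
  expect_error(simulateExperiment(rbind(tr, tr[1, ]), cfg, seed = 1),
               "duplicate")
})

test_that("with no labeled OTUs both arms share expected proportions", {
  tr <- simulateCommunity(30, 0, seed = 3)
  cfg <- gradientConfig()
  expect_equal(expectedProportions(tr, cfg, labeled = TRUE),
               expectedProportions(tr, cfg, labeled = FALSE))
})

test_that("expected mean density is non-decreasing in atom fraction excess", {
  cfg <- gradientConfig()
  dens <- fractionDensities(cfg)
  meanDensity <- function(afe13, afe15 = 0) {
    center <- nativeBD(0.4) + labelShift(afe13, afe15)
    sum(dens * bandProfile(center, cfg))
  }
  m13 <- vapply(seq(0, 1, 0.1), meanDensity, numeric(1))
  expect_true(all(diff(m13) >= -1e-12))
  m15 <- vapply(seq(0, 1, 0.1), function(a) meanDensity(0, a), numeric(1))
  expect_true(all(diff(m15) >= -1e-12))
})

test_that("sampled proportions converge to expected proportions at depth 1e6", {
  tr <- simulateCommunity(25, 0.2, seed = 13)
  cfg <- gradientConfig(depthPerFraction = 1e6)
  se <- simulateExperiment(tr, cfg, seed = 13)
  md <- fractionMetadata(se)
  cnt <- SummarizedExperiment::assay(se)
  lab <- md$sample_id[md$isotope == "labeled"]
  obs <- sweep(cnt[, lab], 2, colSums(cnt[, lab]), "/")
  expe <- expectedProportions(tr, cfg, labeled = TRUE)
  expect_lt(max(abs(obs - expe)), 5e-3)
})

test_that("a fully 13C-labeled OTU shifts its counts by the configured 0.036 g/ml", {
  cfg <- gradientConfig()
  dens <- fractionDensities(cfg)
  set.seed(21)
  center <- nativeBD(0.30)          # band fits the collected range in both arms
  drawMean <- function(c0) {
    k <- rmultinom(1, 1e5, bandProfile(c0, cfg))[, 1]
    sum(dens * k) / sum(k)
  }
  gap <- drawMean(center + labelShift(1, 0)) - drawMean(center)
  expect_lt(abs(gap - 0.036), 0.002)
})

test_that("simulated output is a valid SipExperiment with matched metadata", {
  tr <- simulateCommunity(20, 0.1, seed = 2)
  se <- simulateExperiment(tr, gradientConfig(depthPerFraction = 500),
                           seed = 2, timepoints = c(7, 21),
                           treatment = "PAOM")
  expect_s4_class(se, "SipExperiment")
  expect_identical(ncol(se), 48L)   # 2 timepoints x 2 arms x 12 fractions
  md <- fractionMetadata(se)
  expect_setequal(unique(md$gradient),
                  gradientId("PAOM", rep(c(7, 21), each = 2),
                             c("labeled", "control")))
  expect_true(all(colSums(SummarizedExperiment::assay(se)) == 500))
  expect_identical(communityTruth(se)$otu_id, rownames(se))
})
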