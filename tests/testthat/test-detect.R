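test_that("splitWindows partitions strictly at the heavy threshold", {
  md <- makeGradientMeta()           # default 12-fraction grid
  w <- splitWindows(md, 1.70)
  g <- gradientId("sub", 7, "labeled")
  expect_length(w[[g]]$heavy, 7)     # 7 of 12 bin centers exceed 1.70
  expect_length(w[[g]]$light, 5)
  # a fraction at exactly 1.70 is light ("higher than" is strict)
  md2 <- md
  md2$buoyant_density[md2$fraction_index == 6] <- 1.70
  w2 <- splitWindows(md2, 1.70)
  expect_length(w2[[g]]$light, 6)
  # all-heavy threshold is a window error naming the gradient
  expect_error(splitWindows(md, 1.60), "light window")
  expect_error(splitWindows(md, 1.80), "heavy window")
})

test_that("median-of-ratios size factors match brute-force expectations", {
  cnt <- matrix(rep(c(10L, 40L, 200L), 3), 3, 3,
                dimnames = list(paste0("o", 1:3), paste0("s", 1:3)))
  expect_equal(sizeFactorsMedianRatio(cnt), setNames(rep(1, 3), paste0("s", 1:3)))
  # one sample exactly twice the other: factors (sqrt(2), 1/sqrt(2))
  two <- cbind(a = c(10L, 40L, 200L), b = c(20L, 80L, 400L))
  expect_equal(unname(sizeFactorsMedianRatio(two)),
               c(1 / sqrt(2), sqrt(2)))
  # single-OTU table: factors proportional to the counts
  one <- matrix(c(2L, 8L, 4L), 1, dimnames = list("o", c("a", "b", "c")))
  sf <- sizeFactorsMedianRatio(one)
  expect_equal(unname(sf / sf[1]), c(1, 4, 2))
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  cnt <- matrix(rnbinom(600, mu = 50, size = 2), 50, 12,
                dimnames = list(paste0("o", 1:50), paste0("s", 1:12)))
  cnt[1:5, ] <- cnt[1:5, ] + 1L      # ensure some all-positive rows
  expect_equal(unname(sizeFactorsMedianRatio(cnt)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cnt) /
                        exp(mean(log(DESeq2::estimateSizeFactorsForMatrix(cnt))))),
               tolerance = 1e-10)
})

test_that("OTUs absent from one condition are untested", {
  set.seed(7)
  cnt <- matrix(rpois(40, 20), 4, 10,
                dimnames = list(paste0("o", 1:4),
                                c(paste0("L", 1:5), paste0("C", 1:5))))
  cnt[2, 6:10] <- 0L                 # absent from control group
  cnt[3, 1:5] <- 0L                  # absent from labeled group
  r <- testWindow(cnt, paste0("L", 1:5), paste0("C", 1:5))
  expect_false(r$tested[2])
  expect_false(r$tested[3])
  expect_true(all(is.na(r$pvalue[2:3])))
  expect_true(all(is.na(r$log2FoldChange[2:3])))
  expect_true(r$tested[1])
})

test_that("identical groups give zero fold change and one-sided p >= 0.5", {
  set.seed(8)
  block <- matrix(rpois(50, 30), 10, 5)
  cnt <- cbind(block, block)
  dimnames(cnt) <- list(paste0("o", 1:10),
                        c(paste0("L", 1:5), paste0("C", 1:5)))
  r <- testWindow(cnt, paste0("L", 1:5), paste0("C", 1:5))
  expect_equal(r$log2FoldChange, rep(0, 10))
  expect_true(all(r$pvalue >= 0.5))
})

test_that("a 10x-enriched OTU at 1% abundance is detected (Monte-Carlo)", {
  set.seed(71)
  nOtus <- 50
  base <- rlnorm(nOtus, 0, 1); base[1] <- 0.01 * sum(base) / 0.99
  pC <- base / sum(base)
  pL <- base; pL[1] <- pL[1] * 10; pL <- pL / sum(pL)
  hits <- 0L
  for (rep in 1:100) {
    cnt <- cbind(rmultinom(6, 30000, pL), rmultinom(6, 30000, pC))
    dimnames(cnt) <- list(paste0("o", 1:nOtus),
                          c(paste0("L", 1:6), paste0("C", 1:6)))
    r <- testWindow(cnt, paste0("L", 1:6), paste0("C", 1:6))
    if (r$pvalue[1] < 0.01) hits <- hits + 1L
  }
  expect_gt(hits, 95)
})

test_that("swapping group labels negates fold changes and kills significance", {
  set.seed(9)
  pC <- runif(30); pC <- pC / sum(pC)
  pL <- pC * c(8, rep(1, 29)); pL <- pL / sum(pL)
  cnt <- cbind(rmultinom(6, 20000, pL), rmultinom(6, 20000, pC))
  dimnames(cnt) <- list(paste0("o", 1:30),
                        c(paste0("L", 1:6), paste0("C", 1:6)))
  fwd <- testWindow(cnt, paste0("L", 1:6), paste0("C", 1:6))
  rev <- testWindow(cnt, paste0("C", 1:6), paste0("L", 1:6))
  ok <- fwd$tested & rev$tested
  expect_equal(fwd$log2FoldChange[ok], -rev$log2FoldChange[ok],
               tolerance = 1e-9)
  expect_gt(rev$pvalue[1], 0.5)      # enrichment direction destroyed
  expect_lt(fwd$pvalue[1], 0.01)
  expect_error(testWindow(cnt, "L1", paste0("C", 1:6)), "at least 2")
})

test_that("bhAdjust reproduces the step-up definition and handles NAs", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(c(0.001, 1.0)), c(0.002, 1.0))
  # NA (untested) entries are excluded from the family size
  expect_equal(bhAdjust(c(0.001, NA, 1.0)), c(0.002, NA, 1.0))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_identical(bhAdjust(p), bruteForceBH(p))
  }
})

test_that("classification requires heavy enrichment without light enrichment", {
  mk <- function(padjH, padjL) {
    h <- data.frame(otu_id = "o1", log2FoldChange = 1, lfcSE = 0.1, stat = 1,
                    pvalue = padjH, baseMean = 10, tested = TRUE, padj = padjH)
    l <- h; l$padj <- padjL; l$pvalue <- padjL
    classifyLabels(h, l, fdr = 0.10)
  }
  expect_true(mk(0.02, 0.60)$labeled)
  r <- mk(0.02, 0.02)
  expect_false(r$labeled)
  expect_true(r$criterion2_violated)
  expect_match(r$reason, "criterion 2")
  expect_false(mk(0.50, 0.60)$labeled)
  h <- data.frame(otu_id = "a", tested = TRUE, padj = 0.01,
                  log2FoldChange = 1, lfcSE = 1, stat = 1, pvalue = 0.01)
  l <- h; l$otu_id <- "b"
  expect_error(classifyLabels(h, l), "different OTUs")
})

test_that("labeled OTUs rank at the top by heavy fold change", {
  tr <- simulateCommunity(200, 0.1, "acetate", seed = 55)
  se <- simulateExperiment(tr, gradientConfig(), seed = 55,
                           treatment = "acetate")
  res <- detectLabeledOTUs(se)
  calls <- res$calls
  truth <- communityTruth(se)
  lab <- truth$otu_id[truth$is_labeled & truth$rel_abundance >= 0.005]
  expect_gte(length(lab), 1)
  ranked <- calls$otu_id[order(-calls$heavy_log2fc)]
  expect_true(all(lab %in% ranked[1:30]))
})

test_that("verdicts are monotone in fdr and in the fold-change null", {
  tr <- simulateCommunity(150, 0.1, "acetate", seed = 66)
  se <- simulateExperiment(tr, gradientConfig(), seed = 66)
  base <- detectLabeledOTUs(se, fdr = 0.10, lfcNull = 0.25)$calls
  strictFdr <- detectLabeledOTUs(se, fdr = 0.05, lfcNull = 0.25)$calls
  strictNull <- detectLabeledOTUs(se, fdr = 0.10, lfcNull = 1.0)$calls
  expect_true(all(strictFdr$otu_id[strictFdr$labeled] %in%
                    base$otu_id[base$labeled]))
  expect_true(all(strictNull$otu_id[strictNull$labeled] %in%
                    base$otu_id[base$labeled]))
})

test_that("detect errors when a comparison lacks its control gradient", {
  tr <- simulateCommunity(30, 0.1, seed = 4)
  se <- simulateExperiment(tr, gradientConfig(depthPerFraction = 1000),
                           seed = 4)
  md <- fractionMetadata(se)
  onlyLab <- se[, md$isotope == "labeled"]
  expect_error(detectLabeledOTUs(onlyLab, preprocess = FALSE),
               "missing control")
})
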