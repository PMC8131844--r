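#' Partition gradient fractions into heavy and light windows
#'
#' Heavy fractions are those with buoyant density strictly greater than
#' `heavyThreshold` (1.70 g/ml by convention); the light window is the
#' complement (density <= threshold, unbounded below).
#'
#' @param metadata fraction metadata `data.frame` (needs `sample_id`,
#'   `gradient`, `buoyant_density`), e.g. [fractionMetadata()].
#' @param heavyThreshold density cutoff, g/ml.
#' @return named list (one element per gradient) of lists with `heavy` and
#'   `light` sample-id vectors. A gradient with an empty window is an error.
#' @export
splitWindows <- function(metadata, heavyThreshold = 1.70) {
  metadata <- as.data.frame(metadata)
  if (anyNA(metadata$buoyant_density))
    stop("every fraction needs a buoyant_density")
  if (is.null(metadata$gradient))
    metadata$gradient <- gradientId(metadata$treatment,
                                    metadata$timepoint_days,
                                    metadata$isotope)
  out <- lapply(split(metadata, metadata$gradient), function(g) {
    heavy <- g$sample_id[g$buoyant_density > heavyThreshold]
    light <- g$sample_id[g$buoyant_density <= heavyThreshold]
    if (length(heavy) == 0 || length(light) == 0)
      stop("gradient '", g$gradient[1L], "' has an empty ",
           if (length(heavy) == 0) "heavy" else "light",
           " window at threshold ", heavyThreshold, " g/ml")
    list(heavy = heavy, light = light)
  })
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors correcting for sequencing-depth and composition
#' differences: the reference is the per-OTU geometric mean over samples,
#' restricted to OTUs positive in every sample; each sample's factor is the
#' median of its count/reference ratios, rescaled so the factors have
#' geometric mean 1. When no OTU is positive in all samples the reference
#' falls back to OTUs positive in at least half of the samples (with a
#' warning); ratios at reference zeros are skipped.
#'
#' @param counts integer matrix, OTUs x samples.
#' @return numeric vector of size factors, one per column.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("need at least one sample")
  posAll <- rowSums(counts > 0) == ncol(counts)
  if (!any(posAll)) {
    posAll <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(posAll))
      stop("no OTU positive in at least half of the samples")
    warning("no OTU positive in all samples; ",
            "reference restricted to OTUs positive in >= 50% of samples")
  }
  sub <- counts[posAll, , drop = FALSE]
  logRef <- rowMeans(log(ifelse(sub > 0, sub, NA)), na.rm = TRUE)
  sf <- apply(sub, 2L, function(cl) {
    r <- log(cl) - logRef
    r <- r[is.finite(r)]
    if (length(r) == 0) stop("cannot compute a size factor: no finite ratios")
    exp(median(r))
  })
  sf / exp(mean(log(sf)))
}

#' One-sided negative-binomial Wald test between two fraction groups
#'
#' The per-OTU heavy-window (or light-window) comparison of a labeled
#' gradient against its control. Counts are normalized by median-of-ratios
#' size factors computed on the tested samples; group means are compared on
#' the log2 scale against a fold-change null `lfcNull`, with the alternative
#' `log2FC > lfcNull` (enrichment in the labeled gradient).
#'
#' Per-OTU dispersion is a method-of-moments estimate from the pooled
#' within-group variance of normalized counts, shrunk 50/50 toward a
#' mean-dispersion trend (`a0 + a1/mean`, fitted across OTUs) and floored at
#' 1e-8; OTUs with non-positive moment estimates use the trend (Poisson-like
#' floor). Standard errors come from the delta method on the group means.
#'
#' OTUs with zero counts in either condition (by default, zero in the tested
#' group; pass `detectedLabeled`/`detectedControl` flags computed over whole
#' incubations for the conventional reading) are marked `tested = FALSE` and
#' get no statistics. When an OTU is tested but one window group mean is 0,
#' a +0.5 pseudo-mean stabilizes the fold change.
#'
#' @param counts integer matrix (OTUs x samples) covering at least the tested
#'   sample ids.
#' @param labeledIds,controlIds sample ids of the two groups (>= 2 each).
#' @param lfcNull log2 fold-change null threshold (default 0.25).
#' @param detectedLabeled,detectedControl optional logical vectors (one per
#'   OTU): was the OTU detected anywhere in the labeled / control incubation?
#'   Defaults to detection within the tested groups.
#' @return `data.frame` with `otu_id`, `log2FoldChange`, `lfcSE`, `stat`,
#'   `pvalue`, `baseMean` (mean normalized count over tested samples) and
#'   `tested`.
#' @export
testWindow <- function(counts, labeledIds, controlIds, lfcNull = 0.25,
                       detectedLabeled = NULL, detectedControl = NULL) {
  counts <- as.matrix(counts)
  if (length(labeledIds) < 2L || length(controlIds) < 2L)
    stop("each group needs at least 2 samples")
  bad <- setdiff(c(labeledIds, controlIds), colnames(counts))
  if (length(bad))
    stop("sample id(s) not in count table: ", paste(bad, collapse = ", "))
  sub <- counts[, c(labeledIds, controlIds), drop = FALSE]
  sf <- sizeFactorsMedianRatio(sub)
  norm <- sweep(sub, 2L, sf, "/")
  iL <- seq_along(labeledIds)
  iC <- length(labeledIds) + seq_along(controlIds)
  nL <- length(iL); nC <- length(iC)

  if (is.null(detectedLabeled))
    detectedLabeled <- rowSums(sub[, iL, drop = FALSE]) > 0
  if (is.null(detectedControl))
    detectedControl <- rowSums(sub[, iC, drop = FALSE]) > 0
  tested <- detectedLabeled & detectedControl

  muL <- rowMeans(norm[, iL, drop = FALSE])
  muC <- rowMeans(norm[, iC, drop = FALSE])
  varL <- apply(norm[, iL, drop = FALSE], 1L, var)
  varC <- apply(norm[, iC, drop = FALSE], 1L, var)
  s2 <- ((nL - 1) * varL + (nC - 1) * varC) / (nL + nC - 2)
  mu <- (nL * muL + nC * muC) / (nL + nC)

  # method-of-moments dispersion: Var(K/s) ~ mu * mean(1/s) + alpha * mu^2
  invsL <- mean(1 / sf[iL]); invsC <- mean(1 / sf[iC])
  invsAll <- mean(1 / sf)
  alphaMM <- ifelse(mu > 0, (s2 - mu * invsAll) / mu^2, NA_real_)
  ok <- tested & is.finite(alphaMM) & alphaMM > 0 & mu > 0
  if (sum(ok) >= 3) {
    tr <- lm(alphaMM[ok] ~ I(1 / mu[ok]))
    a0 <- max(coef(tr)[1L], 1e-8); a1 <- max(coef(tr)[2L], 0)
  } else {
    a0 <- if (any(ok)) mean(alphaMM[ok]) else 0.01
    a1 <- 0
  }
  alphaTrend <- pmax(a0 + a1 / pmax(mu, 1e-8), 1e-8)
  alpha <- ifelse(is.finite(alphaMM) & alphaMM > 0,
                  0.5 * alphaMM + 0.5 * alphaTrend, alphaTrend)
  alpha <- pmax(alpha, 1e-8)

  # +0.5 pseudo-mean only for tested OTUs with a zero window-group mean
  muLs <- ifelse(tested & muL == 0, 0.5, muL)
  muCs <- ifelse(tested & muC == 0, 0.5, muC)
  l2fc <- log2(muLs / muCs)
  vLogL <- (muLs * invsL + alpha * muLs^2) / (nL * muLs^2)
  vLogC <- (muCs * invsC + alpha * muCs^2) / (nC * muCs^2)
  se <- sqrt(vLogL + vLogC) / log(2)
  stat <- (l2fc - lfcNull) / se
  p <- pnorm(stat, lower.tail = FALSE)

  out <- data.frame(
    otu_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2FoldChange = ifelse(tested, l2fc, NA_real_),
    lfcSE = ifelse(tested, se, NA_real_),
    stat = ifelse(tested, stat, NA_real_),
    pvalue = ifelse(tested, p, NA_real_),
    baseMean = mu, tested = tested,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment with untested entries excluded
#'
#' Step-up BH over the non-missing p-values (NA entries, i.e. untested OTUs,
#' do not count toward the family size m); output is in input order with NAs
#' preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  out[idx] <- p.adjust(p[idx], method = "BH")
  out
}

#' Dual-criterion labeled/unlabeled verdict
#'
#' An OTU is called labeled when (1) it is significantly more abundant in the
#' heavy fractions of the labeled gradient than of the control gradient
#' (heavy adjusted p < `fdr`), and (2) it is NOT significantly more abundant
#' in the light fractions (light adjusted p >= `fdr`). Criterion 2 guards
#' against whole-gradient compositional differences between the paired
#' incubations. Untested OTUs are never labeled and carry a reason.
#'
#' @param heavy,light `data.frame`s from [testWindow()] for the two windows,
#'   each with a `padj` column (see [bhAdjust()]), same OTUs in the same
#'   order.
#' @param fdr false-discovery-rate threshold on adjusted p-values
#'   (default 0.10).
#' @return `data.frame` with per-OTU heavy/light statistics, `criterion1`,
#'   `criterion2_violated`, `labeled` and `reason`.
#' @export
classifyLabels <- function(heavy, light, fdr = 0.10) {
  if (!identical(heavy$otu_id, light$otu_id))
    stop("heavy and light results refer to different OTUs")
  if (is.null(heavy$padj) || is.null(light$padj))
    stop("results must carry BH-adjusted p-values (padj)")
  c1 <- heavy$tested & !is.na(heavy$padj) & heavy$padj < fdr
  c2v <- light$tested & !is.na(light$padj) & light$padj < fdr
  labeled <- c1 & !c2v
  reason <- rep("", length(labeled))
  reason[!heavy$tested] <- "not detected in both incubations"
  reason[heavy$tested & !c1] <- "no significant heavy enrichment"
  reason[c1 & c2v] <- "significant light enrichment (criterion 2)"
  data.frame(
    otu_id = heavy$otu_id,
    heavy_log2fc = heavy$log2FoldChange, heavy_se = heavy$lfcSE,
    heavy_stat = heavy$stat, heavy_p = heavy$pvalue, heavy_padj = heavy$padj,
    light_log2fc = light$log2FoldChange, light_se = light$lfcSE,
    light_p = light$pvalue, light_padj = light$padj,
    tested = heavy$tested & light$tested,
    criterion1 = c1, criterion2_violated = c2v,
    labeled = labeled, reason = reason,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect labeled OTUs across all labeled/control comparisons
#'
#' The full HRSIP analysis: hygiene filters, heavy/light window split at
#' `heavyThreshold`, one-sided negative-binomial Wald tests of each labeled
#' gradient against its paired control in both windows, BH adjustment within
#' each (comparison, window) family, and the dual-criterion verdict.
#'
#' @param x a [SipExperiment-class].
#' @param heavyThreshold heavy-window density cutoff, g/ml (default 1.70).
#' @param fdr FDR threshold on adjusted p-values (default 0.10).
#' @param lfcNull log2 fold-change null (default 0.25).
#' @param comparisons optional `data.frame` with columns `treatment` and
#'   `timepoint_days`; defaults to every pair present with both isotope arms.
#' @param preprocess apply [preprocessSip()] first (default TRUE).
#' @param ... passed to [preprocessSip()].
#' @return object of class `SipDetectResult`: list with `calls` (combined
#'   long-format table over comparisons), `se` (the filtered
#'   `SipExperiment`), `report` (filter report or NULL) and `params`.
#' @examples
#' tr <- simulateCommunity(50, 0.2, "acetate", seed = 3)
#' se <- simulateExperiment(tr, gradientConfig(depthPerFraction = 5000), seed = 3)
#' res <- detectLabeledOTUs(se)
#' table(res$calls$labeled)
#' @export
detectLabeledOTUs <- function(x, heavyThreshold = 1.70, fdr = 0.10,
                              lfcNull = 0.25, comparisons = NULL,
                              preprocess = TRUE, ...) {
  report <- NULL
  if (preprocess) {
    pp <- preprocessSip(x, ...)
    x <- pp$se; report <- pp$report
  }
  md <- fractionMetadata(x)
  if (is.null(comparisons)) {
    comparisons <- unique(md[, c("treatment", "timepoint_days")])
    comparisons <- comparisons[order(comparisons$treatment,
                                     comparisons$timepoint_days), ,
                               drop = FALSE]
  }
  windows <- splitWindows(md, heavyThreshold)
  counts <- assay(x, "counts")
  calls <- NULL
  for (k in seq_len(nrow(comparisons))) {
    tr <- comparisons$treatment[k]; tp <- comparisons$timepoint_days[k]
    gLab <- gradientId(tr, tp, "labeled")
    gCtl <- gradientId(tr, tp, "control")
    if (!gLab %in% md$gradient || !gCtl %in% md$gradient)
      stop("comparison ", tr, " T", tp,
           ": missing ", if (gLab %in% md$gradient) "control" else "labeled",
           " gradient")
    labAll <- md$sample_id[md$gradient == gLab]
    ctlAll <- md$sample_id[md$gradient == gCtl]
    detLab <- rowSums(counts[, labAll, drop = FALSE]) > 0
    detCtl <- rowSums(counts[, ctlAll, drop = FALSE]) > 0
    res <- lapply(c(heavy = "heavy", light = "light"), function(w) {
      r <- testWindow(counts, windows[[gLab]][[w]], windows[[gCtl]][[w]],
                      lfcNull = lfcNull,
                      detectedLabeled = detLab, detectedControl = detCtl)
      r$padj <- bhAdjust(r$pvalue)
      r
    })
    cl <- classifyLabels(res$heavy, res$light, fdr = fdr)
    cl <- cbind(data.frame(comparison = paste0(tr, "_T", tp),
                           treatment = tr, timepoint_days = tp,
                           stringsAsFactors = FALSE),
                cl)
    calls <- rbind(calls, cl)
  }
  structure(list(calls = calls, se = x, report = report,
                 params = list(heavyThreshold = heavyThreshold, fdr = fdr,
                               lfcNull = lfcNull)),
            class = "SipDetectResult")
}

#' @export
print.SipDetectResult <- function(x, ...) {
  cat("SipDetectResult:", length(unique(x$calls$comparison)),
      "comparison(s),", nrow(x$se), "OTUs\n")
  tab <- tapply(x$calls$labeled, x$calls$comparison, sum)
  for (nm in names(tab)) cat(sprintf("  %s: %d labeled OTUs\n", nm, tab[nm]))
  cat(sprintf("  (heavy > %.2f g/ml, FDR %.2f, lfc null %.2f)\n",
              x$params$heavyThreshold, x$params$fdr, x$params$lfcNull))
  invisible(x)
}
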