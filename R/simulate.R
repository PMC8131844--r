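#' Gradient configuration
#'
#' Parameters of the simulated isopycnic CsCl gradient and its fractionation.
#' Defaults reproduce the study design this package targets: 12 equal-width
#' density fractions spanning 1.674-1.737 g/ml from a gradient spun at a mean
#' density of 1.725 g/ml.
#'
#' @param bdMin,bdMax gradient density range covered by the collected
#'   fractions, g/ml.
#' @param nFractions number of equal-width fractions (>= 2); fraction index 1
#'   is the heaviest (tube bottom collected first).
#' @param bandSd within-OTU Gaussian banding standard deviation, g/ml.
#'   The default 0.006 makes unlabeled and fully 13C-labeled bands overlap
#'   partially on the 12-fraction grid.
#' @param depthPerFraction sequencing reads drawn per fraction.
#' @param meanDensity initial CsCl solution density, g/ml (metadata only).
#' @param nativeBD0,nativeBDSlope coefficients of the native (unlabeled)
#'   GC -> density relation, g/ml; see [nativeBD()].
#' @param shift13C,shift15N full-labeling buoyant-density shifts, g/ml; see
#'   [labelShift()].
#' @return a named list of class `GradientConfig`.
#' @examples
#' gradientConfig()
#' @export
gradientConfig <- function(bdMin = 1.674, bdMax = 1.737, nFractions = 12L,
                           bandSd = 0.006, depthPerFraction = 30000L,
                           meanDensity = 1.725,
                           nativeBD0 = 1.660, nativeBDSlope = 0.098,
                           shift13C = 0.036, shift15N = 0.016) {
  if (bdMin >= bdMax) stop("bdMin must be < bdMax")
  if (nFractions < 2L) stop("nFractions must be >= 2")
  if (bandSd <= 0) stop("bandSd must be > 0")
  if (depthPerFraction < 1) stop("depthPerFraction must be >= 1")
  structure(list(bdMin = bdMin, bdMax = bdMax,
                 nFractions = as.integer(nFractions), bandSd = bandSd,
                 depthPerFraction = as.integer(depthPerFraction),
                 meanDensity = meanDensity,
                 nativeBD0 = nativeBD0, nativeBDSlope = nativeBDSlope,
                 shift13C = shift13C, shift15N = shift15N),
            class = "GradientConfig")
}

#' @export
print.GradientConfig <- function(x, ...) {
  cat(sprintf(
    "GradientConfig: %d fractions, %.3f-%.3f g/ml, band sd %.4f, depth %d\n",
    x$nFractions, x$bdMin, x$bdMax, x$bandSd, x$depthPerFraction))
  invisible(x)
}

#' Buoyant-density bin centers of the gradient fractions
#'
#' @param config a [gradientConfig()].
#' @return numeric vector of bin-center densities, fraction index order
#'   (element 1 = heaviest fraction).
#' @export
fractionDensities <- function(config) {
  w <- (config$bdMax - config$bdMin) / config$nFractions
  rev(config$bdMin + (seq_len(config$nFractions) - 0.5) * w)
}

#' Native buoyant density of unlabeled DNA from its GC content
#'
#' The classical linear relation between G+C fraction and CsCl buoyant
#' density of unlabeled DNA, `a + b * gc`, with the textbook coefficients
#' a = 1.660 g/ml and b = 0.098 g/ml as defaults.
#'
#' @param gc G+C fraction in \[0, 1\].
#' @param intercept,slope relation coefficients, g/ml.
#' @return buoyant density, g/ml.
#' @examples
#' nativeBD(0.5)  # 1.709
#' @export
nativeBD <- function(gc, intercept = 1.660, slope = 0.098) {
  gc <- as.numeric(gc)
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc must be in [0, 1]")
  intercept + slope * gc
}

#' Buoyant-density shift from isotope incorporation
#'
#' Linear in the atom fraction excess (afe) of each isotope:
#' `s13 * afe_13C + s15 * afe_15N`, with full-labeling shifts s13 = 0.036 and
#' s15 = 0.016 g/ml as defaults.
#'
#' @param afe13C,afe15N atom fraction excess of 13C / 15N in the DNA, each in
#'   \[0, 1\].
#' @param s13,s15 full-labeling density shifts, g/ml.
#' @return density shift, g/ml.
#' @examples
#' labelShift(0.15, 0.09)  # PAOM-type partial labeling
#' @export
labelShift <- function(afe13C, afe15N = 0, s13 = 0.036, s15 = 0.016) {
  afe13C <- as.numeric(afe13C); afe15N <- as.numeric(afe15N)
  if (any(afe13C < 0 | afe13C > 1, na.rm = TRUE) ||
      any(afe15N < 0 | afe15N > 1, na.rm = TRUE))
    stop("atom fraction excess must be in [0, 1]")
  s13 * afe13C + s15 * afe15N
}

#' Per-fraction banding profile of one OTU
#'
#' Integrates a Gaussian band (mean `centerBd`, sd `config$bandSd`) over the
#' equal-width density bins of the gradient and renormalizes over the bins,
#' so the returned masses sum to 1 (DNA outside the collected range is
#' attributed proportionally; for a band far outside the grid all mass goes
#' to the nearest end fraction).
#'
#' @param centerBd band center, g/ml.
#' @param config a [gradientConfig()].
#' @return numeric vector of length `nFractions`, in fraction-index order
#'   (element 1 = heaviest bin), summing to 1.
#' @export
bandProfile <- function(centerBd, config = gradientConfig()) {
  if (config$bandSd <= 0) stop("bandSd must be > 0")
  edges <- seq(config$bdMin, config$bdMax, length.out = config$nFractions + 1L)
  mass <- pnorm(edges[-1L], centerBd, config$bandSd) -
    pnorm(edges[-length(edges)], centerBd, config$bandSd)
  tot <- sum(mass)
  if (tot < 1e-300) {           # band entirely outside the grid
    mass <- numeric(config$nFractions)
    mass[if (centerBd > config$bdMax) config$nFractions else 1L] <- 1
  } else {
    mass <- mass / tot
  }
  rev(mass)                     # index 1 = heaviest
}

#' Isotope-labeling presets for the study substrates
#'
#' Atom-fraction-excess caps by substrate, matching the measured labeling
#' degrees of the amended substrates: PAOM 15% 13C / 9% 15N, protein extract
#' 18% 13C / 7% 15N, acetate 50% 13C (no 15N).
#'
#' @param name one of `"PAOM"`, `"protein"`, `"acetate"`.
#' @return list with `afe13C` and `afe15N` caps for labeled OTUs.
#' @export
scenarioPreset <- function(name) {
  presets <- list(PAOM    = list(afe13C = 0.15, afe15N = 0.09),
                  protein = list(afe13C = 0.18, afe15N = 0.07),
                  acetate = list(afe13C = 0.50, afe15N = 0.00))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

.PHYLA <- c("Planctomycetes", "Chloroflexi", "Proteobacteria", "Bacteroidetes",
            "Firmicutes", "Actinobacteria", "Crenarchaeota", "Nanoarchaeota",
            "Epsilonbacteraeota", "Atribacteria")

#' Generate a ground-truth community
#'
#' Relative abundances are lognormal (renormalized to sum to 1), GC content
#' uniform over `gcRange`, and a random subset of OTUs is flagged labeled
#' with atom fraction excess equal to the preset caps times
#' `assimilationEfficiency` (complete assimilation of the substrate label by
#' default). Taxonomy strings are drawn from a fixed pool of sediment phyla.
#'
#' @param nOtus community size.
#' @param fracLabeled fraction of OTUs that assimilated label.
#' @param preset substrate preset name (see [scenarioPreset()]) or a list
#'   with `afe13C`/`afe15N`.
#' @param abundSdlog lognormal sd (log scale) of relative abundances.
#' @param gcRange range of G+C fractions. The default (0.30, 0.50) places
#'   native band centers at 1.689-1.709 g/ml, matching the empirical
#'   observation that bulk unlabeled environmental DNA bands at roughly
#'   1.69-1.71 g/ml in CsCl, just below the conventional 1.70 g/ml heavy
#'   cutoff.
#' @param assimilationEfficiency multiplier in \[0, 1\] diluting the substrate
#'   label fraction into DNA.
#' @param seed optional integer seed.
#' @return data.frame with columns `otu_id`, `rel_abundance`, `gc`,
#'   `is_labeled`, `afe_13C`, `afe_15N`, `taxonomy`.
#' @examples
#' head(simulateCommunity(20, 0.2, "acetate", seed = 1))
#' @export
simulateCommunity <- function(nOtus, fracLabeled = 0.1, preset = "acetate",
                              abundSdlog = 1.5, gcRange = c(0.30, 0.50),
                              assimilationEfficiency = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(preset)) preset <- scenarioPreset(preset)
  if (assimilationEfficiency < 0 || assimilationEfficiency > 1)
    stop("assimilationEfficiency must be in [0, 1]")
  ab <- rlnorm(nOtus, 0, abundSdlog)
  ab <- ab / sum(ab)
  gc <- runif(nOtus, gcRange[1L], gcRange[2L])
  nLab <- round(nOtus * fracLabeled)
  lab <- logical(nOtus)
  if (nLab > 0) lab[sample.int(nOtus, nLab)] <- TRUE
  phy <- sample(.PHYLA, nOtus, replace = TRUE)
  dom <- ifelse(phy %in% c("Crenarchaeota", "Nanoarchaeota"),
                "Archaea", "Bacteria")
  data.frame(
    otu_id = sprintf("OTU_%04d", seq_len(nOtus)),
    rel_abundance = ab, gc = gc, is_labeled = lab,
    afe_13C = ifelse(lab, preset$afe13C * assimilationEfficiency, 0),
    afe_15N = ifelse(lab, preset$afe15N * assimilationEfficiency, 0),
    taxonomy = paste(dom, phy, paste0(phy, "_class"), paste0(phy, "_order"),
                     "unclassified", "unclassified", sep = ";"),
    stringsAsFactors = FALSE)
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a paired labeled/control DNA-SIP experiment
#'
#' For each timepoint, one labeled and one control gradient are built from
#' the same community. Each OTU bands as a Gaussian centered at its native
#' GC-dependent density, shifted by [labelShift()] in the labeled gradient if
#' (and only if) the OTU assimilated label. Expected per-fraction OTU
#' proportions are the abundance-weighted band masses renormalized within
#' each fraction; observed counts are multinomial draws at
#' `config$depthPerFraction` reads per fraction.
#'
#' @param truth community data.frame from [simulateCommunity()] (columns
#'   `otu_id`, `rel_abundance`, `gc`, `is_labeled`, `afe_13C`, `afe_15N`,
#'   optionally `taxonomy`).
#' @param config a [gradientConfig()].
#' @param timepoints sampling days; one labeled/control gradient pair each.
#' @param seed integer seed; identical inputs and seed give identical output.
#' @param treatment treatment name recorded in the metadata.
#' @param compositionJitter Dirichlet concentration-based perturbation of the
#'   control community: 0 (default) reuses the labeled community composition
#'   exactly; a value `c > 0` draws control abundances from
#'   Dirichlet(`c * rel_abundance`), emulating between-slurry compositional
#'   differences (smaller `c` = stronger jitter).
#' @param depthSdlog lognormal sd of per-fraction depth jitter; 0 = fixed
#'   depth.
#' @return a [SipExperiment-class] with the truth attached in `metadata()`.
#' @examples
#' tr <- simulateCommunity(30, 0.2, "acetate", seed = 1)
#' simulateExperiment(tr, gradientConfig(depthPerFraction = 1000), seed = 1)
#' @export
simulateExperiment <- function(truth, config = gradientConfig(),
                               timepoints = 7, seed = 1,
                               treatment = "substrate",
                               compositionJitter = 0, depthSdlog = 0) {
  truth <- as.data.frame(truth)
  if (nrow(truth) == 0) stop("truth community is empty")
  if (anyDuplicated(truth$otu_id))
    stop("duplicate otu_id in truth community")
  set.seed(as.integer(seed))
  n <- nrow(truth)
  dens <- fractionDensities(config)
  nf <- config$nFractions

  # band mass matrix per arm: OTU x fraction
  profiles <- function(shifted) {
    centers <- nativeBD(truth$gc, config$nativeBD0, config$nativeBDSlope)
    if (shifted)
      centers <- centers + ifelse(
        truth$is_labeled,
        labelShift(truth$afe_13C, truth$afe_15N,
                   config$shift13C, config$shift15N),
        0)
    t(vapply(centers, bandProfile, numeric(nf), config = config))
  }
  bandLab <- profiles(TRUE)
  bandCtl <- profiles(FALSE)

  counts <- NULL; meta <- NULL
  for (tp in timepoints) {
    for (iso in c("labeled", "control")) {
      ab <- truth$rel_abundance
      if (iso == "control" && compositionJitter > 0)
        ab <- .rdirichlet1(compositionJitter * ab)
      band <- if (iso == "labeled") bandLab else bandCtl
      expMass <- ab * band                       # OTU x fraction DNA mass
      fracTot <- colSums(expMass)
      cnt <- matrix(0L, n, nf)
      for (f in seq_len(nf)) {
        depth <- config$depthPerFraction
        if (depthSdlog > 0)
          depth <- max(1L, as.integer(round(depth * rlnorm(1, 0, depthSdlog))))
        p <- if (fracTot[f] > 0) expMass[, f] / fracTot[f] else rep(1 / n, n)
        cnt[, f] <- rmultinom(1L, depth, p)[, 1L]
      }
      iso_tag <- if (iso == "labeled") "13C" else "12C"
      ids <- sprintf("%s_T%d_%s_F%02d", treatment, tp, iso_tag, seq_len(nf))
      colnames(cnt) <- ids
      rownames(cnt) <- truth$otu_id
      counts <- if (is.null(counts)) cnt else cbind(counts, cnt)
      meta <- rbind(meta, data.frame(
        sample_id = ids, treatment = treatment, isotope = iso,
        timepoint_days = tp, fraction_index = seq_len(nf),
        buoyant_density = dens, stringsAsFactors = FALSE))
    }
  }
  tax <- if ("taxonomy" %in% colnames(truth))
    data.frame(otu_id = truth$otu_id, lineage = truth$taxonomy) else NULL
  SipExperiment(counts, meta, taxonomy = tax, truth = truth)
}

#' Expected (noise-free) fraction proportions for one gradient arm
#'
#' The multinomial probabilities [simulateExperiment()] samples from, useful
#' for building deterministic fixtures and for convergence checks.
#'
#' @inheritParams simulateExperiment
#' @param labeled logical: apply the label-induced shift to labeled OTUs?
#' @return OTU x fraction matrix of per-fraction proportions (columns sum
#'   to 1), fraction index 1 = heaviest.
#' @export
expectedProportions <- function(truth, config = gradientConfig(),
                                labeled = TRUE) {
  truth <- as.data.frame(truth)
  centers <- nativeBD(truth$gc, config$nativeBD0, config$nativeBDSlope)
  if (labeled)
    centers <- centers + ifelse(
      truth$is_labeled,
      labelShift(truth$afe_13C, truth$afe_15N,
                 config$shift13C, config$shift15N),
      0)
  band <- t(vapply(centers, bandProfile, numeric(config$nFractions),
                   config = config))
  expMass <- truth$rel_abundance * band
  prop <- sweep(expMass, 2L, colSums(expMass), "/")
  dimnames(prop) <- list(truth$otu_id, NULL)
  prop
}
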