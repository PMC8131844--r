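---
title: "HRSIP labeled-OTU detection: model, parameters and design choices"
author: "sipdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRSIP labeled-OTU detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipdetect)
```

## The measurement and the statistical question

DNA-SIP couples substrate assimilation to buoyant density (BD): organisms
that incorporate ¹³C/¹⁵N from a labeled substrate produce denser DNA, which
equilibrates lower in an isopycnic CsCl gradient. After fractionating the
gradient (12 equal fractions over 1.674–1.737 g/ml in the design this
package defaults to) and sequencing 16S amplicons per fraction, the data are
an OTU-by-fraction count table per incubation.

Density alone does not identify labeled DNA: an OTU's native BD depends on
its G+C content (roughly `BD = 1.660 + 0.098·GC` for unlabeled DNA), so a
high-GC unlabeled OTU bands where a low-GC labeled OTU would. HRSIP
therefore asks, per OTU, whether its abundance in the *heavy* fractions
(BD > 1.70 g/ml) of the labeled incubation exceeds its abundance in the
heavy fractions of a parallel control incubation with the same, but
unlabeled, substrate.

`sipdetect` calls an OTU labeled when two criteria hold at a 10% false
discovery rate:

1. significantly more abundant in the heavy window of the labeled gradient
   than of the control gradient (one-sided test, BH-adjusted p < `fdr`), and
2. *not* significantly more abundant in the light window (the complement,
   BD ≤ 1.70 g/ml, unbounded below).

Criterion 2 is a guard: two slurries never have exactly the same community,
and an OTU that is simply more abundant *throughout* the labeled incubation
would otherwise masquerade as labeled. A density shift moves reads from the
light into the heavy window; a compositional shift inflates both windows
together and is vetoed.

## The test

Within one (comparison, window) pair, the heavy fractions of the labeled
gradient form one group and the heavy fractions of the control gradient the
other; fractions act as replicate units (each gradient is one biological
slurry — the replication is technical, across the window's fractions, and
this is the main statistical caveat of the whole framework).

* **Normalization.** Median-of-ratios size factors on the tested samples:
  reference = per-OTU geometric mean over samples, restricted to OTUs
  positive in every sample; sample factor = median count/reference ratio,
  rescaled to geometric mean 1. If no OTU is positive everywhere (sparse
  gradient ends), the reference falls back to OTUs positive in ≥ 50% of
  samples, with a warning.
* **Model.** Counts are treated as negative binomial. Per-OTU dispersion is
  a method-of-moments estimate from the pooled within-group variance of
  normalized counts (`Var(K/s) ≈ μ·mean(1/s) + α·μ²`), shrunk 50/50 toward
  a mean–dispersion trend `a0 + a1/μ` fitted across OTUs by least squares,
  floored at 1e−8. OTUs whose moment estimate is non-positive (at or below
  Poisson noise) use the trend value. This is deliberately simpler than
  reference-grade Cox–Reid/MAP shrinkage; the contract is the
  simulation-calibrated error-control properties exercised by the test
  suite, not numerical identity with any existing implementation.
* **Statistic.** `l2fc = log2(μ_labeled / μ_control)` of the normalized
  group means, with a +0.5 pseudo-mean applied only when a group mean is 0
  but the OTU is detected in both incubations overall. The Wald statistic is
  `(l2fc − lfcNull)/se` with the delta-method standard error, and the
  one-sided p-value tests the alternative `l2fc > lfcNull`.
* **Multiplicity.** BH step-up within each (comparison, window) family,
  over tested OTUs only; heavy and light windows are adjusted separately
  (the two criteria are separate tests).
* **Untestable OTUs.** An OTU with zero reads across all fractions of either
  incubation cannot be compared to its native form; it is reported
  `tested = FALSE` with a reason, never labeled, and does not count toward
  the BH family size.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `heavyThreshold` | 1.70 | g/ml | conventional heavy/light cut; bulk unlabeled DNA bands just below it |
| `fdr` | 0.10 | — | the FDR conventionally used for HRSIP verdicts |
| `lfcNull` | 0.25 | log2 | published HRSIP convention for the fold-change null; echoed in `run_config.yaml` so every run records the value used |
| `minRelAbundance` | 5e-5 | fraction | the 0.005% hygiene floor, strict (`<`), computed over the whole table (a per-gradient mode exists behind `perGradient`) |
| `excludePatterns` | "Cyanobacteria" | — | substrate-derived algal/cyanobacterial DNA is indistinguishable from community DNA |
| `bandSd` | 0.006 | g/ml | unlabeled and fully ¹³C-labeled bands overlap partially on the 12-fraction grid |
| `shift13C`, `shift15N` | 0.036, 0.016 | g/ml | classical full-labeling BD shifts; linear in atom fraction excess |
| `nativeBD0`, `nativeBDSlope` | 1.660, 0.098 | g/ml | classical GC→BD relation for unlabeled DNA |
| `assimilationEfficiency` | 1.0 | — | how much of the substrate's label fraction reaches DNA; the wet experiment cannot constrain it, so it is exposed rather than asserted |

Filter order is fixed (singleton → taxon exclusion → abundance floor) so
that filter reports are reproducible; the retained OTU set is
order-independent, only the attribution of a removal to a rule depends on
the order.

## What the simulator emulates — and what it does not

`simulateCommunity()` + `simulateExperiment()` generate a lognormal-abundance
community (GC uniform on 0.30–0.50 by default), band each OTU as a single
Gaussian centered at `nativeBD(gc)` plus `labelShift(afe13C, afe15N)` in the
labeled arm, integrate the band over the 12 equal-width density bins
(index 1 = heaviest, as collected from the tube bottom), renormalize within
each fraction (sequencing is compositional), and draw multinomial counts at
a fixed depth per fraction. Substrate presets pin the attainable atom
fraction excess to the measured labeling degrees (PAOM 15%/9%, protein
18%/7%, acetate 50%/0%).

The default GC range matters and was chosen on physical grounds: bulk
unlabeled environmental DNA is observed to band at roughly 1.69–1.71 g/ml,
i.e. just below the 1.70 g/ml cutoff — which is exactly why that cutoff is
usable. Under the classical GC→BD relation this corresponds to GC
0.30–0.50. Communities placed substantially above 1.70 natively would make
a 1.70 heavy window meaningless regardless of the test used.

Optional realism knobs, off by default: `compositionJitter` (Dirichlet
perturbation of the control community — the failure mode criterion 2 exists
for) and `depthSdlog` (lognormal per-fraction depth variation).

Not modeled: ultracentrifugation hydrodynamics, diffusion or within-OTU GC
heterogeneity (one common `bandSd` covers both), PCR/chimera artifacts,
paired-end read error, and biological replication of slurries. Passing the
simulation-based tests therefore demonstrates correct behavior of the
*statistical machinery* under the stated banding model — it does not
certify performance on real gradients, where band shapes are wider-tailed
and replicate slurries differ compositionally.

## Numerical choices and degenerate inputs

* A band centered far outside the collected range underflows the bin
  integrals; its mass is then assigned to the nearest end fraction (DNA
  pelleting at the tube extremes).
* A calibration fit requires ≥ 2 standards with distinct refractive indices
  and non-constant densities; collinear standards reproduce their line to
  machine precision and report r = 1.
* Computed BDs outside (1.0, 2.0) g/ml warn rather than error (refractometer
  typos should be visible, not fatal).
* `splitWindows()` errors when a gradient has an empty heavy or light
  window — a threshold outside the collected density range is a design
  error, not a silent no-op.
* The relative-abundance floor is strict (`<`): an OTU at exactly 0.005%
  is retained.
* BH family size excludes untested (NA) entries; adjusted values are
  returned in input order with NAs preserved.

## Problem sizes used by the test suite

The simulation-based checks run at 200 OTUs, 12 fractions × 2 arms,
3×10⁴ reads per fraction, 20 replicate seeds for the error-control
properties (realized false-discovery proportion and sensitivity of
abundant, afe ≥ 0.5 OTUs), 10 seeds for the null scenario, and 10⁵–10⁶
draws for band-model convergence checks. These sizes give stable Monte
Carlo estimates for the assertions made while keeping a full suite run in
tens of seconds.

## Known limitations

* Fractions are pseudo-replicates; p-values are calibrated against the
  banding-and-multinomial noise model, not against between-slurry
  biological variance. Criterion 2 mitigates, but cannot remove, this.
* Sensitivity falls for weakly labeled, high-GC OTUs whose labeled band
  stays partly below the fixed 1.70 g/ml cutoff; multi-window scans (qSIP,
  MW-HRSIP) address this and are out of scope here.
* The light window is unbounded below, so strong *de*-enrichment in the
  heavy window cannot be distinguished from degradation of labeled DNA.
* Quantitative atom-fraction-excess estimation per OTU is not attempted;
  the verdict is binary by design.
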