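# Shared fixture builders (all generated in code; nothing on disk).

# Minimal paired-gradient metadata on the default 12-fraction grid.
makeGradientMeta <- function(config = gradientConfig(), treatment = "sub",
                             timepoint = 7) {
  dens <- fractionDensities(config)
  nf <- config$nFractions
  data.frame(
    sample_id = c(sprintf("%s_T%d_13C_F%02d", treatment, timepoint, 1:nf),
                  sprintf("%s_T%d_12C_F%02d", treatment, timepoint, 1:nf)),
    treatment = treatment,
    isotope = rep(c("labeled", "control"), each = nf),
    timepoint_days = timepoint,
    fraction_index = rep(1:nf, 2),
    buoyant_density = rep(dens, 2),
    stringsAsFactors = FALSE)
}

# Deterministic counts: expected proportions x depth, rounded. Separate truth
# tables for the labeled and control arms allow controlled composition shifts.
makeDeterministicSip <- function(truthLabeledArm, truthControlArm,
                                 config = gradientConfig(),
                                 treatment = "sub", timepoint = 7) {
  pL <- expectedProportions(truthLabeledArm, config, labeled = TRUE)
  pC <- expectedProportions(truthControlArm, config, labeled = FALSE)
  cnt <- cbind(round(pL * config$depthPerFraction),
               round(pC * config$depthPerFraction))
  meta <- makeGradientMeta(config, treatment, timepoint)
  colnames(cnt) <- meta$sample_id
  SipExperiment(cnt, meta)
}

# Independent brute-force BH step-up, straight from the definition:
# adj_(i) = min_{j >= i} min(1, (m/j) * p_(j)), mapped back to input order.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m / seq_len(m) * p[o]
  if (m > 1)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}
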