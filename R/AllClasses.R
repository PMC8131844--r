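#' SipExperiment: OTU counts across density-gradient fractions
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"counts"` (integer OTU x fraction matrix). `colData` carries the
#' fraction metadata (`sample_id`, `treatment`, `isotope`, `timepoint_days`,
#' `fraction_index`, `buoyant_density`, and a derived `gradient` id); `rowData`
#' carries the taxonomy (`lineage` plus parsed ranks). When the object comes
#' from the simulator, the per-OTU ground truth is stored in
#' `metadata(x)$truth`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("SipExperiment", contains = "SummarizedExperiment")

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.validSipExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  }
  cd <- colData(object)
  need <- c("treatment", "isotope", "timepoint_days", "fraction_index",
            "buoyant_density", "gradient")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing fraction metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if ("isotope" %in% colnames(cd) &&
      !all(cd$isotope %in% c("labeled", "control")))
    msg <- c(msg, "isotope must be 'labeled' or 'control'")
  if ("fraction_index" %in% colnames(cd) && "gradient" %in% colnames(cd)) {
    dup <- vapply(split(cd$fraction_index, cd$gradient),
                  function(z) anyDuplicated(z) > 0, logical(1))
    if (any(dup))
      msg <- c(msg, paste0("duplicated fraction_index within gradient(s): ",
                           paste(names(dup)[dup], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("SipExperiment", .validSipExperiment)

#' Construct a SipExperiment
#'
#' @param counts integer matrix, OTUs (rows) x fraction samples (columns).
#'   Row and column names are required.
#' @param fractions `data.frame` of fraction metadata with columns
#'   `sample_id`, `treatment`, `isotope` (`"labeled"`/`"control"`),
#'   `timepoint_days`, `fraction_index` (1 = heaviest), `buoyant_density`
#'   (g/ml). Rows are matched to `colnames(counts)` by `sample_id`.
#' @param taxonomy optional `data.frame` with columns `otu_id` and `lineage`
#'   (semicolon-delimited ranks, domain first); parsed into per-rank columns.
#' @param truth optional per-OTU ground-truth `data.frame` (from the
#'   simulator), stored in `metadata()`.
#'
#' @return A [SipExperiment-class] object.
#' @examples
#' cnt <- matrix(0:7, 2, 4, dimnames = list(c("OTU_1", "OTU_2"), paste0("s", 1:4)))
#' fr <- data.frame(sample_id = paste0("s", 1:4), treatment = "acetate",
#'                  isotope = rep(c("labeled", "control"), each = 2),
#'                  timepoint_days = 7, fraction_index = c(1, 2, 1, 2),
#'                  buoyant_density = c(1.72, 1.69, 1.72, 1.69))
#' SipExperiment(cnt, fr)
#' @export
SipExperiment <- function(counts, fractions, taxonomy = NULL, truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (OTU) and column (sample) names")
  storage.mode(counts) <- "integer"
  fractions <- as.data.frame(fractions)
  if (!"sample_id" %in% colnames(fractions))
    stop("fraction metadata must have a 'sample_id' column")
  orphan <- setdiff(colnames(counts), fractions$sample_id)
  if (length(orphan))
    stop("count columns absent from fraction metadata: ",
         paste(orphan, collapse = ", "))
  fractions <- fractions[match(colnames(counts), fractions$sample_id), ,
                         drop = FALSE]
  if (!"gradient" %in% colnames(fractions))
    fractions$gradient <- gradientId(fractions$treatment,
                                     fractions$timepoint_days,
                                     fractions$isotope)
  cd <- DataFrame(fractions, row.names = fractions$sample_id)
  rd <- DataFrame(otu_id = rownames(counts), row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(c("otu_id", "lineage") %in% colnames(taxonomy)))
      stop("taxonomy must have columns 'otu_id' and 'lineage'")
    missing_tax <- setdiff(rownames(counts), taxonomy$otu_id)
    if (length(missing_tax))
      stop("OTU id(s) missing from taxonomy: ",
           paste(utils::head(missing_tax, 5), collapse = ", "))
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu_id), ,
                         drop = FALSE]
    rd$lineage <- taxonomy$lineage
    ranks <- parseLineage(taxonomy$lineage)
    for (r in colnames(ranks)) rd[[r]] <- ranks[, r]
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  obj <- methods::new("SipExperiment", se)
  if (!is.null(truth)) metadata(obj)$truth <- as.data.frame(truth)
  obj
}

#' Gradient identifier for (treatment, timepoint, isotope) triples
#'
#' One gradient = the set of fractions drawn from a single ultracentrifuge
#' tube, i.e. one incubation at one timepoint in one isotope arm.
#'
#' @param treatment,timepoint_days,isotope vectors recycled to common length.
#' @return character vector of gradient ids.
#' @export
gradientId <- function(treatment, timepoint_days, isotope) {
  paste(treatment, paste0("T", timepoint_days), isotope, sep = "|")
}

#' Split a lineage string into named ranks
#'
#' @param lineage character vector of semicolon-delimited lineages, domain
#'   first. Shorter lineages are padded with `"unclassified"`.
#' @return character matrix with columns domain..genus.
#' @export
parseLineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    length(p) <- length(.TAX_RANKS)
    p[is.na(p)] <- "unclassified"
    p
  }, character(length(.TAX_RANKS))))
  colnames(out) <- .TAX_RANKS
  out
}

#' @describeIn SipExperiment-class buoyant density (g/ml) of each fraction.
#' @param x a `SipExperiment`.
#' @export
buoyantDensity <- function(x) colData(x)$buoyant_density

#' @describeIn SipExperiment-class fraction metadata as a base data.frame.
#' @export
fractionMetadata <- function(x) as.data.frame(colData(x))

#' @describeIn SipExperiment-class taxonomy table (otu_id, lineage, ranks)
#'   as a base data.frame.
#' @export
taxonomyTable <- function(x) as.data.frame(rowData(x))

#' @describeIn SipExperiment-class simulator ground truth (or NULL).
#' @export
communityTruth <- function(x) metadata(x)$truth

setMethod("show", "SipExperiment", function(object) {
  cat("SipExperiment:", nrow(object), "OTUs x", ncol(object), "fractions\n")
  cd <- colData(object)
  cat("  gradients:", length(unique(cd$gradient)),
      " | density range:",
      sprintf("%.4f-%.4f g/ml", min(cd$buoyant_density),
              max(cd$buoyant_density)), "\n")
  if (!is.null(metadata(object)$truth))
    cat("  ground truth attached (",
        sum(metadata(object)$truth$is_labeled), "labeled OTUs )\n")
  invisible(NULL)
})

#' CalibrationModel: linear refractive-index to buoyant-density map
#'
#' Stores the ordinary-least-squares standard curve BD = slope * RI +
#' intercept together with the Pearson correlation of the calibration points.
#'
#' @slot slope numeric, g/ml per refractive-index unit (nonzero).
#' @slot intercept numeric, g/ml.
#' @slot r numeric, Pearson correlation of (RI, density); `|r| <= 1`.
#' @slot n_points integer, number of calibration standards (>= 2).
#' @export
setClass("CalibrationModel",
         representation(slope = "numeric", intercept = "numeric",
                        r = "numeric", n_points = "integer"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (length(object@slope) != 1 || object@slope == 0 || !is.finite(object@slope))
    msg <- c(msg, "slope must be a single finite nonzero number")
  if (object@n_points < 2L) msg <- c(msg, "n_points must be >= 2")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "|r| must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: BD = %.6g * RI + %.6g  (r = %.4g, n = %d)\n",
              object@slope, object@intercept, object@r, object@n_points))
  invisible(NULL)
})
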