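#' Summarize labeled OTUs per taxon
#'
#' For each comparison and each taxon at the chosen rank: the number of
#' labeled OTUs and the percentage of total reads they represent in the
#' labeled incubation, i.e. 100 x (sum of labeled-OTU counts over all
#' fractions of the labeled gradient) / (grand total reads of that gradient).
#' The denominator is the post-filter table the calls were made on. OTUs
#' unclassified at the chosen rank aggregate into an `"unclassified"` row.
#'
#' @param result a `SipDetectResult` from [detectLabeledOTUs()], or a calls
#'   `data.frame` (then `se` is required).
#' @param rank taxonomic rank, one of domain, phylum, class, order, family,
#'   genus (default `"phylum"`).
#' @param se the [SipExperiment-class] the calls refer to (taken from
#'   `result$se` when `result` is a `SipDetectResult`).
#' @return `data.frame` with columns `comparison`, `taxon`, `n_labeled_otus`,
#'   `pct_total_reads`. Comparisons with zero labeled OTUs contribute no rows.
#' @export
summarizeLabeled <- function(result, rank = "phylum", se = NULL) {
  if (inherits(result, "SipDetectResult")) {
    calls <- result$calls
    if (is.null(se)) se <- result$se
  } else calls <- as.data.frame(result)
  if (is.null(se)) stop("need the SipExperiment the calls were made on")
  if (!rank %in% .TAX_RANKS)
    stop("unknown rank '", rank, "'; valid ranks: ",
         paste(.TAX_RANKS, collapse = ", "))
  bad <- setdiff(calls$otu_id, rownames(se))
  if (length(bad))
    stop("calls refer to OTUs absent from counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  tax <- rowData(se)[[rank]]
  if (is.null(tax)) tax <- rep("unclassified", nrow(se))
  tax[is.na(tax)] <- "unclassified"
  names(tax) <- rownames(se)
  md <- fractionMetadata(se)
  counts <- assay(se, "counts")

  out <- NULL
  for (cmp in unique(calls$comparison)) {
    sub <- calls[calls$comparison == cmp & calls$labeled, , drop = FALSE]
    if (nrow(sub) == 0) next
    g <- gradientId(sub$treatment[1L], sub$timepoint_days[1L], "labeled")
    gradSamples <- md$sample_id[md$gradient == g]
    grand <- sum(counts[, gradSamples, drop = FALSE])
    otuReads <- rowSums(counts[sub$otu_id, gradSamples, drop = FALSE])
    taxa <- tax[sub$otu_id]
    agg <- data.frame(
      comparison = cmp,
      taxon = names(split(otuReads, taxa)),
      n_labeled_otus = as.integer(table(taxa)[names(split(otuReads, taxa))]),
      pct_total_reads = 100 * vapply(split(otuReads, taxa), sum,
                                     numeric(1)) / grand,
      row.names = NULL, stringsAsFactors = FALSE)
    out <- rbind(out, agg[order(-agg$pct_total_reads), , drop = FALSE])
  }
  if (is.null(out))
    out <- data.frame(comparison = character(), taxon = character(),
                      n_labeled_otus = integer(),
                      pct_total_reads = numeric())
  rownames(out) <- NULL
  out
}

#' Heavy-window log2 fold-change matrix
#'
#' Long-to-wide pivot of the heavy-window log2 fold changes across
#' comparisons, the quantity heatmapped when comparing treatments and
#' timepoints. OTUs untested in a comparison are missing (NA), not 0.
#'
#' @param result a `SipDetectResult` or calls `data.frame`.
#' @param otus optional character vector restricting the rows.
#' @return numeric matrix, OTUs x comparisons.
#' @export
lfcMatrix <- function(result, otus = NULL) {
  calls <- if (inherits(result, "SipDetectResult")) result$calls
           else as.data.frame(result)
  if (nrow(calls) == 0) stop("no comparisons in calls")
  if (!is.null(otus)) calls <- calls[calls$otu_id %in% otus, , drop = FALSE]
  ids <- unique(calls$otu_id)
  cmps <- unique(calls$comparison)
  m <- matrix(NA_real_, length(ids), length(cmps),
              dimnames = list(ids, cmps))
  keep <- calls$tested & !is.na(calls$heavy_log2fc)
  m[cbind(match(calls$otu_id[keep], ids),
          match(calls$comparison[keep], cmps))] <- calls$heavy_log2fc[keep]
  m
}
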