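#' Read a SipExperiment from TSV tables
#'
#' @param countsPath TSV, first column `otu_id`, remaining columns one per
#'   fraction sample.
#' @param fractionsPath TSV with columns `sample_id`, `treatment`, `isotope`,
#'   `timepoint_days`, `fraction_index`, `buoyant_density`.
#' @param taxonomyPath optional TSV with columns `otu_id`, `lineage`.
#' @return a [SipExperiment-class].
#' @export
readSipExperiment <- function(countsPath, fractionsPath,
                              taxonomyPath = NULL) {
  cdf <- read.delim(countsPath, check.names = FALSE)
  if (colnames(cdf)[1L] != "otu_id")
    stop("counts file must have 'otu_id' as its first column")
  counts <- as.matrix(cdf[, -1L, drop = FALSE])
  rownames(counts) <- cdf$otu_id
  fractions <- read.delim(fractionsPath, check.names = FALSE)
  taxonomy <- if (!is.null(taxonomyPath))
    read.delim(taxonomyPath, check.names = FALSE) else NULL
  SipExperiment(counts, fractions, taxonomy = taxonomy)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SipExperiment (and attached truth) as TSV tables
#'
#' Writes `counts.tsv`, `fractions.tsv`, and when present `taxonomy.tsv` and
#' `truth.tsv`, into `dir`.
#'
#' @param x a [SipExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSipExperiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- assay(x, "counts")
  .write_tsv(data.frame(otu_id = rownames(counts), counts,
                        check.names = FALSE),
             file.path(dir, "counts.tsv"))
  md <- fractionMetadata(x)
  .write_tsv(md[, c("sample_id", "treatment", "isotope", "timepoint_days",
                    "fraction_index", "buoyant_density")],
             file.path(dir, "fractions.tsv"))
  rd <- taxonomyTable(x)
  if (!is.null(rd$lineage))
    .write_tsv(data.frame(otu_id = rownames(x), lineage = rd$lineage),
               file.path(dir, "taxonomy.tsv"))
  tr <- communityTruth(x)
  if (!is.null(tr))
    .write_tsv(tr[, c("otu_id", "is_labeled", "gc", "afe_13C", "afe_15N",
                      "rel_abundance")],
               file.path(dir, "truth.tsv"))
  invisible(dir)
}
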