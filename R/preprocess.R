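#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples equals exactly 1. All-zero
#' rows are retained by this rule (they fall to the abundance floor instead).
#'
#' @param x a [SipExperiment-class].
#' @return list with `se` (filtered object) and `removed` (character ids).
#' @export
removeSingletons <- function(x) {
  tot <- rowSums(assay(x, "counts"))
  drop <- tot == 1
  list(se = x[!drop, ], removed = rownames(x)[drop])
}

#' Remove OTUs below a relative-abundance floor
#'
#' Computes each OTU's total count divided by the grand total over the whole
#' table and drops OTUs strictly below `floor` (the conventional 0.005% floor
#' by default; "lower than" is read strictly, so an OTU exactly at the floor
#' is retained).
#'
#' @param x a [SipExperiment-class].
#' @param floor relative-abundance threshold as a fraction (0.00005 = 0.005%).
#' @param perGradient if TRUE, an OTU is kept when it reaches the floor
#'   within at least one gradient (computed over that gradient's fractions);
#'   default FALSE computes one global abundance over the full table.
#' @return list with `se` and `removed`.
#' @export
filterMinRelAbundance <- function(x, floor = 0.00005, perGradient = FALSE) {
  m <- assay(x, "counts")
  grand <- sum(m)
  if (grand == 0) stop("count table has grand total 0")
  if (perGradient) {
    keep <- rep(FALSE, nrow(m))
    for (g in unique(colData(x)$gradient)) {
      sub <- m[, colData(x)$gradient == g, drop = FALSE]
      gt <- sum(sub)
      if (gt > 0) keep <- keep | (rowSums(sub) / gt >= floor)
    }
    drop <- !keep
  } else {
    drop <- rowSums(m) / grand < floor
  }
  list(se = x[!drop, ], removed = rownames(x)[drop])
}

#' Exclude OTUs by taxon name
#'
#' Drops OTUs whose lineage contains any of the given names at any rank
#' (case-insensitive exact token match on the semicolon-delimited lineage).
#' The default removes Cyanobacteria, whose reads cannot be separated from
#' DNA carried in with an algal substrate.
#'
#' @param x a [SipExperiment-class] with taxonomy in `rowData` (`lineage`).
#' @param patterns character vector of taxon names; empty vector = no-op.
#' @return list with `se` and `removed`.
#' @export
excludeTaxa <- function(x, patterns = "Cyanobacteria") {
  if (length(patterns) == 0)
    return(list(se = x, removed = character()))
  lin <- rowData(x)$lineage
  if (is.null(lin))
    stop("no taxonomy attached; cannot exclude taxa")
  if (anyNA(lin))
    stop("OTU id(s) missing taxonomy: ",
         paste(utils::head(rownames(x)[is.na(lin)], 5), collapse = ", "))
  toks <- lapply(strsplit(tolower(lin), ";", fixed = TRUE), trimws)
  pat <- tolower(patterns)
  drop <- vapply(toks, function(tk) any(tk %in% pat), logical(1))
  list(se = x[!drop, ], removed = rownames(x)[drop])
}

#' Standard OTU-table hygiene filters
#'
#' Applies, in order: singleton removal, taxon exclusion, relative-abundance
#' floor. Each OTU is attributed to the first rule that removed it; the
#' report always reconciles (input = retained + removals). The retained set
#' is order-independent; only the attribution depends on the order.
#'
#' @param x a [SipExperiment-class].
#' @param minRelAbundance abundance floor as a fraction (default 0.005%).
#' @param excludePatterns taxa to exclude (default `"Cyanobacteria"`);
#'   ignored with a message if no taxonomy is attached.
#' @param keepSingletons if TRUE the singleton rule is skipped.
#' @param perGradient see [filterMinRelAbundance()].
#' @return list with `se` (filtered) and `report` (a `FilterReport`:
#'   n_input_otus, n_singletons_removed, n_taxon_excluded,
#'   n_below_abundance_removed, n_retained, plus the removed ids per rule).
#' @examples
#' tr <- simulateCommunity(40, 0.1, seed = 2)
#' se <- simulateExperiment(tr, gradientConfig(depthPerFraction = 2000), seed = 2)
#' preprocessSip(se)$report
#' @export
preprocessSip <- function(x, minRelAbundance = 0.00005,
                          excludePatterns = "Cyanobacteria",
                          keepSingletons = FALSE, perGradient = FALSE) {
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty OTU table")
  nIn <- nrow(x)
  removed <- list(singletons = character(), taxa = character(),
                  abundance = character())
  if (!keepSingletons) {
    s <- removeSingletons(x)
    x <- s$se; removed$singletons <- s$removed
  }
  if (length(excludePatterns) > 0) {
    if (is.null(rowData(x)$lineage)) {
      message("no taxonomy attached; skipping taxon exclusion")
    } else {
      s <- excludeTaxa(x, excludePatterns)
      x <- s$se; removed$taxa <- s$removed
    }
  }
  s <- filterMinRelAbundance(x, minRelAbundance, perGradient)
  x <- s$se; removed$abundance <- s$removed
  report <- structure(list(
    n_input_otus = nIn,
    n_singletons_removed = length(removed$singletons),
    n_taxon_excluded = length(removed$taxa),
    n_below_abundance_removed = length(removed$abundance),
    n_retained = nrow(x),
    removed = removed), class = "FilterReport")
  stopifnot(report$n_input_otus ==
              report$n_retained + report$n_singletons_removed +
              report$n_taxon_excluded + report$n_below_abundance_removed)
  list(se = x, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:\n",
      sprintf("  input OTUs            %d\n", x$n_input_otus),
      sprintf("  singletons removed    %d\n", x$n_singletons_removed),
      sprintf("  taxon-excluded        %d\n", x$n_taxon_excluded),
      sprintf("  below abundance floor %d\n", x$n_below_abundance_removed),
      sprintf("  retained              %d\n", x$n_retained), sep = "")
  invisible(x)
}
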