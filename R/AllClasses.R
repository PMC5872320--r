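#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats as.dist cophenetic rpois runif sd setNames uniroot
#' @importFrom utils read.delim write.table head
NULL

#' OccurrenceExperiment: fragment-colonization counts per sample
#'
#' An \linkS4class{SummarizedExperiment} subclass holding an isolation
#' survey's occurrence matrix: one \code{"counts"} assay of species (rows) by
#' samples (columns), where \code{counts[s, i]} is the number of plated
#' fragments of sample \code{i} from which species \code{s} emerged. The
#' \code{colData} carries, per sample, \code{total_fragments} (the number of
#' fragments plated -- metadata, never inferred from records, since
#' uncolonized fragments leave no record) and \code{colonized_fragments}
#' (distinct fragments yielding at least one isolate; \code{NA} when the
#' sample was not built from fragment-level records).
#'
#' Validity requires non-negative integer counts, and per sample
#' \code{counts <= total_fragments} for every species, plus
#' \code{colonized_fragments <= total_fragments} and
#' \code{sum(counts) >= colonized_fragments} (several species can share one
#' fragment, so the species-count column sum is an upper bound census).
#'
#' @seealso [buildOccurrenceMatrix()], [colonizationRate()],
#'   [diversityProfile()]
#' @export
setClass("OccurrenceExperiment", contains = "SummarizedExperiment")

setValidity("OccurrenceExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  if (!"total_fragments" %in% colnames(cd))
    return("colData column 'total_fragments' is required")
  tot <- cd$total_fragments
  if (any(is.na(tot)) || any(tot <= 0) || any(tot != round(tot)))
    msg <- c(msg, "total_fragments must be positive integers")
  else if (ncol(cts) > 0 && any(sweep(cts, 2, tot, ">")))
    msg <- c(msg, "a species count exceeds its sample's total_fragments")
  if ("colonized_fragments" %in% colnames(cd)) {
    colz <- cd$colonized_fragments
    ok <- !is.na(colz)
    if (any(colz[ok] > tot[ok]))
      msg <- c(msg, "colonized_fragments exceeds total_fragments")
    if (any(ok & colSums(cts) < ifelse(is.na(colz), 0, colz)))
      msg <- c(msg, "column count sums fall below colonized_fragments")
    if (nrow(cts) > 0 && ncol(cts) > 0 &&
        any(ok & apply(cts, 2, max) > ifelse(is.na(colz), Inf, colz)))
      msg <- c(msg, "a species occupies more fragments than were colonized")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OccurrenceExperiment
#'
#' @param counts integer matrix, species (rows) by samples (columns), with
#'   dimnames.
#' @param total_fragments integer vector, fragments plated per sample, named
#'   by or aligned with \code{colnames(counts)}.
#' @param colonized_fragments optional integer vector, distinct colonized
#'   fragments per sample (\code{NA} when unknown).
#' @param colData optional \code{DataFrame}/data.frame of extra per-sample
#'   metadata (grouping variables such as locality or medium).
#' @return an \linkS4class{OccurrenceExperiment}.
#' @examples
#' oe <- OccurrenceExperiment(
#'   counts = matrix(c(2L, 1L, 0L, 3L), 2, 2,
#'                   dimnames = list(c("sp1", "sp2"), c("A", "B"))),
#'   total_fragments = c(A = 8L, B = 8L))
#' totalFragments(oe)
#' @export
OccurrenceExperiment <- function(counts, total_fragments,
                                 colonized_fragments = NA_integer_,
                                 colData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)))
    .stopf("counts must have sample (column) names")
  if (!is.null(names(total_fragments)))
    total_fragments <- total_fragments[colnames(counts)]
  cd <- S4Vectors::DataFrame(
    sample_id = colnames(counts),
    total_fragments = as.integer(total_fragments),
    colonized_fragments = as.integer(rep(colonized_fragments,
                                         length.out = ncol(counts))),
    row.names = colnames(counts))
  if (!is.null(colData)) {
    extra <- S4Vectors::DataFrame(colData)
    cd <- cbind(cd, extra[, setdiff(colnames(extra), colnames(cd)),
                          drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("OccurrenceExperiment", se)
}

#' @describeIn OccurrenceExperiment the counts assay (species x samples).
#' @param object,x an \code{OccurrenceExperiment}.
#' @export
occurrenceCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn OccurrenceExperiment fragments plated per sample (named).
#' @export
totalFragments <- function(x)
  setNames(SummarizedExperiment::colData(x)$total_fragments, colnames(x))

#' @describeIn OccurrenceExperiment distinct colonized fragments per sample
#'   (named; \code{NA} when the matrix was not built from records).
#' @export
colonizedFragments <- function(x)
  setNames(SummarizedExperiment::colData(x)$colonized_fragments, colnames(x))

setMethod("show", "OccurrenceExperiment", function(object) {
  cat("OccurrenceExperiment:", nrow(object), "species x",
      ncol(object), "samples\n")
  cat("  fragments plated:",
      paste0(colnames(object), "=", totalFragments(object),
             collapse = ", "), "\n")
  callNextMethod()
})

#' SimilarityMatrix: pairwise Sorensen-Dice similarities
#'
#' Symmetric matrix of presence/absence similarities in \[0, 1\] with unit
#' diagonal, as produced by [similarityMatrix()]. The number of informative
#' cases is the upper triangle, \code{n(n-1)/2} for \code{n} samples.
#'
#' @slot values symmetric numeric matrix, unit diagonal, entries in \[0, 1\].
#' @seealso [sorensenDice()], [zeroSimilarityCensus()]
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("matrix needs matching row/column sample names")
  if (!isTRUE(all.equal(v, t(v)))) return("matrix must be symmetric")
  if (any(v < 0 | v > 1)) return("entries must lie in [0, 1]")
  if (any(abs(diag(v) - 1) > 1e-12)) return("diagonal must equal 1")
  TRUE
})

#' @describeIn SimilarityMatrix the underlying numeric matrix.
#' @param x a \code{SimilarityMatrix}.
#' @export
similarityValues <- function(x) x@values

setMethod("show", "SimilarityMatrix", function(object) {
  n <- nrow(object@values)
  cat("SimilarityMatrix over", n, "samples (",
      n * (n - 1) / 2, "pairwise cases )\n")
  print(round(object@values, 2))
})
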