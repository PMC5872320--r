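#' Sorensen-Dice similarity of two communities
#'
#' \code{QS = 2C / (A + B)} on presence/absence data, where \code{A} and
#' \code{B} are the two species counts and \code{C} the number of shared
#' species. Weighs joint occurrences more than mismatches; 0 means no shared
#' species, 1 identical composition. Defined on sets, so duplicated labels
#' are collapsed; abundances play no role.
#'
#' @param a,b character vectors of species labels (presence sets).
#' @return similarity in \[0, 1\].
#' @examples
#' tf2 <- c("Alternaria alternata", "Biscogniauxia mediterrranea",
#'          "Neofusicoccum australe", "Phoma sp. 1")
#' tf7 <- c("Alternaria alternata", "Neofusicoccum australe",
#'          "Stemphylium solani")
#' sorensenDice(tf2, tf7)   # 2*2/7 = 0.571
#' @export
sorensenDice <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) && !length(b))
    .stopf("undefined: Sorensen-Dice of two empty communities")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Sorensen-Dice similarity matrix
#'
#' All pairwise similarities over a collection of communities -- for \code{n}
#' samples, \code{n(n-1)/2} informative off-diagonal cases. Counts are
#' binarized at >= 1 when an occurrence matrix is given.
#'
#' @param x a named list of species-label vectors, or an
#'   \linkS4class{OccurrenceExperiment} (samples = columns, presence =
#'   count >= 1).
#' @return a \linkS4class{SimilarityMatrix}.
#' @examples
#' m <- similarityMatrix(list(a = c("x", "y"), b = c("y", "z"), c = "w"))
#' similarityValues(m)["a", "b"]   # 0.5
#' @export
similarityMatrix <- function(x) {
  if (is(x, "OccurrenceExperiment")) {
    cts <- occurrenceCounts(x)
    x <- lapply(setNames(colnames(cts), colnames(cts)),
                function(s) rownames(cts)[cts[, s] >= 1])
  }
  if (!is.list(x) || length(x) < 2)
    .stopf("need at least 2 communities")
  if (is.null(names(x)) || anyDuplicated(names(x)))
    .stopf("input error: communities need unique sample names")
  n <- length(x)
  v <- diag(1, n)
  dimnames(v) <- list(names(x), names(x))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    v[i, j] <- v[j, i] <- sorensenDice(x[[i]], x[[j]])
  new("SimilarityMatrix", values = v)
}

#' Count zero-similarity cases
#'
#' Number of off-diagonal (upper-triangle) pairs with *exactly* zero
#' similarity. Because QS is a ratio of integers, a pair sharing no species
#' yields an exact floating-point 0, so no tolerance is involved.
#'
#' @param m a \linkS4class{SimilarityMatrix}.
#' @return integer count.
#' @examples
#' m <- similarityMatrix(list(a = "x", b = "y", c = "z", d = "w"))
#' zeroSimilarityCensus(m)   # 6: all pairs disjoint
#' @export
zeroSimilarityCensus <- function(m) {
  stopifnot(is(m, "SimilarityMatrix"))
  v <- similarityValues(m)
  sum(v[upper.tri(v)] == 0)
}
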