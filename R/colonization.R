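#' Colonization rate
#'
#' CR\% is the percentage of plated fragments yielding at least one isolate:
#' \code{100 * colonized_fragments / total_fragments}. A fragment colonized
#' by several species counts once, so CR needs fragment-level provenance: it
#' is only defined for samples whose \code{colonized_fragments} is known
#' (matrices built by [buildOccurrenceMatrix()] carry it; hand-made count
#' matrices may not).
#'
#' @param x an \linkS4class{OccurrenceExperiment}.
#' @param sample_id optional character vector of samples; default all.
#' @return data.frame with \code{sample_id}, \code{colonized_fragments},
#'   \code{total_fragments} and \code{cr_percent} (full precision; use
#'   [roundHalfUp()] for 2-decimal display).
#' @examples
#' oe <- OccurrenceExperiment(
#'   matrix(c(3L, 2L), 2, 1, dimnames = list(c("a", "b"), "TF1")),
#'   total_fragments = c(TF1 = 8L), colonized_fragments = 5L)
#' colonizationRate(oe)$cr_percent   # 62.5
#' @export
colonizationRate <- function(x, sample_id = NULL) {
  stopifnot(is(x, "OccurrenceExperiment"))
  if (is.null(sample_id)) sample_id <- colnames(x)
  missing_s <- setdiff(sample_id, colnames(x))
  if (length(missing_s))
    .stopf("unknown sample(s): %s", paste(missing_s, collapse = ", "))
  tot <- totalFragments(x)[sample_id]
  colz <- colonizedFragments(x)[sample_id]
  if (any(is.na(colz)))
    .stopf("colonization rate needs fragment-level data; colonized_fragments is NA for: %s",
           paste(sample_id[is.na(colz)], collapse = ", "))
  if (any(tot == 0)) .stopf("undefined denominator: total_fragments is 0")
  data.frame(sample_id = sample_id,
             colonized_fragments = as.integer(colz),
             total_fragments = as.integer(tot),
             cr_percent = 100 * colz / tot, row.names = NULL)
}

#' Colonization frequency
#'
#' CF\% is the percentage of plated fragments colonized by a given species:
#' \code{100 * count / denominator}, per sample or overall (overall
#' denominator = sum of the sample fragment totals; overall count of a
#' species = sum of its per-sample counts).
#'
#' @param x an \linkS4class{OccurrenceExperiment}.
#' @param scope \code{"per_sample"} (one row per (sample, species) pair) or
#'   \code{"overall"} (one row per species).
#' @param dense if \code{FALSE} (default) only species with count > 0 are
#'   reported; if \code{TRUE}, absent species appear with CF 0.
#' @return data.frame of \code{sample_id} (absent for overall scope),
#'   \code{species}, \code{count}, \code{denominator}, \code{cf_percent}.
#' @examples
#' oe <- OccurrenceExperiment(
#'   matrix(c(5L, 13L), 2, 1,
#'          dimnames = list(c("Preussia sp. 1", "Neofusicoccum sp. 3"), "LP2")),
#'   total_fragments = c(LP2 = 38L))
#' colonizationFrequency(oe)   # 13/38 = 34.21...
#' @export
colonizationFrequency <- function(x, scope = c("per_sample", "overall"),
                                  dense = FALSE) {
  stopifnot(is(x, "OccurrenceExperiment"))
  scope <- match.arg(scope)
  cts <- occurrenceCounts(x)
  tot <- totalFragments(x)
  if (scope == "overall") {
    cnt <- rowSums(cts)
    denom <- sum(tot)
    out <- data.frame(species = rownames(cts), count = as.integer(cnt),
                      denominator = denom,
                      cf_percent = 100 * cnt / denom, row.names = NULL)
    if (!dense) out <- out[out$count > 0, , drop = FALSE]
  } else {
    out <- do.call(rbind, lapply(colnames(cts), function(s) {
      data.frame(sample_id = s, species = rownames(cts),
                 count = as.integer(cts[, s]), denominator = tot[[s]],
                 cf_percent = 100 * cts[, s] / tot[[s]], row.names = NULL)
    }))
    if (!dense) out <- out[out$count > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summarize colonization rates
#'
#' Arithmetic mean and sample (n-1) standard deviation of a set of CR\%
#' values, matching the AVG/SD footer convention of survey CR tables. The SD
#' is \code{NA} (flagged) for a single value.
#'
#' @param cr_percent numeric vector of CR percentages (or the data.frame
#'   returned by [colonizationRate()]).
#' @return list with \code{mean}, \code{sd}, and \code{n}.
#' @examples
#' summarizeCR(c(0, 100))$mean   # 50
#' @export
summarizeCR <- function(cr_percent) {
  if (is.data.frame(cr_percent)) cr_percent <- cr_percent$cr_percent
  if (!length(cr_percent)) .stopf("empty input: no CR values to summarize")
  list(mean = mean(cr_percent),
       sd = if (length(cr_percent) > 1) sd(cr_percent) else NA_real_,
       n = length(cr_percent))
}
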