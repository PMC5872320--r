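#' Read an isolation-record table
#'
#' Reads one row per plant-fragment x emerged-species event from delimited
#' text. The header must name the columns \code{plant_id, island, locality,
#' medium, stem_age, fragment_id, species}; unknown extra columns are
#' ignored. Duplicate events -- the same species emerging from the same
#' \code{(plant_id, medium, stem_age, fragment_id)} -- are collapsed to a
#' single record, following the survey counting rule that a species isolated
#' twice from one fragment is counted once; the number of collapsed rows is
#' reported via \code{message()}. Distinct species co-colonizing one fragment
#' are all kept.
#'
#' @param path path to a CSV or TSV file (UTF-8).
#' @param delim field delimiter; \code{NULL} (default) auto-detects tab
#'   vs comma from the header line.
#' @return a data.frame of validated, deduplicated isolation records with the
#'   seven schema columns.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plant_id,island,locality,medium,stem_age,fragment_id,species",
#'              "TF1,Tenerife,MM,PDA,unspecified,f1,Alternaria alternata",
#'              "TF1,Tenerife,MM,PDA,unspecified,f1,Alternaria alternata"), f)
#' nrow(readIsolationTable(f))  # 1 -- the duplicate collapses
#' @export
readIsolationTable <- function(path, delim = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0 || !nzchar(header))
    .stopf("empty input: %s has no header line", path)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(.record_columns, names(df))
  if (length(missing_cols))
    .stopf("format error: missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  df <- df[.record_columns]
  for (col in .record_columns) df[[col]] <- as.character(df[[col]])
  validateIsolationRecords(df)
  key <- do.call(paste, c(df[c("plant_id", "medium", "stem_age",
                               "fragment_id", "species")], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate fragment/species row(s) collapsed")
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Validate a set of isolation records
#'
#' Checks the record schema: required columns present, non-empty species
#' labels, medium within PDA/LCA/V8 and stem age within the recognized
#' levels. Called by the readers and the simulator; exported because
#' user-assembled data frames can be checked the same way.
#'
#' @param records data.frame of isolation records.
#' @return the records, invisibly, if valid; otherwise an error.
#' @export
validateIsolationRecords <- function(records) {
  missing_cols <- setdiff(.record_columns, names(records))
  if (length(missing_cols))
    .stopf("format error: missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  if (nrow(records)) {
    if (any(!nzchar(records$species) | is.na(records$species)))
      .stopf("value error: empty species label")
    bad <- setdiff(unique(records$medium), .media_levels)
    if (length(bad))
      .stopf("value error: medium outside {%s}: %s",
             paste(.media_levels, collapse = ", "),
             paste(bad, collapse = ", "))
    bad_age <- setdiff(unique(records$stem_age), .stem_age_levels)
    if (length(bad_age))
      .stopf("value error: stem_age outside {%s}: %s",
             paste(.stem_age_levels, collapse = ", "),
             paste(bad_age, collapse = ", "))
  }
  invisible(records)
}

#' Write an isolation-record table
#'
#' Inverse of [readIsolationTable()]: writes the seven schema columns as
#' delimited text, so that read/write round-trips reproduce the record set.
#'
#' @param records data.frame of isolation records.
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
writeIsolationTable <- function(records, path, delim = ",") {
  validateIsolationRecords(records)
  write.table(records[.record_columns], path, sep = delim,
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an occurrence matrix from isolation records
#'
#' Aggregates records into an \linkS4class{OccurrenceExperiment} under a
#' grouping: each sample is the combination of the chosen grouping keys, its
#' count for a species is the number of *distinct* fragments yielding that
#' species, and its \code{colonized_fragments} is the number of distinct
#' fragments yielding at least one isolate. Fragment identity is the full
#' \code{(plant_id, medium, stem_age, fragment_id)} tuple. Fragment totals
#' are supplied as metadata, never inferred from records (uncolonized
#' fragments leave no record).
#'
#' @param records data.frame of isolation records (see
#'   [readIsolationTable()]).
#' @param grouping character vector of grouping keys, a subset of
#'   \code{c("plant_id", "locality", "island", "medium", "stem_age")};
#'   multi-key samples are labelled \code{key1/key2}.
#' @param frame_totals named integer vector: fragments plated per sample.
#'   Every sample observed in \code{records} must be named; samples named
#'   here but absent from the records yield all-zero columns. Sample order
#'   follows \code{names(frame_totals)}.
#' @return an \linkS4class{OccurrenceExperiment}; species rows are in
#'   lexicographic order.
#' @examples
#' rec <- data.frame(plant_id = "LP4", island = "La Palma", locality = "TIG",
#'                   medium = "PDA", stem_age = "unspecified",
#'                   fragment_id = paste0("f", 1:5),
#'                   species = "Preussia sp. 1")
#' oe <- buildOccurrenceMatrix(rec, "plant_id", c(LP4 = 20L))
#' occurrenceCounts(oe)["Preussia sp. 1", "LP4"]  # 5
#' @export
buildOccurrenceMatrix <- function(records, grouping = "plant_id",
                                  frame_totals) {
  validateIsolationRecords(records)
  allowed <- c("plant_id", "locality", "island", "medium", "stem_age")
  if (!length(grouping) || !all(grouping %in% allowed))
    .stopf("grouping must be a non-empty subset of {%s}",
           paste(allowed, collapse = ", "))
  if (is.null(names(frame_totals)))
    .stopf("configuration error: frame_totals must be named by sample")
  sample_of <- function(df) {
    if (!nrow(df)) return(character(0))
    do.call(paste, c(df[grouping], sep = "/"))
  }
  samp <- sample_of(records)
  unknown <- setdiff(unique(samp), names(frame_totals))
  if (length(unknown))
    .stopf("configuration error: no frame_total for sample(s): %s",
           paste(unknown, collapse = ", "))
  samples <- names(frame_totals)
  species <- sort(unique(records$species))
  cts <- matrix(0L, nrow = length(species), ncol = length(samples),
                dimnames = list(species, samples))
  colonized <- setNames(integer(length(samples)), samples)
  if (nrow(records)) {
    frag <- do.call(paste, c(records[c("plant_id", "medium", "stem_age",
                                       "fragment_id")], sep = "\r"))
    # distinct fragments per (sample, species)
    keep <- !duplicated(paste(samp, frag, records$species, sep = "\r"))
    tab <- table(factor(records$species[keep], levels = species),
                 factor(samp[keep], levels = samples))
    cts[] <- as.integer(tab)
    cz <- tapply(frag, factor(samp, levels = samples),
                 function(f) length(unique(f)))
    colonized[names(cz)] <- ifelse(is.na(cz), 0L, as.integer(cz))
  }
  meta <- NULL
  if (nrow(records)) {
    first <- records[!duplicated(samp), , drop = FALSE]
    rownames(first) <- sample_of(first)
    meta <- first[samples, grouping, drop = FALSE]
    rownames(meta) <- samples
  }
  OccurrenceExperiment(cts, frame_totals, colonized, colData = meta)
}
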