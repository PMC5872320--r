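#' Round half away from zero
#'
#' Commercial ("round half up") rounding used wherever 2-decimal display
#' values are reported; \code{base::round} rounds half to even, which does
#' not reproduce conventional field tables (e.g. 34.215 -> 34.22, not 34.21
#' vs 34.22 ambiguity under banker's rounding).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 2).
#' @return numeric vector rounded half up at \code{digits} decimals.
#' @examples
#' roundHalfUp(100 * 13 / 38)   # 34.21
#' roundHalfUp(0.445)           # 0.45
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  # small relative guard against representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## the enumerations the isolation-record schema admits
.media_levels <- c("PDA", "LCA", "V8")
.stem_age_levels <- c("le_1yr", "gt_1yr", "unspecified")
.record_columns <- c("plant_id", "island", "locality", "medium",
                     "stem_age", "fragment_id", "species")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
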