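#' Margalef species richness
#'
#' \code{d = (S - 1) / ln(N)}: species count normalized by the logarithm of
#' the number of individuals, 0 for a single-species sample.
#'
#' @param S integer, number of taxa (>= 1).
#' @param N integer, number of individuals (>= 2, so that ln N > 0; must be
#'   >= S).
#' @return the index at full precision.
#' @examples
#' margalef(11, 15)   # 3.6927 -> 3.69
#' @export
margalef <- function(S, N) {
  if (any(N < 2)) .stopf("domain error: margalef needs N >= 2")
  if (any(S > N)) .stopf("consistency error: S cannot exceed N")
  if (any(S < 1)) .stopf("domain error: S must be >= 1")
  (S - 1) / log(N)
}

#' Brillouin diversity
#'
#' \code{HB = (ln N! - sum_i ln n_i!) / N} for a fully censused collection
#' with abundances \code{n_i}. Computed through \code{lgamma}, so large
#' counts cannot overflow a factorial. Unlike Simpson's index it is not
#' invariant under scaling the abundances (e.g. (1,1,1) gives 0.60 but
#' (2,2,2) gives 0.75).
#'
#' @param n positive integer vector of per-species abundances.
#' @return the index (>= 0) at full precision.
#' @examples
#' brillouin(c(2, 1))   # 0.3662 -> 0.37
#' @export
brillouin <- function(n) {
  if (!length(n)) .stopf("empty input: no abundances")
  if (any(n < 1) || any(n != round(n)))
    .stopf("abundances must be positive integers")
  N <- sum(n)
  (lgamma(N + 1) - sum(lgamma(n + 1))) / N
}

#' Simpson diversity (1 - D)
#'
#' Probability that two individuals drawn at random belong to different
#' species. Two estimators are exposed: \code{"proportion_squared"},
#' \code{1 - sum((n_i/N)^2)} (the plug-in form, bounded above by
#' \code{1 - 1/S} and invariant under scaling \code{n -> k n}), and
#' \code{"unbiased"}, \code{1 - sum(n_i (n_i - 1)) / (N (N - 1))} (sampling
#' without replacement). The default is the plug-in form, which is what
#' standard desktop diversity software reports (e.g. it gives 0.50 for two
#' singletons, where the unbiased form gives 1).
#'
#' @param n positive integer vector of per-species abundances.
#' @param estimator \code{"proportion_squared"} (default) or
#'   \code{"unbiased"}.
#' @return the index in \[0, 1\] at full precision.
#' @examples
#' simpsonDiversity(c(2, 1))               # 1 - 5/9 = 0.444
#' simpsonDiversity(c(1, 1), "unbiased")   # 1
#' @export
simpsonDiversity <- function(n, estimator = c("proportion_squared",
                                              "unbiased")) {
  estimator <- match.arg(estimator)
  if (!length(n)) .stopf("empty input: no abundances")
  if (any(n < 1) || any(n != round(n)))
    .stopf("abundances must be positive integers")
  N <- sum(n)
  if (estimator == "proportion_squared") {
    1 - sum((n / N)^2)
  } else {
    if (N < 2) .stopf("domain error: unbiased Simpson needs N >= 2")
    1 - sum(n * (n - 1)) / (N * (N - 1))
  }
}

#' Fisher's log-series alpha
#'
#' Solves \code{S = a * ln(1 + N/a)} for \code{a > 0}. The function
#' \code{f(a) = a ln(1 + N/a) - S} increases strictly from \code{-S} toward
#' \code{N - S}, so for \code{S < N} a unique positive root exists; it is found by geometric
#' bracket expansion from \[1e-3, 1e6\] followed by Brent's derivative-free
#' method, then bisection polishing until the residual
#' \code{|a ln(1 + N/a) - S|} is below \code{tol}. When \code{S = N} (every
#' individual its own species) the root diverges to +Inf; the conventional
#' desktop-software sentinel 0 is returned with the \code{"degenerate"}
#' attribute set, rather than an error, so whole survey tables can be
#' profiled in one call.
#'
#' @param S integer, number of taxa (>= 1).
#' @param N integer, number of individuals (>= S).
#' @param tol residual tolerance (default 1e-9).
#' @param max_iter maximum polish iterations (default 200).
#' @return the root (or sentinel 0), with attribute \code{degenerate}
#'   (logical).
#' @examples
#' fisherAlpha(11, 15)   # 18.604 -> 18.60
#' fisherAlpha(5, 5)     # 0, degenerate
#' @export
fisherAlpha <- function(S, N, tol = 1e-9, max_iter = 200L) {
  if (S > N) .stopf("consistency error: S cannot exceed N")
  if (S < 1 || N < 1) .stopf("domain error: S and N must be >= 1")
  if (S == N) return(structure(0, degenerate = TRUE))
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-3; hi <- 1e6
  while (f(lo) > 0 && lo > 1e-300) lo <- lo / 10
  while (f(hi) < 0 && hi < 1e300) hi <- hi * 10
  a <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  iter <- 0L
  while (abs(f(a)) >= tol) {      # bisection polish on the residual
    iter <- iter + 1L
    if (iter > max_iter)
      .stopf("numeric error: fisherAlpha did not converge to tol %g", tol)
    if (f(a) < 0) lo <- a else hi <- a
    a <- (lo + hi) / 2
  }
  structure(a, degenerate = FALSE)
}

#' Alpha-diversity indices for one abundance vector
#'
#' @param n positive integer vector of per-species abundances (strain counts
#'   \code{n_i}).
#' @param estimator Simpson estimator, see [simpsonDiversity()].
#' @return one-row data.frame with \code{S}, \code{N}, \code{margalef},
#'   \code{brillouin}, \code{simpson_1d}, \code{fisher_alpha},
#'   \code{degenerate_fisher}. Margalef and Simpson are 0 for a
#'   single-species sample; Margalef is \code{NA} when \code{N < 2}.
#' @examples
#' diversityIndices(c(2, 1))
#' @export
diversityIndices <- function(n, estimator = c("proportion_squared",
                                              "unbiased")) {
  estimator <- match.arg(estimator)
  S <- length(n); N <- sum(n)
  fa <- fisherAlpha(S, N)
  data.frame(S = S, N = N,
             margalef = if (N >= 2) margalef(S, N) else NA_real_,
             brillouin = brillouin(n),
             simpson_1d = simpsonDiversity(n, estimator),
             fisher_alpha = as.numeric(fa),
             degenerate_fisher = attr(fa, "degenerate"))
}

#' Diversity profile of an occurrence matrix
#'
#' Computes the four alpha-diversity indices per sample, using each sample's
#' species counts (fragments colonized per species) as its abundance vector
#' \code{n_i}. All-zero samples are skipped with a warning.
#'
#' @param x an \linkS4class{OccurrenceExperiment}, or a named list of
#'   abundance vectors.
#' @param estimator Simpson estimator, see [simpsonDiversity()].
#' @param round if \code{TRUE}, report indices round-half-up at 2 decimals
#'   (the survey-table display convention); default full precision.
#' @return data.frame with one row per sample: \code{sample_id}, \code{S},
#'   \code{N} and the four indices.
#' @examples
#' diversityProfile(list(`TF4/IC` = c(2, 1)), round = TRUE)
#' @export
diversityProfile <- function(x, estimator = c("proportion_squared",
                                              "unbiased"),
                             round = FALSE) {
  estimator <- match.arg(estimator)
  ab <- if (is(x, "OccurrenceExperiment")) {
    cts <- occurrenceCounts(x)
    lapply(setNames(colnames(cts), colnames(cts)),
           function(s) cts[cts[, s] > 0, s])
  } else if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("sample", seq_along(x))
    x
  } else .stopf("x must be an OccurrenceExperiment or a list of vectors")
  empty <- vapply(ab, function(v) length(v) == 0L, TRUE)
  if (any(empty)) {
    warning("skipping sample(s) with no occurrences: ",
            paste(names(ab)[empty], collapse = ", "))
    ab <- ab[!empty]
  }
  if (!length(ab)) .stopf("no non-empty samples")
  out <- do.call(rbind, lapply(names(ab), function(s)
    cbind(sample_id = s, diversityIndices(ab[[s]], estimator))))
  rownames(out) <- NULL
  if (round) {
    for (col in c("margalef", "brillouin", "simpson_1d", "fisher_alpha"))
      out[[col]] <- roundHalfUp(out[[col]], 2)
  }
  out
}
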