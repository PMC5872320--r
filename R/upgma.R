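#' UPGMA agglomerative clustering
#'
#' Unweighted pair-group method with arithmetic mean: iteratively merges the
#' closest pair of clusters; the distance from a merged cluster to any other
#' is the size-weighted arithmetic average of its parts' distances, i.e. the
#' plain average over all member pairs. Ties on the minimal merge distance
#' are broken deterministically toward the lowest (row, column) index pair in
#' the current cluster ordering. The result is an ultrametric dendrogram:
#' every leaf sits at the same height below the root, and cophenetic
#' distances equal the merge heights.
#'
#' @param d a \code{dist} or a square symmetric numeric matrix with zero
#'   diagonal and non-negative entries (dissimilarities; similarity matrices
#'   are converted with \code{1 - QS} upstream, see [bootstrapSupport()]).
#' @return an object of class \code{c("upgma", "hclust")}: standard
#'   \code{merge}/\code{height}/\code{order}/\code{labels} structure, so
#'   \code{stats::cophenetic}, \code{plot} and \code{ape::as.phylo} all
#'   apply. Node height convention downstream: a leaf-to-node branch in the
#'   exported tree spans merge distance / 2.
#' @examples
#' d <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- upgma(d)
#' tr$height   # 0.2, 0.8
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2) .stopf("need at least 2 samples to cluster")
  if (ncol(m) != n || !isTRUE(all.equal(m, t(m))))
    .stopf("input error: distance matrix must be square and symmetric")
  if (any(m < 0)) .stopf("input error: negative distances")
  if (any(abs(diag(m)) > 1e-12)) .stopf("input error: non-zero diagonal")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  id <- -seq_len(n)          # hclust convention: negatives are leaves
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(id)
    best <- c(NA_integer_, NA_integer_); bmin <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (m[i, j] < bmin) { bmin <- m[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    pair <- c(id[i], id[j])   # hclust row convention: singletons first,
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]  # ascending index
    height[step] <- bmin
    # size-weighted average distance to every other cluster
    newd <- (size[i] * m[i, ] + size[j] * m[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    m <- rbind(cbind(m[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    id <- c(id[keep], step)
    size <- c(size[keep], size[i] + size[j])
  }
  leaf_order <- function(node)
    if (node < 0) -node else c(leaf_order(merge[node, 1]),
                               leaf_order(merge[node, 2]))
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1), labels = labels,
                 method = "upgma", call = match.call(),
                 dist.method = "user-supplied"),
            class = c("upgma", "hclust"))
}

# label sets of every internal node (bipartition keys), in merge order
.cladeKeys <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[s, ]
    get1 <- function(k) if (k < 0) tree$labels[-k] else sets[[k]]
    sets[[s]] <- sort(c(get1(kids[1]), get1(kids[2])))
  }
  vapply(sets, paste, "", collapse = "\r")
}

# Sorensen dissimilarity (1 - QS) from a samples x species presence matrix.
# A bootstrap replicate can leave a pair of samples with no species at all;
# QS is undefined there and the pair's dissimilarity is set to 1.
.sorensenDissimilarity <- function(bin) {
  bin <- (bin > 0) * 1
  A <- rowSums(bin)
  C <- tcrossprod(bin)
  denom <- outer(A, A, "+")
  qs <- ifelse(denom > 0, 2 * C / pmax(denom, 1), 0)
  empty_pairs <- sum(denom[upper.tri(denom)] == 0)
  d <- 1 - qs
  diag(d) <- 0
  attr(d, "undefined_pairs") <- empty_pairs
  d
}

#' Bootstrap support for a UPGMA dendrogram
#'
#' Builds the UPGMA tree of \code{1 - QS} Sorensen dissimilarities from a
#' presence/absence matrix, then resamples species columns with replacement
#' \code{n_iter} times, recomputes dissimilarities and the tree, and scores
#' each original internal bipartition by the percentage of replicates in
#' which it reappears. The root bipartition is present in every replicate,
#' so its support is 100 by construction. When a replicate leaves a pair of
#' samples with no species, that pair's QS is undefined and its dissimilarity
#' is set to 1; the number of such events is reported via \code{message()}.
#'
#' @param x an \linkS4class{OccurrenceExperiment} (binarized at count >= 1)
#'   or a samples x species presence/absence matrix with row names.
#' @param n_iter bootstrap iterations (conventionally 1000); 0 returns the
#'   tree without supports.
#' @param seed optional integer; fixing it makes supports reproducible.
#' @return an \code{ape} \code{phylo} tree; ultrametric, with branch lengths
#'   on the merge-distance/2 height convention and, for \code{n_iter > 0},
#'   \code{node.label} holding supports in \[0, 100\].
#' @examples
#' set.seed(1)
#' bin <- matrix(rbinom(5 * 30, 1, .4), 5, 30,
#'               dimnames = list(paste0("s", 1:5), NULL))
#' tr <- bootstrapSupport(bin, n_iter = 100, seed = 1)
#' tr$node.label
#' @export
bootstrapSupport <- function(x, n_iter = 1000L, seed = NULL) {
  bin <- if (is(x, "OccurrenceExperiment")) t(occurrenceCounts(x) >= 1) else
    as.matrix(x)
  if (nrow(bin) < 3) .stopf("need at least 3 samples")
  if (ncol(bin) < 1) .stopf("need at least 1 species")
  if (is.null(rownames(bin))) .stopf("samples need row names")
  if (!is.null(seed)) set.seed(seed)
  d0 <- .sorensenDissimilarity(bin)
  tree <- upgma(d0)
  phy <- ape::as.phylo(tree)
  if (n_iter <= 0) return(phy)

  keys <- .cladeKeys(tree)
  hits <- setNames(integer(length(keys)), keys)
  undefined <- 0L
  for (b in seq_len(n_iter)) {
    cols <- sample.int(ncol(bin), replace = TRUE)
    db <- .sorensenDissimilarity(bin[, cols, drop = FALSE])
    undefined <- undefined + attr(db, "undefined_pairs")
    kb <- .cladeKeys(upgma(db))
    present <- keys %in% kb
    hits[present] <- hits[present] + 1L
  }
  if (undefined > 0)
    message(undefined, " replicate pair(s) had no species; ",
            "their dissimilarity was set to 1")
  support <- 100 * hits / n_iter
  # map merge-order supports onto phylo internal nodes via their tip sets
  pp <- ape::prop.part(phy)
  node_keys <- vapply(pp, function(tips)
    paste(sort(phy$tip.label[tips]), collapse = "\r"), "")
  phy$node.label <- as.numeric(roundHalfUp(support[node_keys], 1))
  phy
}

#' Newick export
#'
#' Serializes a dendrogram to a Newick string with branch lengths from the
#' node heights (merge distance / 2, so cophenetic distances round-trip) and
#' bootstrap supports, when present, as internal node labels. Labels with
#' Newick-reserved characters are quoted by \code{ape}.
#'
#' @param tree a \code{phylo} (as from [bootstrapSupport()]) or an
#'   \code{hclust}/\code{upgma} tree (as from [upgma()]).
#' @return a single Newick string, parseable by \code{ape::read.tree}.
#' @examples
#' d <- matrix(c(0, .6, .6, 0), 2, 2, dimnames = list(c("A", "B"), NULL))
#' colnames(d) <- rownames(d)
#' toNewick(upgma(d))   # "(A:0.3,B:0.3);"
#' @export
toNewick <- function(tree) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) .stopf("tree must be phylo or hclust")
  ape::write.tree(tree)
}
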