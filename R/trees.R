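# Distance-based trees (NJ, UPGMA), bootstrap support, and tree comparison.
# Full maximum-likelihood tree search is deliberately out of scope; the
# alignment writers produce files external ML tools accept.

check_dist_input <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ (ape backend). Negative branch lengths, an artifact of the
#' NJ formulas on non-additive matrices, are clamped to zero with the
#' deficit moved to the sibling branch so path lengths are preserved where
#' possible.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with zero diagonal.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- check_dist_input(d)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sibs <- which(tr$edge[, 1L] == tr$edge[e, 1L])
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
      if (tr$edge.length[sibs[1L]] < 0) tr$edge.length[sibs[1L]] <- 0
    }
  }
  tr
}

#' UPGMA tree
#'
#' Average-linkage hierarchical clustering (phangorn backend); returns an
#' ultrametric rooted tree. Used in particular to build CBC trees from CBC
#' count matrices.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return A rooted ultrametric [ape::phylo] tree.
#' @export
upgma_tree <- function(d) {
  d <- check_dist_input(d)
  phangorn::upgma(stats::as.dist(d))
}

#' Joint-state p-distance matrix of an alignment
#'
#' Fraction of differing 12-state columns over columns where both rows are
#' ungapped; the distance the sequence-structure trees are built from.
#'
#' @param aln A `SeqStructAlignment`.
#' @param cols Optional column subset (for bootstrap resampling).
#' @return Symmetric matrix.
#' @export
ssaln_distance <- function(aln, cols = NULL) {
  st <- aln$states
  if (!is.null(cols)) st <- st[, cols, drop = FALSE]
  n <- nrow(st)
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      both <- st[a, ] != 0L & st[b, ] != 0L
      D[a, b] <- D[b, a] <- if (any(both)) {
        mean(st[a, both] != st[b, both])
      } else NA_real_
    }
  }
  D
}

#' Bootstrap support for a distance tree
#'
#' Alignment columns are resampled with replacement `reps` times; each
#' replicate's distance matrix is fed to `builder` and the support of every
#' internal bipartition of the full-data tree is the percentage of
#' replicates containing it. Deterministic for a fixed seed.
#'
#' @param aln A `SeqStructAlignment`.
#' @param builder Function from distance matrix to tree (default
#'   [nj_tree()]).
#' @param reps Number of pseudo-replicates (>= 1).
#' @param seed Random seed.
#' @return The full-data tree with `node.label` set to support percentages
#'   (`NA` on the root).
#' @export
bootstrap_support <- function(aln, builder = nj_tree, reps = 1000L,
                              seed = 1L) {
  if (reps < 1L) stop("reps must be >= 1")
  main <- builder(ssaln_distance(aln))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  L <- ncol(aln$states)
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, replace = TRUE)
    boots[[r]] <- builder(ssaln_distance(aln, cols = cols))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / reps, 1)
  main
}

#' Robinson-Foulds distance between two trees
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return Integer bipartition distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Collapse weakly supported edges
#'
#' Internal edges with support below `cutoff` (per the published-figure
#' convention of mapping only supports above 50) are collapsed into
#' polytomies.
#'
#' @param tree Tree with `node.label` support percentages.
#' @param cutoff Support cutoff (default 50).
#' @return A [ape::phylo] tree.
#' @export
collapse_low_support <- function(tree, cutoff = 50) {
  if (is.null(tree$node.label)) return(tree)
  lab <- suppressWarnings(as.numeric(tree$node.label))
  drop <- which(!is.na(lab) & lab < cutoff) + length(tree$tip.label)
  if (length(drop) == 0L) return(tree)
  internal <- tree$edge[, 2L] %in% drop
  tree$edge.length[internal] <- 0
  ape::di2multi(tree, tol = 1e-10)
}
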