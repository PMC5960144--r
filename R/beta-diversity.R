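# Pairwise community distances (Bray-Curtis, Jaccard, unweighted and weighted
# UniFrac) and full distance matrices. UniFrac is computed by a single
# postorder traversal that accumulates per-branch descendant mass for all
# samples at once.

#' Bray-Curtis dissimilarity between two samples
#'
#' @param x,y Count (or proportion) vectors over the same feature universe.
#' @return `sum(|x - y|) / sum(x + y)` in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (sum(x) + sum(y) <= 0) stop("both samples are empty")
  sum(abs(x - y)) / sum(x + y)
}

#' Jaccard distance between two samples
#'
#' Presence/absence by default (`1 - |A n B| / |A u B|` over the feature
#' supports), matching its use as the unweighted counterpart of Bray-Curtis.
#' `abundance = TRUE` gives the quantitative (Ruzicka) variant
#' `1 - sum(min) / sum(max)`.
#'
#' @param x,y Count vectors over the same feature universe.
#' @param abundance Use the abundance-weighted variant.
#' @return Distance in \[0, 1\].
#' @export
jaccard <- function(x, y, abundance = FALSE) {
  if (sum(x > 0) + sum(y > 0) == 0) stop("both samples are empty")
  if (abundance) {
    1 - sum(pmin(x, y)) / sum(pmax(x, y))
  } else {
    a <- x > 0
    b <- y > 0
    1 - sum(a & b) / sum(a | b)
  }
}

# Per-branch descendant mass for every sample in one postorder pass.
# props: features x samples proportion matrix. Returns list(len, P) where
# P[e, s] is the fraction of sample s's mass descending from edge e.
branch_mass <- function(tree, props) {
  tree <- validate_tree(tree)
  present <- rownames(props)[rowSums(props) > 0]
  miss <- setdiff(present, tree$tip.label)
  if (length(miss))
    stop("feature(s) present in samples but missing from tree: ",
         paste(miss[1:min(5, length(miss))], collapse = ", "))
  ntip <- length(tree$tip.label)
  nodes <- matrix(0, ntip + tree$Nnode, ncol(props))
  hit <- match(tree$tip.label, rownames(props))
  ok <- !is.na(hit)
  nodes[which(ok), ] <- props[hit[ok], , drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    nodes[po$edge[e, 1], ] <- nodes[po$edge[e, 1], ] + nodes[po$edge[e, 2], ]
  }
  list(len = po$edge.length, P = nodes[po$edge[, 2], , drop = FALSE])
}

unifrac_from_mass <- function(bm, i, j, weighted, normalized) {
  px <- bm$P[, i]
  py <- bm$P[, j]
  if (weighted) {
    raw <- sum(bm$len * abs(px - py))
    if (!normalized) return(raw)
    denom <- sum(bm$len * (px + py))
    if (denom == 0) stop("both samples are empty")
    raw / denom
  } else {
    ax <- px > 0
    ay <- py > 0
    denom <- sum(bm$len[ax | ay])
    if (denom == 0) stop("no observed branch length for this pair")
    sum(bm$len[xor(ax, ay)]) / denom
  }
}

pair_props <- function(x, y) {
  stopifnot(length(x) == length(y))
  m <- cbind(x = x / max(sum(x), 1e-300), y = y / max(sum(y), 1e-300))
  if (is.null(names(x))) stop("feature names required for UniFrac")
  rownames(m) <- names(x)
  m
}

#' Unweighted UniFrac distance between two samples
#'
#' Fraction of the branch length observed in either sample that leads
#' exclusively to taxa of one of them. Presence-only: invariant to abundance
#' rescaling.
#'
#' @param x,y Named count vectors (names = tree leaf labels).
#' @param tree Rooted [ape::phylo] tree with branch lengths covering all
#'   present features.
#' @return Distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(x, y, tree) {
  bm <- branch_mass(tree, pair_props(x, y))
  unifrac_from_mass(bm, 1, 2, weighted = FALSE, normalized = FALSE)
}

#' Weighted UniFrac distance between two samples
#'
#' `sum_b l_b |p_b(x) - p_b(y)|` over branches, where `p_b(s)` is the fraction
#' of sample `s`'s reads descending from branch `b`. The normalized variant
#' (default) divides by `sum_b l_b (p_b(x) + p_b(y))` so values are
#' comparable across pairs.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Divide by the maximum attainable value for this pair.
#' @return Distance (in \[0, 1\] when normalized).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  bm <- branch_mass(tree, pair_props(x, y))
  unifrac_from_mass(bm, 1, 2, weighted = TRUE, normalized = normalized)
}

#' All pairwise distances for a count table
#'
#' Bray-Curtis and Jaccard are delegated to [vegan::vegdist()]; UniFrac uses
#' the package's single-traversal implementation. Distance-based analyses are
#' conventionally run on rarefied counts (see [rarefy()]); this function does
#' not rarefy.
#'
#' @param x Count table (features x samples).
#' @param metric One of `"bray_curtis"`, `"jaccard"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param tree Rooted tree, required for the UniFrac metrics.
#' @param normalized Normalize weighted UniFrac (default `TRUE`).
#' @return A [stats::dist] over the samples.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "jaccard",
                                          "unweighted_unifrac",
                                          "weighted_unifrac"),
                            tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  validate_count_table(x)
  if (metric %in% c("bray_curtis", "jaccard")) {
    d <- if (metric == "bray_curtis") {
      vegan::vegdist(t(x), method = "bray")
    } else {
      vegan::vegdist(t(x), method = "jaccard", binary = TRUE)
    }
    return(d)
  }
  if (is.null(tree)) stop("a tree is required for UniFrac metrics")
  props <- sweep(x, 2, pmax(colSums(x), 1e-300), "/")
  bm <- branch_mass(tree, props)
  n <- ncol(x)
  m <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  weighted <- metric == "weighted_unifrac"
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- unifrac_from_mass(bm, i, j, weighted, normalized)
    }
  }
  stats::as.dist(m)
}
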