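# Hierarchical clustering of dissimilarity matrices and rooted-tree
# comparison metrics.  Trees are ape "phylo" objects throughout.

#' UPGMA clustering of a dissimilarity matrix
#'
#' Unweighted pair-group average linkage: clusters merge at half the mean
#' of all cross-pair dissimilarities (recomputed from the original
#' matrix), yielding an ultrametric rooted tree.  Labels are ordered
#' lexicographically before clustering so equal-distance ties resolve
#' deterministically toward the alphabetically smallest pair.
#'
#' @param d a symmetric zero-diagonal matrix (e.g. a \code{diss_matrix}),
#'   or a \code{dist} object.
#' @return a rooted ultrametric \code{phylo} tree.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(m))
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix or dist object")
  if (anyNA(d)) stop("dissimilarity matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix is asymmetric")
  if (nrow(d) < 2L) stop("need at least 2 samples")
  lab <- rownames(d)
  if (is.null(lab)) lab <- paste0("S", seq_len(nrow(d)))
  o <- order(lab)
  dm <- unclass(d)[o, o]
  h <- stats::hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(h)
}

#' Serialize / parse trees as Newick
#'
#' Thin wrappers over \code{ape}'s Newick reader and writer; topology,
#' labels and branch lengths round-trip.  Multifurcations and trees
#' without branch lengths (typical reference trees) are supported.
#'
#' @param tree a \code{phylo} object.
#' @param text a Newick string.
#' @param path optional file to write to / read from instead of a string.
#' @rdname newick
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

#' @rdname newick
#' @export
from_newick <- function(text = NULL, path = NULL) {
  tree <- if (!is.null(path)) ape::read.tree(path)
    else ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in Newick input")
  tree
}

# Per-tree triplet topology codes for all C(n,3) leaf triplets, leaves
# taken in the order of `labels`.  Code: 0 = unresolved (all three
# coalesce at one node), 1 = pair {1,2} deepest, 2 = pair {1,3},
# 3 = pair {2,3}, where indices refer to the sorted triplet.
.triplet_codes <- function(tree, labels) {
  n <- length(labels)
  tip <- match(labels, tree$tip.label)
  tree$edge.length <- rep(1, nrow(tree$edge))
  depth <- ape::node.depth.edgelength(tree)  # root = 0, downwards
  mr <- ape::mrca(tree)                       # tip x tip MRCA node ids
  mr <- mr[tip, tip]
  trip <- utils::combn(n, 3)
  a <- trip[1, ]; b <- trip[2, ]; c <- trip[3, ]
  dab <- depth[mr[cbind(a, b)]]
  dac <- depth[mr[cbind(a, c)]]
  dbc <- depth[mr[cbind(b, c)]]
  code <- integer(ncol(trip))
  code[dab > dac & dab > dbc] <- 1L
  code[dac > dab & dac > dbc] <- 2L
  code[dbc > dab & dbc > dac] <- 3L
  code
}

#' Rooted triples distance between two trees
#'
#' Number of 3-leaf subsets on which the two rooted trees induce
#' different topologies.  Each triplet is categorised by which pair
#' coalesces below the triplet's deepest coalescence, or as unresolved
#' when all three leaves meet at one (multifurcating) node; a
#' resolved-vs-unresolved disagreement counts as a difference.
#'
#' @param t1,t2 rooted \code{phylo} trees on the same leaf set (n >= 3).
#' @return non-negative integer, at most \code{choose(n, 3)}.
#' @export
triples_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  labels <- sort(t1$tip.label)
  if (!identical(labels, sort(t2$tip.label)))
    stop("trees have different leaf-label sets")
  if (length(labels) < 3L) stop("need at least 3 leaves")
  sum(.triplet_codes(t1, labels) != .triplet_codes(t2, labels))
}

# Non-trivial clades of a rooted tree as canonical label strings
# (sorted tips, "|"-joined); excludes singletons and the full leaf set.
.clade_set <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  cl <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"),
               character(1))
  sizes <- lengths(pp)
  unique(cl[sizes > 1 & sizes < n])
}

#' Clade symmetric difference between two rooted trees
#'
#' Represents every internal node by its leaf cluster and counts the
#' clades present in exactly one of the two trees (non-trivial clades
#' only: singletons and the full leaf set are shared by construction).
#'
#' @param t1,t2 rooted \code{phylo} trees on the same leaf set.
#' @return non-negative integer.
#' @export
symmetric_difference <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!identical(sort(t1$tip.label), sort(t2$tip.label)))
    stop("trees have different leaf-label sets")
  s1 <- .clade_set(t1)
  s2 <- .clade_set(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Random sequentially-joined rooted tree
#'
#' Builds a rooted binary tree by repeatedly joining a uniformly chosen
#' pair of the current clusters; the null model for tree-distance
#' calibration.
#'
#' @param labels leaf labels.
#' @param seed optional RNG seed (caller state restored).
#' @return a rooted \code{phylo} tree without branch lengths.
#' @export
random_join_tree <- function(labels, seed = NULL) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 labels")
  .with_seed(seed, {
    sub <- as.list(labels)
    while (length(sub) > 1L) {
      pick <- sample.int(length(sub), 2L)
      merged <- paste0("(", sub[[pick[1]]], ",", sub[[pick[2]]], ")")
      sub <- c(sub[-pick], merged)
    }
    from_newick(paste0(sub[[1]], ";"))
  })
}

#' Null distribution of a tree distance over random trees
#'
#' Draws \code{n_trees} random sequentially-joined trees on the leaf set
#' and computes their distance to the reference tree; the observed
#' tree's distance is located in that null with the add-one permutation
#' p-value \code{(1 + #\{null <= observed\}) / (n_trees + 1)}.
#'
#' @param observed_tree,reference_tree rooted \code{phylo} trees on the
#'   same leaf set.
#' @param n_trees number of random trees (default 3000).
#' @param metric \code{"triples"} or \code{"sd"}.
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{distribution} (length
#'   \code{n_trees}) and \code{p_value}.
#' @export
random_tree_null <- function(observed_tree, reference_tree,
                             n_trees = 3000L, metric = c("triples", "sd"),
                             seed = NULL) {
  metric <- match.arg(metric)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  fun <- if (metric == "triples") triples_distance else symmetric_difference
  obs <- fun(observed_tree, reference_tree)
  labels <- reference_tree$tip.label
  .with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
    dist <- vapply(seeds, function(s)
      fun(random_join_tree(labels, seed = s), reference_tree), numeric(1))
    list(observed = obs, distribution = dist,
         p_value = (1 + sum(dist <= obs)) / (n_trees + 1))
  })
}
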