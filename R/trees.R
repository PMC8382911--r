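#' Node ages of a dated (ultrametric) tree
#'
#' Ages are measured back from the leaves: all leaves at age 0, the root
#' maximal. Small numerical deviations from ultrametricity (relative 1e-8)
#' are tolerated and leaf ages snapped to exactly 0.
#'
#' @param tree Rooted ultrametric `phylo` tree.
#' @return Numeric vector of ages indexed by node id (tips first, as in
#'   `phylo` numbering).
#' @export
node_ages <- function(tree) {
  .check_tree(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  tip_depth <- depth[seq_len(n_tip)]
  h <- max(tip_depth)
  if (h > 0 && diff(range(tip_depth)) > 1e-8 * h)
    stop("tree is not ultrametric: leaf depths differ")
  ages <- h - depth
  ages[seq_len(n_tip)] <- 0
  ages
}

.validate_dated_tree <- function(tree) {
  ages <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  internal <- ages[(n_tip + 1):length(ages)]
  par_age <- ages[tree$edge[, 1]]
  chi_age <- ages[tree$edge[, 2]]
  if (any(par_age <= chi_age))
    stop("parent age must be strictly greater than child age")
  if (anyDuplicated(signif(internal, 12)))
    stop("tied internal node ages; jitter ages to make them distinct")
  ages
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}), with negative
#' estimated branch lengths clamped to zero. The result is returned in the
#' usual unrooted representation (rooted at a trifurcation); root it with
#' [midpoint_root()] or `ape::root()`.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and taxon
#'   names as dimnames; at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 3) stop("at least 3 taxa are required")
  if (is.null(rownames(distances))) stop("distance matrix must carry taxon names")
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  tr <- ape::nj(distances)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. If the
#' midpoint falls exactly on an existing node, that node becomes the root.
#'
#' @param tree A `phylo` tree with at least 2 leaves and finite,
#'   non-negative branch lengths, not all zero.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  .check_tree(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) stop("tree must have at least 2 leaves")
  if (sum(tree$edge.length) <= 0)
    stop("all branch lengths are zero: no unique midpoint")
  if (n_tip == 2) {
    half <- sum(tree$edge.length) / 2
    out <- tree
    out$edge.length <- rep(half, nrow(out$edge))
    return(out)
  }
  phangorn::midpoint(tree)
}

#' Rescale a tree to a target mean root-to-tip path length
#'
#' Multiplies all branch lengths by a common factor so that the mean
#' root-to-tip path equals `height` (used to convert simulated time-unit
#' trees to expected replacements per site).
#'
#' @param tree Rooted `phylo` tree.
#' @param height Target mean root-to-tip path length.
#' @export
scale_tree_height <- function(tree, height) {
  .check_tree(tree)
  depth <- ape::node.depth.edgelength(tree)
  mean_rt <- mean(depth[seq_along(tree$tip.label)])
  if (mean_rt <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length * (height / mean_rt)
  tree
}

# internal-node labels, assigning stable defaults where absent
.node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab) || !length(lab)) lab <- rep("", tree$Nnode)
  empty <- !nzchar(lab)
  lab[empty] <- paste0("nd", seq_len(tree$Nnode) + n_tip)[empty]
  lab
}
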