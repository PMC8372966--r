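#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of two tips equals the shared
#' root-to-MRCA path length, and each tip's variance equals its
#' root-to-tip depth (constant on an ultrametric chronogram). Computed
#' from scratch by a postorder sweep: pairs of tips falling in distinct
#' child subtrees of a node share exactly that node's depth.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return Species x species covariance matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree) {
  n <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_node <- n + tree$Nnode
  depth <- numeric(n_node)
  for (i in seq_len(nrow(tree$edge)))
    depth[tree$edge[i, 2L]] <- depth[tree$edge[i, 1L]] + tree$edge.length[i]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  tips_below <- vector("list", n_node)
  # postorder over internal nodes: children appear after parents in
  # cladewise edge order, so walk edges backwards
  for (i in seq_len(n)) tips_below[[i]] <- i
  for (v in rev(unique(tree$edge[, 1L]))) {
    ch <- kids[[as.character(v)]]
    sets <- tips_below[ch]
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a < b) C[sets[[a]], sets[[b]]] <- depth[v]
      }
    }
    tips_below[[v]] <- unlist(sets)
  }
  C <- C + t(C)
  diag(C) <- depth[seq_len(n)]
  d <- diag(C)
  if (diff(range(d)) > 1e-8 * max(d))
    warning("tree is not ultrametric: tip depths vary")
  C
}

#' Pairwise phylogenetic distances from a covariance matrix
#'
#' `d_ij = C_ii + C_jj - 2 C_ij`, the Brownian-motion expected squared
#' divergence scale; on ultrametric trees this equals the patristic
#' (tip-to-tip path) distance.
#'
#' @param C a covariance matrix from [phylo_covariance()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
phylo_pair_distance <- function(C) {
  d <- diag(C)
  D <- outer(d, d, "+") - 2 * C
  diag(D) <- 0
  D
}
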