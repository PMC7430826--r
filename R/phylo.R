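#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion
#' `Q_ij = (n - 2) d_ij - r_i - r_j`. Ties in Q are broken by the smallest
#' label-sorted pair (internal nodes inherit the smallest label among their
#' leaves), so the result is deterministic and invariant to input order.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sibling branch, preserving the joined pair's path length. On an
#' additive matrix the tree's path distances reproduce the input exactly.
#'
#' @param d symmetric labeled distance matrix with at least 3 taxa.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(d)  # pendant branches 2, 3, 7
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs)) stop("d must have unique labels")
  if (nrow(d) < 3) stop("neighbor joining requires at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("d must be symmetric")
  if (any(!is.finite(d))) stop("d must be finite")
  # newick fragment and tie-break key per active node; quote labels only
  # when they contain characters Newick reserves
  needs_quote <- grepl("[^A-Za-z0-9_.|-]", labs)
  frag <- ifelse(needs_quote, sprintf("'%s'", gsub("'", "''", labs)), labs)
  key <- labs
  D <- unname(d)
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
    k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- order(k1, k2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    newkey <- min(key[i], key[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    D <- D2
  }
  la <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  lb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  lc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], max(la, 0), frag[2], max(lb, 0), frag[3],
                 max(lc, 0))
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup_label a tip label present in the tree.
#' @return a rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  tip <- match(outgroup_label, tree$tip.label)
  if (is.na(tip)) stop("unknown tip label: ", outgroup_label)
  edge <- which(tree$edge[, 2] == tip)
  phytools::reroot(tree, tip, position = tree$edge.length[edge] / 2)
}

#' Test a set of tips for monophyly
#'
#' TRUE when the smallest clade containing all the query tips contains no
#' other tips.
#'
#' @param tree an `ape::phylo` tree (root it first for a rooted reading).
#' @param labels tip labels to test.
#' @return logical.
#' @export
is_monophyletic <- function(tree, labels) {
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing)) stop("unknown tip label: ", missing[1])
  ape::is.monophyletic(tree, labels)
}

#' Cophenetic (path) distances of a tree
#'
#' Convenience wrapper returning tip-to-tip path lengths, used to verify
#' that neighbor joining reproduces additive matrices.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return symmetric labeled matrix of path distances.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
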