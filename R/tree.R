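# Neighbor-joining trees and tree utilities.
#
# Trees are plain ape "phylo" objects with branch lengths in the same
# fractional units as the K2P matrix, so patristic distances are directly
# comparable to model distances. NJ is implemented here (Saitou-Nei
# Q-criterion, deterministic first-minimum tie-breaking in current node
# order, negative branch lengths clamped to zero); rooting, monophyly,
# patristic distances and newick I/O delegate to ape/phangorn.

fmt_len <- function(x) sprintf("%.15g", x)

#' Build a neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair (i, j) minimizing
#' Q(i, j) = (m - 2) d(i, j) - r_i - r_j. Ties are broken deterministically
#' by the first minimal pair in current node order (input leaf order, merged
#' nodes appended), so runs are reproducible without seeds. Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero
#' to keep patristic distances metric-like.
#'
#' @param distance_matrix symmetric matrix with dimnames, no \code{NA}
#'   entries, at least 3 taxa
#' @return An unrooted \code{phylo} tree (trifurcating root node).
#' @export
build_nj <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must carry row names")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("undefined distance for pair (", labs[bad[1L, 1L]], ", ",
         labs[bad[1L, 2L]], ")")
  }
  frag <- labs
  act <- D
  while (nrow(act) > 3L) {
    m <- nrow(act)
    r <- rowSums(act)
    Q <- (m - 2) * act - outer(r, r, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- act[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- act[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    merged <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(vi),
                      frag[j], fmt_len(vj))
    dnew <- (act[i, ] + act[j, ] - act[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    act <- act[-c(i, j), -c(i, j), drop = FALSE]
    act <- rbind(cbind(act, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], merged)
  }
  d12 <- act[1L, 2L]; d13 <- act[1L, 3L]; d23 <- act[2L, 3L]
  a <- max((d12 + d13 - d23) / 2, 0)
  b <- max((d12 + d23 - d13) / 2, 0)
  cc <- max((d13 + d23 - d12) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1L], fmt_len(a), frag[2L], fmt_len(b),
                 frag[3L], fmt_len(cc))
  ape::read.tree(text = nwk)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (delegates to \code{phangorn::midpoint}). Used before monophyly
#' assessment, since clades are only defined on rooted trees.
#'
#' @param tree a \code{phylo} tree with branch lengths
#' @return A rooted \code{phylo} tree.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Is a set of leaves monophyletic?
#'
#' TRUE iff the smallest clade of the rooted tree containing every label in
#' \code{label_set} contains no other leaves. A singleton is trivially
#' monophyletic.
#'
#' @param tree a rooted \code{phylo} tree
#' @param label_set character vector of tip labels
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, label_set) {
  unknown <- setdiff(label_set, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(label_set) <= 1L) return(TRUE)
  ape::is.monophyletic(tree, tips = label_set)
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the path between leaves
#' i and j (delegates to \code{cophenetic.phylo}).
#'
#' @param tree a \code{phylo} tree with branch lengths
#' @return Symmetric matrix in tip-label order.
#' @export
patristic_matrix <- function(tree) {
  M <- stats::cophenetic(tree)
  M[tree$tip.label, tree$tip.label]
}

#' Newick input/output
#'
#' Thin wrappers over \code{ape::read.tree}/\code{ape::write.tree} so trees
#' round-trip with branch lengths preserved.
#'
#' @param text newick string
#' @return \code{parse_newick}: a \code{phylo}; \code{write_newick}: a
#'   newick string.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed newick: ", substr(text, 1, 60))
  tree
}

#' @rdname parse_newick
#' @param tree a \code{phylo} tree
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}
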