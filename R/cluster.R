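# Distance-based subfamily grouping: identity distances from global
# alignments, neighbour joining with deterministic tie-breaking, and a
# bipartition (monophyly) check on the resulting unrooted trees.

#' Pairwise identity distances
#'
#' `d = 1 - identity` of the global Needleman-Wunsch alignment (BLOSUM62,
#' gap 11/1), where identity counts identical positions over alignment
#' columns.  Optionally Poisson-corrected (`-ln(1 - d)`) for multiple hits;
#' the raw identity distance is the default since only clade structure, not
#' branch length, is interpreted downstream.
#'
#' @param seqs Named character vector of at least two non-empty sequences.
#' @param correction `"raw"` or `"poisson"`.
#' @inheritParams smith_waterman
#' @return Symmetric numeric matrix with zero diagonal, taxa in input order.
#' @export
pairwise_distances <- function(seqs, correction = c("raw", "poisson"),
                               matrix = "BLOSUM62", gap_open = 11,
                               gap_extend = 1) {
  correction <- match.arg(correction)
  if (length(seqs) < 2) abort("need at least two sequences")
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence: ",
                 paste(names(seqs)[!nzchar(seqs)], collapse = ", ")))
  }
  n <- length(seqs)
  D <- base::matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 1 - global_identity(seqs[[i]], seqs[[j]], matrix,
                               gap_open, gap_extend)
      if (correction == "poisson") d <- -log(pmax(1 - d, 1e-12))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbour-joining tree
#'
#' Standard neighbour-joining agglomeration with two determinism/sanity
#' refinements: when several pairs minimise the Q criterion (within a small
#' numerical tolerance) the lexicographically smallest pair of current
#' cluster labels is merged, and a negative branch length is clamped to zero
#' with the deficit shifted onto its sister branch so path lengths are
#' preserved.
#'
#' @param D Symmetric distance matrix (>= 3 taxa, zero diagonal) with
#'   dimnames, as from [pairwise_distances()].
#' @param tol Numerical tolerance for Q-criterion ties.
#' @return Unrooted binary tree of class `phylo` (ape).
#' @examples
#' D <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' tr <- neighbor_joining(D)
#' is_clade(tr, c("A", "B"))
#' @export
neighbor_joining <- function(D, tol = 1e-9) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix is not symmetric")
  if (any(diag(D) != 0)) abort("distance matrix must have a zero diagonal")
  n <- nrow(D)
  if (n < 3) abort("need at least three taxa")
  labels <- rownames(D) %||% as.character(seq_len(n))
  rownames(D) <- colnames(D) <- NULL

  # active clusters hold partial newick strings
  newick <- labels
  active <- seq_len(n)
  Dw <- D
  clamp_pair <- function(li, lj) {
    # shift any negative length onto the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) sprintf("%.10g", x)

  while (length(active) > 3) {
    r <- length(active)
    sums <- rowSums(Dw)
    # Q criterion
    Q <- (r - 2) * Dw - outer(sums, sums, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest eligible pair of cluster labels
    key <- map_chr(seq_len(nrow(cand)), function(t) {
      pair <- sort(c(newick[active[cand[t, 1]]], newick[active[cand[t, 2]]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dw[i, j]
    li <- dij / 2 + (sums[i] - sums[j]) / (2 * (r - 2))
    lj <- dij - li
    ll <- clamp_pair(li, lj)
    merged <- paste0("(", newick[active[i]], ":", fmt(ll[1]), ",",
                     newick[active[j]], ":", fmt(ll[2]), ")")
    # distances to the new node
    dnew <- (Dw[i, ] + Dw[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newick[length(newick) + 1] <- merged
    active <- c(active[keep], length(newick))
  }

  # final three-point join
  d12 <- Dw[1, 2]; d13 <- Dw[1, 3]; d23 <- Dw[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- paste0("(", newick[active[1]], ":", fmt(l1), ",",
                newick[active[2]], ":", fmt(l2), ",",
                newick[active[3]], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Is a label set a clade of an unrooted tree?
#'
#' True iff some edge of the tree bipartitions the taxa exactly into
#' `labels` versus the rest.  Singletons and the full taxon set are
#' trivially clades.
#'
#' @param tree A `phylo` tree.
#' @param labels Character vector of tip labels (all must be in the tree).
#' @return Logical.
#' @export
is_clade <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown)) {
    abort(paste0("unknown taxon label(s): ", paste(unknown, collapse = ", ")))
  }
  labels <- unique(labels)
  if (length(labels) %in% c(1L, length(tips))) return(TRUE)
  target <- sort(labels)
  ntip <- length(tips)
  # tip sets under each internal node (arbitrary rooting); each edge's
  # bipartition is {descendant tips} vs complement
  desc <- map(seq_len(ntip + tree$Nnode), function(i) character())
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  # process edges child-first (postorder)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    side <- sort(unique(desc[[node]]))
    if (identical(side, target) ||
        identical(sort(setdiff(tips, side)), target)) {
      return(TRUE)
    }
  }
  # tip edges handled by the singleton shortcut above
  FALSE
}
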