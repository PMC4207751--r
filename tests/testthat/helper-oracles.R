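# Independent oracles used to cross-check the dynamic-programming code
# paths: exhaustive chain enumeration, exhaustive local-alignment
# enumeration over monotone index pairings, and random pattern/tree
# generators.

test_profiles <- acyl_profiles()

# exhaustive enumeration of all in-order, non-overlapping occurrence
# combinations; independent of the DP in scan_chain()
brute_chain_score <- function(seq, prof, dbm_mode = "soft",
                              dbm_penalty = 0.5, motifs = 1:4) {
  occ <- lapply(motifs, function(k) {
    as.data.frame(find_occurrences(prof$motifs[[k]], seq))
  })
  if (any(vapply(occ, nrow, 0L) == 0)) return(NULL)
  idx <- expand.grid(lapply(occ, function(o) seq_len(nrow(o))))
  best <- -Inf
  for (r in seq_len(nrow(idx))) {
    off <- vapply(seq_along(motifs), function(k) occ[[k]]$offset[idx[r, k]], 0L)
    len <- vapply(seq_along(motifs), function(k) occ[[k]]$length[idx[r, k]], 0L)
    sc <- sum(vapply(seq_along(motifs), function(k) occ[[k]]$score[idx[r, k]], 0))
    d <- off[-1] - (off[-length(off)] + len[-length(len)])
    if (any(d < 0)) next
    ok <- TRUE
    for (k in seq_along(d)) {
      rng <- prof$dbm[[motifs[k]]]
      outside <- max(rng[1] - d[k], d[k] - rng[2], 0)
      if (outside > 0) {
        if (dbm_mode == "hard") { ok <- FALSE; break }
        sc <- sc - dbm_penalty * outside
      }
    }
    if (ok && sc > best) best <- sc
  }
  if (is.finite(best)) best else NULL
}

# exhaustive local alignment with affine gaps: enumerate every pair of
# equal-size increasing index subsets (aligned columns); a length-g gap
# segment costs open + extend * g.  Feasible for sequences up to ~8
# residues, and entirely independent of the alignment library.
brute_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  gapcost <- function(g) if (g == 0) 0 else gap_open + gap_extend * g
  best <- 0
  for (k in seq_len(min(na, nb))) {
    ia <- utils::combn(na, k, simplify = FALSE)
    ib <- utils::combn(nb, k, simplify = FALSE)
    for (I in ia) {
      for (J in ib) {
        sc <- sum(mat[cbind(av[I], bv[J])])
        if (k > 1) {
          sc <- sc - sum(vapply(diff(I) - 1, gapcost, 0)) -
            sum(vapply(diff(J) - 1, gapcost, 0))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

aa20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

# random degenerate pattern (no optional positions unless asked)
random_pattern <- function(len = NULL, allow_optional = FALSE) {
  if (is.null(len)) len <- sample(5:9, 1)
  toks <- vapply(seq_len(len), function(i) {
    kind <- sample(c("lit", "x", "phi", "pi", "alt"), 1,
                   prob = c(0.4, 0.2, 0.15, 0.1, 0.15))
    switch(kind,
           lit = sample(aa20, 1),
           x = "x", phi = "phi", pi = "pi",
           alt = paste0("[", paste(sample(c("A","C","D","E","F","G","H","K"), 2),
                                   collapse = "/"), "]"))
  }, "")
  if (allow_optional) {
    j <- sample(seq_len(len), 1)
    toks[j] <- "[-/N]"
  }
  parse_pattern(paste(toks, collapse = " "))
}

# draw one full-length string matching a pattern (optional positions kept)
sample_from_pattern <- function(p) {
  paste(vapply(p$positions, function(sp) sample(sp$allowed, 1), ""),
        collapse = "")
}

# canonical split set of an unrooted tree (each nontrivial bipartition as a
# sorted label string of the smaller side)
unrooted_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    desc[[ord$edge[e, 1]]] <- c(desc[[ord$edge[e, 1]]], desc[[ord$edge[e, 2]]])
  }
  out <- character()
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    side <- sort(unique(desc[[node]]))
    other <- sort(setdiff(tips, side))
    if (length(side) < 2 || length(other) < 2) next
    pick <- if (length(side) < length(other) ||
                (length(side) == length(other) &&
                 paste(side, collapse = ",") < paste(other, collapse = ","))) {
      side
    } else {
      other
    }
    out <- c(out, paste(pick, collapse = ","))
  }
  sort(unique(out))
}
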