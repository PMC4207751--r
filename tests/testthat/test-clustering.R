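# Identity distances, neighbour joining and the monophyly check.

test_that("identity distances behave at the extremes", {
  s <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  D <- pairwise_distances(c(a = s, b = s, c = paste(rep("W", 50), collapse = "")))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)   # no identical aligned positions
  expect_equal(D, t(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_error(pairwise_distances(c(a = "ACD", b = "")), "empty")
  expect_error(pairwise_distances(c(a = "ACD")), "two")
})

test_that("distance tracks the simulated substitution rate", {
  set.seed(11)
  s <- paste(sample(aa20, 500, replace = TRUE), collapse = "")
  m <- mutate_protein(s, 0.1)
  D <- pairwise_distances(c(a = s, b = m))
  expect_lt(abs(D["a", "b"] - 0.1), 0.05)
})

test_that("three taxa give the unique topology with three-point lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  path <- ape::cophenetic.phylo(tr)
  expect_equal(path[rownames(D), colnames(D)], D)
})

test_that("a four-taxon additive matrix recovers its split", {
  tree_txt <- "((A:1,B:1):1,(C:1,D:1):1);"
  D <- ape::cophenetic.phylo(ape::read.tree(text = tree_txt))
  # verify additivity by the four-point condition first
  sums <- c(D["A", "B"] + D["C", "D"], D["A", "C"] + D["B", "D"],
            D["A", "D"] + D["B", "C"])
  expect_equal(sort(sums)[2], sort(sums)[3])
  tr <- neighbor_joining(D)
  expect_true(is_clade(tr, c("A", "B")))
  expect_true(is_clade(tr, c("C", "D")))
  expect_false(is_clade(tr, c("A", "C")))
})

test_that("the split set is invariant under taxon permutations", {
  set.seed(13)
  ref <- ape::rtree(7)
  D <- ape::cophenetic.phylo(ref)
  base_splits <- unrooted_splits(neighbor_joining(D))
  for (rep in 1:5) {
    perm <- sample(rownames(D))
    expect_equal(unrooted_splits(neighbor_joining(D[perm, perm])),
                 base_splits)
  }
})

test_that("NJ recovers generating topologies and matches ape's implementation", {
  set.seed(14)
  for (rep in 1:10) {
    k <- sample(6:10, 1)
    ref <- ape::rtree(k)
    ref$edge.length <- stats::runif(length(ref$edge.length), 0.3, 1.5)
    D <- ape::cophenetic.phylo(ref)
    tr <- neighbor_joining(D)
    expect_equal(unrooted_splits(tr), unrooted_splits(ref))
    # independent implementation agrees on the topology
    expect_equal(unrooted_splits(ape::nj(D)), unrooted_splits(tr))
  }
})

test_that("degenerate inputs are rejected and negatives are clamped", {
  D <- matrix(c(0, 1, 1, 2, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D), "symmetric")
  D2 <- matrix(0.5, 2, 2); diag(D2) <- 0
  expect_error(neighbor_joining(D2), "three")
  # near-zero distances can produce negative NJ branch estimates; the tree
  # must still come back with non-negative lengths
  set.seed(15)
  seqs <- c(a = paste(sample(aa20, 80, replace = TRUE), collapse = ""))
  seqs["b"] <- mutate_protein(seqs[["a"]], 0.02)
  seqs["c"] <- mutate_protein(seqs[["a"]], 0.02)
  seqs["d"] <- mutate_protein(seqs[["a"]], 0.6)
  tr <- neighbor_joining(pairwise_distances(seqs))
  expect_true(all(tr$edge.length >= 0))
})

test_that("is_clade checks bipartitions of the unrooted tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  expect_true(is_clade(tr, "A"))
  expect_true(is_clade(tr, c("A", "B", "C", "D", "E")))
  expect_true(is_clade(tr, c("D", "E")))
  expect_true(is_clade(tr, c("C", "D", "E")))
  # complements of clades are clades of the unrooted tree
  expect_true(is_clade(tr, c("A", "B", "C")))
  expect_false(is_clade(tr, c("B", "D")))
  expect_error(is_clade(tr, "Z"), "Z")
  # cross-check against phangorn's split decomposition
  set.seed(16)
  for (rep in 1:5) {
    rt <- ape::rtree(8)
    splits <- phangorn::as.splits(rt)
    labs <- attr(splits, "labels")
    for (i in seq_along(splits)) {
      side <- labs[splits[[i]]]
      expect_true(is_clade(rt, side))
    }
    expect_equal(is_clade(rt, labs[c(1, 5)]),
                 paste(sort(labs[c(1, 5)]), collapse = ",") %in%
                   unrooted_splits(rt) ||
                   paste(sort(setdiff(labs, labs[c(1, 5)])), collapse = ",") %in%
                   unrooted_splits(rt))
  }
})

test_that("planted subclasses form monophyletic groups at low divergence", {
  set.seed(18)
  mono <- 0
  n_rep <- 5
  ortho_set <- function(prof, n, tag) {
    founder <- generate_family(prof, n = 1)
    stats::setNames(vapply(seq_len(n), function(i) {
      mutate_protein(founder$sequence, 0.05,
                     protect = founder$protected[[1]],
                     constraints = founder$constraints[[1]])
    }, ""), paste0(tag, seq_len(n)))
  }
  for (rep in 1:n_rep) {
    seqs <- c(ortho_set(test_profiles[["fGPAT-A"]], 4, "A"),
              ortho_set(test_profiles[["eGPAT"]], 4, "E"))
    tr <- neighbor_joining(pairwise_distances(seqs))
    mono <- mono + (is_clade(tr, paste0("A", 1:4)) &&
                      is_clade(tr, paste0("E", 1:4)))
  }
  expect_equal(mono, n_rep)
})
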