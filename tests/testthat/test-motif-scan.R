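# Chain placement under spacing constraints, DBM arithmetic, and the
# motif-I H..D spacing.

make_test_profile <- function() {
  # tiny custom profile loaded through the YAML interface
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "toy:",
    "  motif_I:   {pattern: \"H H\", hallmark: [1]}",
    "  dbm_I_II:   [2, 4]",
    "  motif_II:  {pattern: \"C C\", hallmark: []}",
    "  dbm_II_III: [3, 5]",
    "  motif_III: {pattern: \"W W\", hallmark: []}",
    "  dbm_III_IV: [1, 2]",
    "  motif_IV:  {pattern: \"M M\", hallmark: []}"
  ), path)
  acyl_profiles(path)[["toy"]]
}

test_that("compute_dbm counts residues strictly between motifs", {
  pl <- tibble::tibble(offset = c(11, 21, 31, 61), length = c(7, 8, 8, 5))
  expect_equal(compute_dbm(pl), c(3L, 2L, 22L))
  # adjacent motifs: one ends at 16, the next starts at 17
  adj <- tibble::tibble(offset = c(10, 17), length = c(7, 4))
  expect_equal(compute_dbm(adj), 0L)
  # inclusive sensitivity variant counts the bounding motifs too
  expect_equal(compute_dbm(pl, inclusive = TRUE), c(18L, 18L, 35L))
  expect_error(compute_dbm(tibble::tibble(offset = c(10, 12), length = c(7, 4))),
               "overlap")
})

test_that("planted family members yield exactly the planted chain", {
  for (f in names(test_profiles)) {
    fam <- generate_family(test_profiles[[f]], n = 5,
                           seed = 300 + match(f, names(test_profiles)))
    for (i in seq_len(nrow(fam))) {
      ch <- scan_chain(fam$sequence[i], test_profiles[[f]])
      expect_false(is.null(ch))
      expect_equal(ch$offset, c(fam$offset_I[i], fam$offset_II[i],
                                fam$offset_III[i], fam$offset_IV[i]))
      expect_equal(chain_dbm(ch), c(fam$dbm_I_II[i], fam$dbm_II_III[i],
                                    fam$dbm_III_IV[i]))
    }
  }
})

test_that("sequences without histidine match no profile", {
  seq <- paste(rep("ACDEFG", 60), collapse = "")
  for (prof in test_profiles) {
    expect_null(scan_chain(seq, prof))
  }
})

test_that("hard mode keeps only spacing-compliant placements", {
  prof <- make_test_profile()
  # two motif-II placements; only the first gives dbm_II_III inside [3, 5]
  #        HH..CC...WW.MM      vs a decoy CC right before WW (dbm 0)
  seq <- "HHAACCAAACCWWAMM"
  hard <- scan_chain(seq, prof, dbm_mode = "hard")
  expect_equal(hard$offset[2], 5)       # compliant CC at offset 5
  expect_equal(chain_dbm(hard), c(2L, 5L, 1L))
  soft <- scan_chain(seq, prof, dbm_mode = "soft")
  # soft mode agrees with exhaustive enumeration too
  expect_equal(chain_score(soft), brute_chain_score(seq, prof, "soft"))
  expect_equal(chain_score(hard), brute_chain_score(seq, prof, "hard"))
})

test_that("DP chain equals exhaustive enumeration on multi-occurrence inputs", {
  prof <- make_test_profile()
  set.seed(77)
  for (rep in 1:40) {
    # background plus several planted copies of each 2-mer motif
    chars <- sample(setdiff(aa20, c("H", "C", "W", "M")), 150, replace = TRUE)
    seq <- paste(chars, collapse = "")
    for (block in c("HH", "CC", "WW", "MM")) {
      for (cp in seq_len(sample(1:3, 1))) {
        k <- sample(1:(nchar(seq) - 2), 1)
        substr(seq, k, k + 1) <- block
      }
    }
    for (mode in c("soft", "hard")) {
      ch <- scan_chain(seq, prof, dbm_mode = mode)
      bf <- brute_chain_score(seq, prof, mode)
      if (is.null(bf)) {
        expect_null(ch)
      } else {
        expect_false(is.null(ch))
        expect_equal(chain_score(ch), bf)
      }
    }
  }
})

test_that("chain placements tile the sequence exactly", {
  fam <- generate_family(test_profiles[["eGPAT"]], n = 10, seed = 8)
  for (i in seq_len(nrow(fam))) {
    ch <- scan_chain(fam$sequence[i], test_profiles[["eGPAT"]])
    flanks <- (ch$offset[1] - 1) +
      (nchar(fam$sequence[i]) - (ch$offset[4] + ch$length[4] - 1))
    expect_equal(sum(ch$length) + sum(chain_dbm(ch)) + flanks,
                 nchar(fam$sequence[i]))
  }
})

test_that("motif-I H..D spacing is measured between the invariant pair", {
  famA <- generate_family(test_profiles[["fGPAT-A"]], n = 2, seed = 31)
  chA <- scan_chain(famA$sequence[1], test_profiles[["fGPAT-A"]])
  expect_equal(hx_spacing(famA$sequence[1], chA), 5)
  famM <- generate_family(test_profiles[["mitoGPAT"]], n = 2, seed = 32)
  chM <- scan_chain(famM$sequence[1], test_profiles[["mitoGPAT"]])
  expect_equal(hx_spacing(famM$sequence[1], chM), 4)
  # degenerate window "HD"
  hd <- structure(tibble::tibble(motif = "I", offset = 1L, length = 2L,
                                 score = 0),
                  class = c("acyl_chain", class(tibble::tibble())))
  expect_equal(hx_spacing("HDAAA", hd), 0)
  # windows without the terminal pair are an error
  bad <- structure(tibble::tibble(motif = "I", offset = 1L, length = 3L,
                                  score = 0),
                   class = c("acyl_chain", class(tibble::tibble())))
  expect_error(hx_spacing("HDA", bad), "H and end with D")
})

test_that("shipped DBM ranges reproduce the published table values", {
  expect_equal(test_profiles[["eGPAT"]]$dbm$dbm_II_III, c(23L, 27L))
  expect_equal(test_profiles[["mitoGPAT"]]$dbm$dbm_III_IV, c(28L, 28L))
  expect_equal(test_profiles[["fGPAT-A"]]$dbm$dbm_II_III, c(97L, 132L))
  expect_equal(test_profiles[["fGPAT-B"]]$dbm$dbm_II_III, c(21L, 104L))
})
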