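# Subclass assignment: recovery of planted labels, the HX4D/HX5D hard
# filter, decoy rejection, and the report surfaces.

test_that("noise-free members of every subclass are called correctly", {
  for (f in names(test_profiles)) {
    fam <- generate_family(test_profiles[[f]], n = 5,
                           seed = 600 + match(f, names(test_profiles)))
    res <- classify_sequences(fam, test_profiles)
    expect_equal(res$call, rep(f, 5))
    expect_equal(res$status, rep("called", 5))
    expect_true(all(res$margin >= 0))
  }
})

test_that("the HX spacing class separates fungal GPATs from the rest", {
  for (f in names(test_profiles)) {
    fam <- generate_family(test_profiles[[f]], n = 8,
                           seed = 700 + match(f, names(test_profiles)))
    res <- classify_sequences(fam, test_profiles)
    expected <- if (f %in% c("fGPAT-A", "fGPAT-B")) "HX5D" else "HX4D"
    expect_equal(res$hx_class, rep(expected, 8))
    if (expected == "HX5D") {
      expect_false(any(res$call %in% c("eGPAT", "mitoGPAT", "fGDPAT",
                                       "DHAPAT", "GDPAT-like")))
    } else {
      expect_false(any(res$call %in% c("fGPAT-A", "fGPAT-B")))
    }
  }
})

test_that("random decoys are almost never assigned a subclass", {
  dec <- generate_decoys(200, c(480, 520), seed = 41)
  res <- classify_sequences(dec, test_profiles)
  benign <- res$status %in% c("none", "ambiguous", "partial")
  expect_gte(mean(benign), 0.99)
})

test_that("accuracy is non-increasing in conservative substitution noise", {
  noise_levels <- c(0, 0.02, 0.05, 0.1)
  acc <- vapply(noise_levels, function(nz) {
    hits <- 0; total <- 0
    for (f in names(test_profiles)) {
      fam <- generate_family(test_profiles[[f]], n = 8, noise = nz,
                             seed = 800 + match(f, names(test_profiles)))
      res <- classify_sequences(fam, test_profiles)
      hits <- hits + sum(res$call == f & res$status == "called")
      total <- total + nrow(fam)
    }
    hits / total
  }, 0)
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 1)
})

test_that("near-ties within the GDPAT branch yield the branch-level call", {
  prof <- test_profiles
  # a chimera satisfying both the mitoGPAT and fGDPAT patterns
  m1 <- "HKSHLD"; m2 <- "FFIRRKL"; m3 <- "FLEGGRSR"; m4 <- "LLPLA"
  gap <- function(n) paste(rep("A", n), collapse = "")
  seq <- paste0(gap(30), m1, gap(38), m2, gap(27), m3, gap(28), m4, gap(30))
  res <- classify_sequence(seq, prof, min_margin = 8)
  expect_equal(res$call, "GDPAT-like")
  expect_equal(res$status, "gdpat_like")
  # with the default margin the more specific profile wins outright
  res2 <- classify_sequence(seq, prof)
  expect_equal(res2$status, "called")
  expect_true(res2$call %in% c("mitoGPAT", "fGDPAT", "DHAPAT"))
})

test_that("sequences with three placeable motifs are reported as partial", {
  fam <- generate_family(test_profiles[["fGDPAT"]], n = 1, seed = 61)
  # destroy motif IV's anchoring proline
  s <- fam$sequence[1]
  p_pos <- fam$offset_IV[1] + 2
  substr(s, p_pos, p_pos) <- "E"
  res <- classify_sequence(s, test_profiles)
  expect_equal(res$status, "partial")
  expect_true(is.na(res$call))
})

test_that("classify_fasta round-trips files and is byte-deterministic", {
  fam <- generate_family(test_profiles[["eGPAT"]], n = 6, seed = 77)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(fam, fa)
  out1 <- tempfile(fileext = ".tsv")
  out2 <- tempfile(fileext = ".tsv")
  res <- suppressMessages(classify_fasta(fa, test_profiles, out = out1))
  suppressMessages(classify_fasta(fa, test_profiles, out = out2))
  expect_equal(res$call, rep("eGPAT", 6))
  expect_equal(res$id, fam$id)  # stable input order
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  expect_error(suppressMessages(classify_fasta(tempfile())), "not found")
  # empty files are an error
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(suppressMessages(classify_fasta(empty)))
  expect_error(classify_sequence("", test_profiles), "non-empty")
})

test_that("presence/absence has at-least-one-isoform semantics", {
  famA <- generate_family(test_profiles[["fGPAT-A"]], n = 2, seed = 90)
  dec <- generate_decoys(5, c(300, 400), seed = 91)
  recs <- tibble::tibble(
    id = c(famA$id, dec$id),
    sequence = c(famA$sequence, dec$sequence),
    proteome = c("sack", "sack", rep("empty", 5))
  )
  res <- classify_sequences(recs, test_profiles)
  pres <- presence_absence(res)
  expect_s3_class(pres, "acyl_presence")
  # two isoforms, one TRUE cell
  expect_true(pres$sack[pres$subclass == "fGPAT-A"])
  expect_equal(sum(pres$sack), 1)
  # all-decoy proteome gives an all-false column
  expect_false(any(pres$empty))
  # subclasses absent from the plan stay absent
  expect_false(pres$sack[pres$subclass == "mitoGPAT"])
  expect_false(pres$sack[pres$subclass == "fGDPAT"])
  expect_error(presence_absence(classify_sequences(famA, test_profiles)),
               "proteome")
})

test_that("classification results have tidy/glance/autoplot surfaces", {
  fam <- generate_family(test_profiles[["DHAPAT"]], n = 3, seed = 95)
  res <- classify_sequences(fam, test_profiles)
  g <- glance(res)
  expect_equal(g$n, 3)
  expect_equal(g$n_called, 3)
  td <- tidy(res)
  expect_false(inherits(td, "acyl_classification"))
  expect_s3_class(autoplot(res), "ggplot")
})
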