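# The generator: planted structure, reproducibility, and the statistical
# properties downstream stages rely on.

test_that("planted fGPAT-A members carry the invariant motif III", {
  fam <- generate_family(test_profiles[["fGPAT-A"]], n = 20, seed = 201)
  expect_true(all(grepl("FPEGGSHD", fam$sequence, fixed = TRUE)))
})

test_that("planted spacings always respect the profile ranges", {
  fam <- generate_family(test_profiles[["eGPAT"]], n = 30, seed = 202)
  expect_true(all(fam$dbm_II_III >= 23 & fam$dbm_II_III <= 27))
  expect_true(all(fam$dbm_III_IV == 18))
  # documented spacing exceptions can be emulated by overriding a range
  exc <- generate_family(test_profiles[["mitoGPAT"]], n = 3, seed = 203,
                         dbm_override = list(c(38, 39), c(65, 65), c(28, 28)))
  expect_true(all(exc$dbm_II_III == 65))
})

test_that("generation is reproducible from the seed down to FASTA bytes", {
  a <- generate_family(test_profiles[["fGDPAT"]], n = 5, noise = 0.05,
                       pts1 = "canonical", seed = 204)
  b <- generate_family(test_profiles[["fGDPAT"]], n = 5, noise = 0.05,
                       pts1 = "canonical", seed = 204)
  expect_identical(a, b)
  fa1 <- tempfile(); fa2 <- tempfile()
  write_fasta(a, fa1); write_fasta(b, fa2)
  expect_identical(readBin(fa1, "raw", file.size(fa1)),
                   readBin(fa2, "raw", file.size(fa2)))
  d1 <- generate_decoys(10, seed = 205)
  d2 <- generate_decoys(10, seed = 205)
  expect_identical(d1, d2)
})

test_that("decoys follow the background composition", {
  dec <- generate_decoys(250, c(390, 410), seed = 206)
  chars <- strsplit(paste(dec$sequence, collapse = ""), "")[[1]]
  N <- length(chars)
  expect_gt(N, 9e4)
  freq <- table(factor(chars, levels = aa20)) / N
  sigma <- sqrt(0.05 * 0.95 / N)
  expect_true(all(abs(freq - 0.05) < 3 * sigma + 1e-9))
  # the invariant motif-III literal is absent at this scale for this seed
  expect_false(any(grepl("FPEGGSHD", dec$sequence, fixed = TRUE)))
})

test_that("planted DBM values are uniform over their ranges", {
  fam <- generate_family(test_profiles[["fGPAT-A"]], n = 2000, seed = 207)
  # dbm_I_II ranges over 35..46 (12 cells)
  obs <- table(factor(fam$dbm_I_II, levels = 35:46))
  expect_gt(stats::chisq.test(obs)$p.value, 0.01)
})

test_that("conservative noise respects selection; harsh noise does not", {
  fam <- generate_family(test_profiles[["mitoGPAT"]], n = 30, noise = 0.1,
                         noise_mode = "conservative", seed = 208)
  # every member still carries its full chain
  for (i in seq_len(nrow(fam))) {
    expect_false(is.null(scan_chain(fam$sequence[i],
                                    test_profiles[["mitoGPAT"]])))
  }
  harsh <- generate_family(test_profiles[["mitoGPAT"]], n = 30, noise = 0.3,
                           noise_mode = "harsh", seed = 209)
  broken <- sum(vapply(harsh$sequence, function(s) {
    is.null(scan_chain(s, test_profiles[["mitoGPAT"]]))
  }, TRUE))
  expect_gt(broken, 0)
})

test_that("constrained mutation stays inside each position's allowed set", {
  fam <- generate_family(test_profiles[["eGPAT"]], n = 1, seed = 210)
  set.seed(211)
  m <- mutate_protein(fam$sequence, 0.5, protect = fam$protected[[1]],
                      constraints = fam$constraints[[1]])
  cons <- fam$constraints[[1]]
  chars <- strsplit(m, "")[[1]]
  for (posname in names(cons)) {
    pos <- as.integer(posname)
    expect_true(chars[pos] %in% strsplit(cons[[posname]], "")[[1]])
  }
  # protected positions are untouched even under heavy mutation
  orig <- strsplit(fam$sequence, "")[[1]]
  expect_identical(chars[fam$protected[[1]]], orig[fam$protected[[1]]])
  expect_identical(mutate_protein(fam$sequence, 0), fam$sequence)
  expect_error(mutate_protein("ACD", 1), "rate")
})

test_that("impossible length ranges are rejected", {
  expect_error(generate_family(test_profiles[["fGPAT-A"]], n = 1,
                               length_range = c(50, 60), seed = 212),
               "length range")
})

test_that("survey presets encode the documented gain/loss patterns", {
  sack <- survey_plan("sack_like")
  expect_equal(unique(sack$proteome), "sack_like")
  expect_equal(sack$subclass, "fGPAT-A")
  single <- survey_plan("single_egpat")
  expect_equal(nrow(single), 1)
  sc <- generate_survey_set(plan = survey_plan("opisthokont8"),
                            proteome_size = 12, reference_decoys = 5,
                            seed = 213)
  truth <- sc$truth
  expect_false(truth$sack_like[truth$subclass == "mitoGPAT"])
  expect_false(truth$sack_like[truth$subclass == "fGDPAT"])
  expect_equal(sum(truth$microsporidian_like), 1)
  expect_true(truth$microsporidian_like[truth$subclass == "eGPAT"])
  # whole-directory reproducibility
  sc2 <- generate_survey_set(plan = survey_plan("opisthokont8"),
                             proteome_size = 12, reference_decoys = 5,
                             seed = 213)
  expect_identical(sc$proteomes, sc2$proteomes)
  expect_identical(sc$reference, sc2$reference)
  # only fGDPAT founders carry a targeting signal
  pts <- detect_pts1(stats::setNames(sc$founders$sequence,
                                     sc$founders$subclass))
  expect_true(pts$positive[pts$id == "fGDPAT"])
  expect_false(any(pts$positive[pts$id %in% c("mitoGPAT", "DHAPAT")]))
})
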