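# Rule-based C-terminal peroxisomal targeting signal (PTS1) detection.
# A tripeptide classifier standing in for position-weight scoring services:
# the canonical tier is the classic [S/A/C][K/R/H][L/M] consensus, the
# relaxed tier admits the broader substitutions commonly reported for
# functional signals.  Only the final three residues matter.

PTS1_POS3 <- c("S", "A", "C")              # canonical -3
PTS1_POS2 <- c("K", "R", "H")              # -2 (both tiers)
PTS1_POS1 <- c("L", "M")                   # canonical -1
PTS1_POS3_RELAXED <- c("S", "A", "C", "G", "P", "T")
PTS1_POS1_RELAXED <- c("L", "M", "I", "F")

#' Detect a C-terminal PTS1 peroxisomal targeting signal
#'
#' Classifies the last three residues of each protein: `canonical` when the
#' tripeptide matches `[S/A/C][K/R/H][L/M]`, `relaxed` when it matches the
#' broader `[S/A/C/G/P/T][K/R/H][L/M/I/F]` consensus, `none` otherwise.
#' Sequences shorter than three residues are negative.  The call depends
#' only on the final tripeptide.
#'
#' @param seq Character vector of protein sequences.
#' @param id Optional identifiers (defaults to names of `seq` or an index).
#' @return Tibble with columns `id`, `tripeptide`, `tier`
#'   (`canonical`/`relaxed`/`none`) and `positive`.
#' @examples
#' detect_pts1(c(a = "MSTAVLSKL", b = "MSTAVLDEL"))
#' @export
detect_pts1 <- function(seq, id = NULL) {
  if (is.null(id)) id <- names(seq) %||% as.character(seq_along(seq))
  seq <- toupper(seq)
  res <- map2(seq, id, function(s, i) {
    n <- nchar(s)
    if (n < 3) {
      return(tibble(id = i, tripeptide = s, tier = "none", positive = FALSE))
    }
    tp <- substr(s, n - 2, n)
    r <- strsplit(tp, "")[[1]]
    tier <- if (r[1] %in% PTS1_POS3 && r[2] %in% PTS1_POS2 && r[3] %in% PTS1_POS1) {
      "canonical"
    } else if (r[1] %in% PTS1_POS3_RELAXED && r[2] %in% PTS1_POS2 &&
               r[3] %in% PTS1_POS1_RELAXED) {
      "relaxed"
    } else {
      "none"
    }
    tibble(id = i, tripeptide = tp, tier = tier, positive = tier != "none")
  })
  bind_rows(res)
}

sample_pts1_tripeptide <- function(tier = c("canonical", "relaxed")) {
  tier <- match.arg(tier)
  if (tier == "canonical") {
    paste0(sample(PTS1_POS3, 1), sample(PTS1_POS2, 1), sample(PTS1_POS1, 1))
  } else {
    # a relaxed-but-not-canonical signal
    repeat {
      tp <- paste0(sample(PTS1_POS3_RELAXED, 1), sample(PTS1_POS2, 1),
                   sample(PTS1_POS1_RELAXED, 1))
      r <- strsplit(tp, "")[[1]]
      if (!(r[1] %in% PTS1_POS3 && r[3] %in% PTS1_POS1)) return(tp)
    }
  }
}
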