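# Pairwise alignment layer.  Exact Smith-Waterman / Needleman-Wunsch with
# affine gaps via Biostrings::pairwiseAlignment (BLOSUM62, gap open 11 /
# extend 1 -- the standard protein-search defaults), plus a Karlin-Altschul
# E-value with fixed gapped-BLOSUM62 constants so the conventional
# "E <= 0.05 candidate homologue" semantics carry over.  Exact alignment
# (no heuristic seeding) is entirely adequate at the proteome sizes this
# package targets.

.align_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (is.null(.align_cache[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .align_cache[[key]] <- e[[name]]
  }
  .align_cache[[key]]
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with fixed gapped-BLOSUM62 constants
#' `lambda = 0.267`, `K = 0.041` (the published values for the 11/1 gap
#' scheme).
#'
#' @param score Raw alignment score(s).
#' @param m,n Lengths of the two sequences.
#' @param lambda,K Karlin-Altschul constants.
#' @return E-value(s).
#' @export
karlin_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Optimal local alignment of two proteins
#'
#' Exact Smith-Waterman with affine gap penalties (a length-`g` gap costs
#' `gap_open + gap_extend * g`).
#'
#' @param a,b Protein strings over the standard alphabet plus `X`.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Constants for [karlin_evalue()].
#' @return One-row tibble: `score`, aligned spans on both sequences
#'   (`query_start/end`, `subject_start/end`, 1-based inclusive),
#'   `identity` (identical positions over alignment columns) and `e_value`.
#' @examples
#' smith_waterman("ACDEFG", "ACDEFG")$score
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  a <- assert_protein(a, allow_nonstandard = FALSE, what = "sequence a")
  b <- assert_protein(b, allow_nonstandard = FALSE, what = "sequence b")
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = substitution_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  score <- Biostrings::score(aln)
  if (score < 0) score <- 0  # empty local alignment floor
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  ident <- if (width > 0) Biostrings::nmatch(aln) / width else 0
  tibble(
    score = score,
    query_start = Biostrings::start(Biostrings::pattern(aln)),
    query_end = Biostrings::end(Biostrings::pattern(aln)),
    subject_start = Biostrings::start(Biostrings::subject(aln)),
    subject_end = Biostrings::end(Biostrings::subject(aln)),
    identity = ident,
    e_value = karlin_evalue(score, nchar(a), nchar(b), lambda, K)
  )
}

# score-only local alignment of one query against many subjects (fast path)
local_scores <- function(query, subjects, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (length(subjects) == 0) return(numeric())
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(subjects)), Biostrings::AAString(query),
    type = "local", substitutionMatrix = substitution_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
  pmax(sc, 0)
}

#' Best local-alignment hit of a query in a proteome
#'
#' Scores the query against every proteome member, keeps the maximum raw
#' score (ties broken by lexicographically smaller subject id), and retains
#' it only when its E-value passes the cutoff.
#'
#' @param query Protein string.
#' @param proteome Named character vector (id -> sequence).
#' @param cutoff E-value cutoff (default 0.05, the conventional candidate
#'   threshold; `Inf` disables the filter, which is the reciprocal-search
#'   convention where only the identity of the best hit matters).
#' @inheritParams smith_waterman
#' @return One-row tibble (`subject_id` plus the [smith_waterman()] columns)
#'   or `NULL` when nothing passes.
#' @export
best_hit <- function(query, proteome, cutoff = 0.05, matrix = "BLOSUM62",
                     gap_open = 11, gap_extend = 1,
                     lambda = 0.267, K = 0.041) {
  if (length(proteome) == 0) abort("proteome must be non-empty")
  if (is.null(names(proteome))) abort("proteome must be a named vector")
  sc <- local_scores(query, proteome, matrix, gap_open, gap_extend)
  top <- which(sc == max(sc))
  winner <- top[order(names(proteome)[top])][1]
  ev <- karlin_evalue(sc[winner], nchar(query), nchar(proteome[winner]),
                      lambda, K)
  if (ev > cutoff) return(NULL)
  details <- smith_waterman(query, proteome[[winner]], matrix,
                            gap_open, gap_extend, lambda, K)
  bind_cols(tibble(subject_id = names(proteome)[winner]), details)
}

# identity fraction of the global (Needleman-Wunsch) alignment
global_identity <- function(a, b, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (width == 0) return(0)
  Biostrings::nmatch(aln) / width
}
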