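# Chain placement: locate motifs I-IV in order, non-overlapping, under the
# profile's inter-motif distance (DBM) constraints, by dynamic programming
# over the per-motif occurrence lists.

#' Residues strictly between consecutive motif placements
#'
#' @param placements Tibble or data frame with columns `offset` and `length`
#'   (1-based placements of consecutive motifs, in order).
#' @param inclusive Count the bounding motif residues too (a sensitivity
#'   variant); the default counts residues strictly between, which is the
#'   convention of the shipped DBM ranges.
#' @return Integer vector of length `nrow(placements) - 1`.
#' @examples
#' pl <- tibble::tibble(offset = c(11, 21, 31, 61), length = c(7, 8, 8, 5))
#' compute_dbm(pl)
#' @export
compute_dbm <- function(placements, inclusive = FALSE) {
  off <- placements$offset
  len <- placements$length
  if (length(off) < 2) return(integer())
  d <- off[-1] - (off[-length(off)] + len[-length(len)])
  if (any(d < 0)) abort("motif placements overlap")
  if (inclusive) d <- d + len[-length(len)] + len[-1]
  as.integer(d)
}

dbm_penalty_term <- function(d, range, mode, penalty_per_residue) {
  outside <- pmax(range[1] - d, d - range[2], 0)
  if (mode == "hard") {
    ifelse(outside > 0, -Inf, 0)
  } else {
    -penalty_per_residue * outside
  }
}

#' Place the best motif chain on a protein
#'
#' Among all in-order, non-overlapping combinations of occurrences of the
#' profile's motifs, returns the maximum-score chain.  The chain score is
#' the sum of per-position specificity weights `log2(20 / |allowed|)` over
#' matched motif positions plus a DBM term: 0 when an inter-motif distance
#' falls inside the profile's range, and in soft mode a penalty of
#' `dbm_penalty` per residue outside it (hard mode discards such chains).
#' Computed by dynamic programming over per-motif occurrence lists; ties are
#' broken deterministically towards the leftmost placements.
#'
#' @param seq Protein string (non-empty).
#' @param prof An `acyl_profile`.
#' @param dbm_mode `"soft"` (default: penalised spacing violations, used for
#'   classification so that documented range exceptions are not rejected
#'   outright) or `"hard"` (chains outside any DBM range are discarded).
#' @param dbm_penalty Soft-mode penalty per residue outside a DBM range.
#' @param motifs Integer subset of `1:4` to place (consecutive); the default
#'   places the full chain.  Three-motif chains back the "partial" fallback
#'   of [classify_sequence()].
#' @param inclusive_dbm Use the inclusive DBM counting variant throughout.
#' @return A tibble of class `acyl_chain` with one row per placed motif
#'   (`motif`, `offset`, `length`, `score`) and attributes `dbm` (integer
#'   spacings), `score` (total chain score) and `subclass`; or `NULL` when
#'   some motif has no occurrence or no chain survives hard mode.
#' @examples
#' profs <- acyl_profiles()
#' fam <- generate_family(profs[["fGDPAT"]], n = 1, seed = 1)
#' scan_chain(fam$sequence[1], profs[["fGDPAT"]])
#' @export
scan_chain <- function(seq, prof, dbm_mode = c("soft", "hard"),
                       dbm_penalty = 0.5, motifs = 1:4,
                       inclusive_dbm = FALSE) {
  dbm_mode <- match.arg(dbm_mode)
  stopifnot(inherits(prof, "acyl_profile"))
  if (!nzchar(seq)) abort("sequence must be non-empty")
  motifs <- sort(as.integer(motifs))
  if (length(motifs) < 1 || any(diff(motifs) != 1)) {
    abort("motifs must be a consecutive subset of 1:4")
  }
  seq <- toupper(seq)
  code <- encode_seq(seq)
  n <- nchar(seq)
  occ <- map(motifs, function(k) occurrences_core(prof$motifs[[k]], code, n))
  if (any(map_int(occ, function(o) length(o$offset)) == 0)) return(NULL)

  # DP forward pass; f[[k]][j] = best score of a partial chain ending at
  # occurrence j of the k-th placed motif.
  nk <- length(motifs)
  f <- map(occ, function(o) o$score)
  back <- map(occ, function(o) rep(NA_integer_, length(o$offset)))
  for (k in seq_len(nk)[-1]) {
    prev <- occ[[k - 1]]
    cur <- occ[[k]]
    rng <- prof$dbm[[motifs[k - 1]]]
    fk <- rep(-Inf, length(cur$offset))
    bk <- rep(NA_integer_, length(cur$offset))
    for (j in seq_along(cur$offset)) {
      d <- cur$offset[j] - (prev$offset + prev$length)
      feas <- d >= 0
      if (!any(feas)) next
      d_eff <- if (inclusive_dbm) d + prev$length + cur$length[j] else d
      pen <- dbm_penalty_term(d_eff, rng, dbm_mode, dbm_penalty)
      tot <- f[[k - 1]] + pen
      tot[!feas] <- -Inf
      best <- which.max(tot)  # first max -> leftmost previous placement
      if (is.finite(tot[best])) {
        fk[j] <- tot[best] + cur$score[j]
        bk[j] <- best
      }
    }
    f[[k]] <- fk
    back[[k]] <- bk
  }
  if (!any(is.finite(f[[nk]]))) return(NULL)
  j <- which.max(f[[nk]])
  total <- f[[nk]][j]
  idx <- integer(nk)
  idx[nk] <- j
  for (k in rev(seq_len(nk))[-1]) idx[k] <- back[[k + 1]][idx[k + 1]]
  placements <- tibble(
    motif = MOTIF_LABELS[motifs],
    offset = map_int(seq_len(nk), function(k) as.integer(occ[[k]]$offset[idx[k]])),
    length = map_int(seq_len(nk), function(k) as.integer(occ[[k]]$length[idx[k]])),
    score = map_dbl(seq_len(nk), function(k) occ[[k]]$score[idx[k]])
  )
  structure(placements,
            dbm = compute_dbm(placements, inclusive = inclusive_dbm),
            score = total,
            subclass = prof$subclass,
            class = c("acyl_chain", class(placements)))
}

#' Total score of a placed chain
#' @param chain An `acyl_chain` as returned by [scan_chain()].
#' @return Numeric chain score.
#' @export
chain_score <- function(chain) attr(chain, "score")

#' DBM values of a placed chain
#' @inheritParams chain_score
#' @return Integer vector of inter-motif distances.
#' @export
chain_dbm <- function(chain) attr(chain, "dbm")

#' Spacing of the catalytic H and D in a placed motif I
#'
#' Counts the residues strictly between the invariant histidine and
#' aspartate of the motif-I window of a chain (5 for fungal GPATs, HX5D;
#' 4 for the other subclasses, HX4D).
#'
#' @param seq The protein the chain was placed on.
#' @param chain An `acyl_chain` whose first row is a motif-I placement.
#' @return Integer spacing.
#' @export
hx_spacing <- function(seq, chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  if (chain$motif[1] != "I") abort("chain does not start with motif I")
  window <- substr(toupper(seq), chain$offset[1],
                   chain$offset[1] + chain$length[1] - 1)
  if (nchar(window) != chain$length[1]) abort("motif I placement out of range")
  if (substr(window, 1, 1) != "H" ||
      substr(window, nchar(window), nchar(window)) != "D") {
    abort("motif I window does not start with H and end with D")
  }
  as.integer(nchar(window) - 2)
}
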