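# Amino-acid alphabet and the degenerate residue classes used by the motif
# grammar.  Class symbols follow the compact alignment nomenclature common in
# the motif literature: "pi" (short-chain), "phi" (hydrophobic), "[+]" (basic).

AA_STANDARD20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Non-standard codes that may occur in real protein records.  They match only
# the full wildcard "x": conservative matching avoids spurious hallmark hits.
AA_NONSTANDARD <- c("B", "Z", "X", "U", "J", "O")

#' Degenerate residue classes of the motif grammar
#'
#' Returns the residue sets behind the class tokens accepted by
#' [parse_pattern()]: `pi` (short-chain: P, G, A, S), `phi` (hydrophobic:
#' V, I, L, F, W, Y, M) and `+` (basic/positively chargeable: K, R, H).
#' The basic class is not pinned down by the motif tables this grammar was
#' designed around; K/R/H is the conventional reading and histidine is
#' included because it is positively chargeable in the basic motif contexts
#' where the token occurs.  Override entries to explore alternatives.
#'
#' @param ... Named character vectors replacing individual class definitions,
#'   e.g. `"+" = c("K", "R")`.
#' @return Named list of uppercase residue character vectors with entries
#'   `pi`, `phi` and `+`.
#' @examples
#' residue_classes()$phi
#' residue_classes("+" = c("K", "R"))
#' @export
residue_classes <- function(...) {
  classes <- list(
    "pi"  = c("P", "G", "A", "S"),
    "phi" = c("V", "I", "L", "F", "W", "Y", "M"),
    "+"   = c("K", "R", "H")
  )
  override <- list(...)
  for (nm in names(override)) {
    if (!nm %in% names(classes)) {
      abort(paste0("unknown residue class '", nm, "'"))
    }
    res <- toupper(as.character(override[[nm]]))
    if (length(res) == 0 || !all(res %in% AA_STANDARD20)) {
      abort(paste0("class '", nm, "' must be a non-empty subset of the 20 standard residues"))
    }
    classes[[nm]] <- res
  }
  classes
}

# Integer encoding: 1..20 standard residues (AA_STANDARD20 order), 21+ the
# non-standard codes, NA for anything else.  Used by the vectorised scanner.
encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(chars, c(AA_STANDARD20, AA_NONSTANDARD))
}

assert_protein <- function(seq, allow_nonstandard = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    abort(paste0(what, " must be a single character string"))
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ok <- if (allow_nonstandard) c(AA_STANDARD20, AA_NONSTANDARD) else c(AA_STANDARD20, "X")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0) {
    abort(paste0(what, " contains unsupported residue(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(toupper(seq))
}

# Sample residues from a background composition (named numeric over the 20
# standard residues, or the string "uniform").
resolve_composition <- function(composition) {
  if (is.character(composition) && length(composition) == 1) {
    if (composition != "uniform") abort("unknown composition preset")
    return(setNames(rep(1 / 20, 20), AA_STANDARD20))
  }
  if (is.null(names(composition)) || !all(sort(names(composition)) == sort(AA_STANDARD20))) {
    abort("composition must name all 20 standard residues")
  }
  p <- composition[AA_STANDARD20]
  p / sum(p)
}

sample_background <- function(n, composition = "uniform") {
  p <- resolve_composition(composition)
  sample(AA_STANDARD20, n, replace = TRUE, prob = p)
}
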