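# Degenerate motif grammar
#
# Patterns are space-delimited token strings, e.g. "H x N Q F phi D".
# Tokens: a literal residue, the wildcard "x", a class symbol ("pi", "phi",
# "[+]"; the unicode spellings of pi/phi are also accepted), or a bracketed
# alternative "[A/B/...]" whose alternatives are literals, class symbols or
# "-" (the position may be absent, i.e. optional).

CLASS_TOKENS <- c("pi", "π", "phi", "φ")

position_spec <- function(allowed, hallmark = FALSE, optional = FALSE,
                          wild = FALSE) {
  allowed <- sort(unique(toupper(allowed)))
  if (length(allowed) == 0 || !all(allowed %in% AA_STANDARD20)) {
    abort("allowed set must be a non-empty subset of the 20 standard residues")
  }
  if (optional && hallmark) {
    abort("an optional position cannot be a hallmark position")
  }
  n_codes <- 20 + length(AA_NONSTANDARD)
  memb <- logical(n_codes)
  memb[match(allowed, AA_STANDARD20)] <- TRUE
  if (wild) memb[21:n_codes] <- TRUE  # nonstandard residues match only x
  list(allowed = allowed, hallmark = hallmark, optional = optional,
       wild = wild, weight = log2(20 / length(allowed)), memb = memb)
}

parse_token <- function(token, column, classes) {
  fail <- function() {
    abort(paste0("cannot parse motif token '", token, "' at column ", column))
  }
  resolve_class <- function(tok) {
    switch(tok,
           "pi" = , "π" = classes[["pi"]],
           "phi" = , "φ" = classes[["phi"]],
           "+" = classes[["+"]],
           NULL)
  }
  if (token == "x" || token == "X") {
    return(position_spec(AA_STANDARD20, wild = TRUE))
  }
  if (token %in% CLASS_TOKENS) {
    return(position_spec(resolve_class(token)))
  }
  if (nchar(token) == 1 && toupper(token) %in% AA_STANDARD20) {
    return(position_spec(toupper(token)))
  }
  if (grepl("^\\[.+\\]$", token)) {
    inner <- substr(token, 2, nchar(token) - 1)
    alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
    if (length(alts) == 0) fail()
    if (length(alts) == 1 && alts == "+") {
      return(position_spec(classes[["+"]]))
    }
    optional <- FALSE
    allowed <- character()
    for (alt in alts) {
      if (alt == "-") {
        optional <- TRUE
      } else if (!is.null(resolve_class(alt))) {
        allowed <- c(allowed, resolve_class(alt))
      } else if (nchar(alt) == 1 && toupper(alt) %in% AA_STANDARD20) {
        allowed <- c(allowed, toupper(alt))
      } else {
        fail()
      }
    }
    if (length(allowed) == 0) fail()
    return(position_spec(allowed, optional = optional))
  }
  fail()
}

#' Parse a degenerate motif pattern
#'
#' Compiles a space-delimited pattern string into a motif object usable by
#' [find_occurrences()] and [scan_chain()].  Tokens are literals, the
#' wildcard `x`, the residue-class symbols `pi`, `phi` and `[+]` (see
#' [residue_classes()]) and bracketed alternatives such as `[T/S]` or
#' `[pi/phi]`.  A `-` alternative, as in `[-/N]`, marks the position
#' optional: matches may either include it or skip it, so the motif length
#' varies by one.
#'
#' @param text Pattern string, tokens separated by whitespace.
#' @param label Motif label, conventionally one of `"I"`, `"II"`, `"III"`,
#'   `"IV"`.
#' @param hallmark Integer positions (1-based, counting tokens) flagged as
#'   the invariant hallmark residues of the motif.
#' @param classes Residue-class definitions, see [residue_classes()].
#' @return An object of class `acyl_motif`: the ordered position
#'   specifications plus the original pattern string.
#' @examples
#' m <- parse_pattern("H x N Q F phi D", "I", hallmark = c(1, 7))
#' motif_length(m)
#' @export
parse_pattern <- function(text, label = "I", hallmark = integer(),
                          classes = residue_classes()) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    abort("empty motif pattern")
  }
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  positions <- map2(tokens, seq_along(tokens), parse_token, classes = classes)
  hallmark <- as.integer(hallmark)
  if (any(hallmark < 1 | hallmark > length(positions))) {
    abort("hallmark positions out of range")
  }
  for (h in hallmark) {
    if (positions[[h]]$optional) {
      abort("an optional position cannot be a hallmark position")
    }
    positions[[h]]$hallmark <- TRUE
  }
  structure(
    list(label = label, source = paste(tokens, collapse = " "),
         positions = positions),
    class = "acyl_motif"
  )
}

#' @export
print.acyl_motif <- function(x, ...) {
  cat("<acyl_motif ", x$label, "> ", x$source, "\n", sep = "")
  hall <- which(map_lgl(x$positions, "hallmark"))
  if (length(hall)) cat("  hallmark positions: ", paste(hall, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialise a motif pattern back to its textual form
#'
#' Inverse of [parse_pattern()]: `parse_pattern(serialize_pattern(p), ...)`
#' reproduces `p` (given the same hallmark positions).
#'
#' @param p An `acyl_motif`.
#' @return The pattern string.
#' @export
serialize_pattern <- function(p) {
  stopifnot(inherits(p, "acyl_motif"))
  p$source
}

#' Number of positions of a motif pattern
#'
#' @param p An `acyl_motif`.
#' @return Integer; for motifs with an optional position this is the maximum
#'   match length.
#' @export
motif_length <- function(p) {
  stopifnot(inherits(p, "acyl_motif"))
  length(p$positions)
}

# All concrete variants of a pattern: one per subset of optional positions.
# Returns list of integer vectors of kept position indices (full variant
# first, then progressively shorter), each with the variant score attached.
motif_variants <- function(p) {
  opt <- which(map_lgl(p$positions, "optional"))
  keep_sets <- list(seq_along(p$positions))
  if (length(opt) > 0) {
    subsets <- expand.grid(rep(list(c(TRUE, FALSE)), length(opt)))
    keep_sets <- pmap(subsets, function(...) {
      drop <- opt[!unlist(list(...))]
      setdiff(seq_along(p$positions), drop)
    })
  }
  keep_sets[order(-lengths(keep_sets))]
}

variant_score <- function(p, kept) {
  sum(map_dbl(p$positions[kept], "weight"))
}

# membership lookup over the extended code space (20 standard + nonstandard),
# precomputed at parse time
allowed_codes <- function(spec) spec$memb

#' Match a motif at a fixed offset
#'
#' Tests whether the window starting at `i` satisfies the pattern, trying
#' every optional-position variant.
#'
#' @param p An `acyl_motif`.
#' @param seq Protein string.
#' @param i 1-based offset into `seq`.
#' @return Sorted integer vector of match lengths (empty when nothing
#'   matches).  Non-standard residues (B, Z, X, U, ...) match only the `x`
#'   wildcard.
#' @examples
#' m <- parse_pattern("H x N Q F phi D")
#' match_at(m, "HANQFLD", 1)
#' match_at(m, "HANQFPD", 1)
#' @export
match_at <- function(p, seq, i) {
  stopifnot(inherits(p, "acyl_motif"))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (i < 1 || i > n + 1) abort("offset out of range")
  code <- encode_seq(seq)
  lengths_hit <- integer()
  for (kept in motif_variants(p)) {
    L <- length(kept)
    if (i + L - 1 > n) next
    ok <- TRUE
    for (j in seq_len(L)) {
      memb <- allowed_codes(p$positions[[kept[j]]])
      cd <- code[i + j - 1]
      if (is.na(cd) || !memb[cd]) { ok <- FALSE; break }
    }
    if (ok) lengths_hit <- c(lengths_hit, L)
  }
  sort(unique(lengths_hit))
}

#' Find all occurrences of a motif in a sequence
#'
#' Exhaustive scan over every offset and every optional-position variant,
#' vectorised over offsets.
#'
#' @inheritParams match_at
#' @return Tibble with one row per occurrence: `offset` (1-based), `length`,
#'   and `score` (sum of per-position specificity weights
#'   `log2(20 / |allowed|)`; skipped optional positions contribute 0).
#'   Sorted by offset, then ascending length.
#' @export
find_occurrences <- function(p, seq) {
  stopifnot(inherits(p, "acyl_motif"))
  seq <- toupper(seq)
  occ <- occurrences_core(p, encode_seq(seq), nchar(seq))
  tibble(offset = occ$offset, length = occ$length, score = occ$score)
}

# hot path shared by find_occurrences() and scan_chain(): plain vectors,
# encoded sequence supplied by the caller
occurrences_core <- function(p, code, n) {
  out_off <- integer(0); out_len <- integer(0); out_sc <- double(0)
  if (n > 0) {
    for (kept in motif_variants(p)) {
      L <- length(kept)
      if (L == 0 || L > n) next
      ok <- rep(TRUE, n - L + 1)
      for (j in seq_len(L)) {
        memb <- allowed_codes(p$positions[[kept[j]]])
        m <- memb[code[j:(j + n - L)]]
        m[is.na(m)] <- FALSE
        ok <- ok & m
        if (!any(ok)) break
      }
      off <- which(ok)
      if (length(off)) {
        out_off <- c(out_off, off)
        out_len <- c(out_len, rep(L, length(off)))
        out_sc <- c(out_sc, rep(variant_score(p, kept), length(off)))
      }
    }
  }
  # sort by offset then length; on duplicates keep the best score
  ord <- order(out_off, out_len, -out_sc)
  out_off <- out_off[ord]; out_len <- out_len[ord]; out_sc <- out_sc[ord]
  dup <- duplicated(paste(out_off, out_len))
  list(offset = out_off[!dup], length = out_len[!dup], score = out_sc[!dup])
}

#' Derive a consensus pattern from aligned motif instances
#'
#' Column rules, applied in order: a single distinct residue becomes a
#' literal; a column contained in the short-chain class becomes `pi`; one
#' contained in the hydrophobic class becomes `phi`; at most `max_alts`
#' distinct residues become a bracketed alternative in alphabetical order;
#' anything else becomes the wildcard `x`.
#'
#' @param instances Character vector (>= 2) of equal-length motif strings
#'   over the standard alphabet.
#' @param max_alts Maximum number of distinct residues rendered as a
#'   bracketed alternative.
#' @param label Label for the derived motif.
#' @param classes Residue-class definitions.
#' @return An `acyl_motif` that matches every input instance.
#' @examples
#' derive_consensus(c("HASHLD", "HKSHVD"), max_alts = 2)
#' @export
derive_consensus <- function(instances, max_alts = 3, label = "derived",
                             classes = residue_classes()) {
  if (length(instances) < 2) abort("need at least two motif instances")
  instances <- toupper(instances)
  lens <- nchar(instances)
  if (length(unique(lens)) != 1) {
    abort("motif instances must all have the same length")
  }
  chars <- map(instances, function(s) strsplit(s, "")[[1]])
  bad <- setdiff(unique(unlist(chars)), AA_STANDARD20)
  if (length(bad)) {
    abort(paste0("non-standard residue(s) in instances: ", paste(bad, collapse = ", ")))
  }
  tokens <- map_chr(seq_len(lens[1]), function(j) {
    col <- sort(unique(map_chr(chars, j)))
    if (length(col) == 1) return(col)
    if (all(col %in% classes[["pi"]])) return("pi")
    if (all(col %in% classes[["phi"]])) return("phi")
    if (length(col) <= max_alts) {
      return(paste0("[", paste(col, collapse = "/"), "]"))
    }
    "x"
  })
  parse_pattern(paste(tokens, collapse = " "), label = label, classes = classes)
}
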