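# Subclass assignment.  Every profile is scanned in soft-DBM mode; the
# HX4D/HX5D motif-I spacing acts as a hard filter between the fungal GPAT
# clades and the other four subclasses; the winner is the highest-scoring
# chain provided its margin over the runner-up reaches min_margin.

hx_group <- function(subclass) {
  ifelse(subclass %in% FUNGAL_GPAT, "HX5D", "HX4D")
}

chain_hx_class <- function(seq, chain) {
  out <- tryCatch(hx_spacing(seq, chain), error = function(e) NA_integer_)
  if (is.na(out)) return("none")
  if (out == 5) "HX5D" else if (out == 4) "HX4D" else "none"
}

empty_chain_cols <- function() {
  tibble(offset_I = NA_integer_, offset_II = NA_integer_,
         offset_III = NA_integer_, offset_IV = NA_integer_,
         dbm_I_II = NA_integer_, dbm_II_III = NA_integer_,
         dbm_III_IV = NA_integer_)
}

chain_cols <- function(chain) {
  off <- setNames(as.list(chain$offset), paste0("offset_", chain$motif))
  d <- chain_dbm(chain)
  out <- empty_chain_cols()
  for (nm in names(off)) out[[nm]] <- as.integer(off[[nm]])
  if (length(d) == 3) {
    out$dbm_I_II <- d[1]; out$dbm_II_III <- d[2]; out$dbm_III_IV <- d[3]
  }
  out
}

#' Classify one protein into an acyltransferase subclass
#'
#' Scans the sequence with every subclass profile (soft DBM mode), applies
#' the HX4D/HX5D motif-I hard filter, and calls the top-scoring subclass
#' when its score margin over the runner-up reaches `min_margin`.  When the
#' within-margin candidates all belong to the mitoGPAT/fGDPAT/DHAPAT branch
#' -- whose motifs are nearly identical -- the call is the branch label
#' `"GDPAT-like"` together with the PTS1 flag, deliberately refusing to
#' assign substrate preference.  Proteins placing only three motifs are
#' reported as `"partial"`; proteins placing none as `"none"`.
#'
#' @param seq Protein string.
#' @param profiles Named list of `acyl_profile` objects
#'   (default [acyl_profiles()]).
#' @param min_motifs Minimum motifs for a candidate chain (default 4; with
#'   `min_motifs = 3` a three-motif chain still only yields a "partial"
#'   report, never a confident call).
#' @param min_margin Minimum best-minus-runner-up score for a confident
#'   call, in chain-score (bit) units.
#' @param dbm_mode Spacing mode passed to [scan_chain()]; classification
#'   defaults to soft because documented members of the mitoGPAT subclass
#'   exceed the typical II-III spacing and would be rejected in hard mode.
#' @param id Identifier stored in the result row.
#' @return One-row tibble: `id`, `call`, `status` (`called`, `gdpat_like`,
#'   `ambiguous`, `partial`, `none`), `margin`, `hx_class`, `pts1_tier`,
#'   `pts1_positive`, per-subclass chain scores (`score_*`), and the winning
#'   chain's motif offsets and DBM values.
#' @examples
#' profs <- acyl_profiles()
#' fam <- generate_family(profs[["eGPAT"]], n = 1, seed = 7)
#' classify_sequence(fam$sequence[1], profs)
#' @export
classify_sequence <- function(seq, profiles = acyl_profiles(),
                              min_motifs = 4, min_margin = 2,
                              dbm_mode = "soft", id = "protein") {
  if (!nzchar(seq)) abort("sequence must be non-empty")
  if (length(profiles) == 0) abort("profiles must be non-empty")
  chains <- map(profiles, function(p) {
    scan_chain(seq, p, dbm_mode = dbm_mode)
  })
  has_full <- !map_lgl(chains, is.null)
  pts <- detect_pts1(seq, id = id)
  score_cols <- setNames(
    as.list(ifelse(has_full, map_dbl(chains, function(ch) {
      if (is.null(ch)) NA_real_ else chain_score(ch)
    }), NA_real_)),
    paste0("score_", gsub("-", "_", names(profiles)))
  )
  base <- function(call, status, margin, hx, ccols) {
    bind_cols(
      tibble(id = id, call = call, status = status, margin = margin,
             hx_class = hx, pts1_tier = pts$tier,
             pts1_positive = pts$positive),
      as_tibble(score_cols), ccols
    )
  }

  if (!any(has_full)) {
    # three-motif fallback: consecutive triples only
    partial <- NULL
    for (p in profiles) {
      for (sub in list(1:3, 2:4)) {
        ch <- scan_chain(seq, p, dbm_mode = dbm_mode, motifs = sub)
        if (!is.null(ch) &&
            (is.null(partial) || chain_score(ch) > chain_score(partial))) {
          partial <- ch
        }
      }
    }
    if (!is.null(partial) && min_motifs <= 4) {
      return(base(NA_character_, "partial", NA_real_, "none",
                  chain_cols(partial)))
    }
    return(base(NA_character_, "none", NA_real_, "none", empty_chain_cols()))
  }

  cand <- names(profiles)[has_full]
  scores <- map_dbl(chains[cand], chain_score)
  best0 <- cand[order(-scores, match(cand, SUBCLASSES))][1]
  hx <- chain_hx_class(seq, chains[[best0]])
  if (hx != "none") {
    keep <- hx_group(cand) == hx
    cand <- cand[keep]
    scores <- scores[keep]
  }
  ord <- order(-scores, match(cand, SUBCLASSES))
  cand <- cand[ord]
  scores <- scores[ord]
  best <- cand[1]
  margin <- if (length(cand) > 1) scores[1] - scores[2] else Inf
  within <- cand[scores > scores[1] - min_margin]
  ccols <- chain_cols(chains[[best]])
  if (margin >= min_margin) {
    return(base(best, "called", margin, hx, ccols))
  }
  if (all(within %in% GDPAT_BRANCH)) {
    return(base("GDPAT-like", "gdpat_like", margin, hx, ccols))
  }
  base(NA_character_, "ambiguous", margin, hx, ccols)
}

#' Classify many sequences
#'
#' Vectorised driver for [classify_sequence()].
#'
#' @param x Named character vector of sequences, or a data frame with `id`
#'   and `sequence` columns (e.g. the output of [generate_family()] or
#'   [read_fasta()]); an optional `proteome` column is carried through.
#' @inheritParams classify_sequence
#' @return Tibble of class `acyl_classification`, one row per input, in
#'   input order.
#' @export
classify_sequences <- function(x, profiles = acyl_profiles(),
                               min_motifs = 4, min_margin = 2,
                               dbm_mode = "soft") {
  if (is.character(x)) {
    ids <- names(x) %||% as.character(seq_along(x))
    x <- tibble(id = ids, sequence = unname(x))
  }
  if (!all(c("id", "sequence") %in% names(x))) {
    abort("x must have id and sequence columns")
  }
  if (anyDuplicated(x$id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  rows <- map2(x$sequence, x$id, function(s, i) {
    classify_sequence(s, profiles, min_motifs = min_motifs,
                      min_margin = min_margin, dbm_mode = dbm_mode, id = i)
  })
  out <- bind_rows(rows)
  if ("proteome" %in% names(x)) {
    out <- bind_cols(tibble(proteome = x$proteome), out) |>
      select("id", "proteome", dplyr::everything())
  }
  class(out) <- c("acyl_classification", class(out))
  attr(out, "min_margin") <- min_margin
  attr(out, "dbm_mode") <- dbm_mode
  out
}

#' Classify every record of a FASTA file
#'
#' @param path FASTA file with at least one record; duplicate or empty
#'   records are an error naming the offender.
#' @param out Optional path; when given, the classification table is also
#'   written as a tab-separated report (commented `#` header, 0-based
#'   half-open coordinates on disk).
#' @param proteome Optional proteome tag stored with every row.
#' @inheritParams classify_sequences
#' @return Tibble of class `acyl_classification` (invisibly when `out` is
#'   given); a per-subclass summary of confident calls is reported via
#'   `message()`.
#' @export
classify_fasta <- function(path, profiles = acyl_profiles(),
                           min_motifs = 4, min_margin = 2,
                           dbm_mode = "soft", proteome = NULL, out = NULL) {
  recs <- read_fasta(path)
  if (!is.null(proteome)) recs$proteome <- proteome
  res <- classify_sequences(recs, profiles, min_motifs = min_motifs,
                            min_margin = min_margin, dbm_mode = dbm_mode)
  counts <- table(factor(res$call[res$status %in% c("called", "gdpat_like")],
                         levels = c(SUBCLASSES, "GDPAT-like")))
  message("confident calls: ",
          paste(names(counts), counts, sep = "=", collapse = " "))
  if (!is.null(out)) {
    write_classification_tsv(res, out)
    return(invisible(res))
  }
  res
}

#' Presence/absence matrix of subclasses across proteomes
#'
#' A cell is `TRUE` iff the proteome contains at least one confident call of
#' that subclass (`status == "called"`; branch-level `GDPAT-like` calls are
#' tallied as their own row, since they deliberately withhold the subclass).
#'
#' @param results An `acyl_classification` with a `proteome` column.
#' @return Tibble of class `acyl_presence`: one row per subclass, one
#'   logical column per proteome.
#' @export
presence_absence <- function(results) {
  if (!"proteome" %in% names(results)) {
    abort("results must carry a proteome column")
  }
  proteomes <- unique(results$proteome)
  calls <- results |>
    filter(.data$status %in% c("called", "gdpat_like"))
  rows <- c(SUBCLASSES, "GDPAT-like")
  mat <- map(proteomes, function(pr) {
    present <- unique(calls$call[calls$proteome == pr])
    rows %in% present
  })
  out <- bind_cols(tibble(subclass = rows), setNames(as_tibble(mat, .name_repair = "minimal"), proteomes))
  if (!any(unlist(out[out$subclass == "GDPAT-like", -1]))) {
    out <- out[out$subclass != "GDPAT-like", ]
  }
  structure(out, class = c("acyl_presence", class(out)))
}

#' Per-profile scan report
#'
#' One row per sequence and subclass tried: motif offsets, the three DBM
#' values, the chain score and the spacing mode.  The long-format companion
#' of [classify_sequences()], useful for inspecting near-miss profiles.
#'
#' @inheritParams classify_sequences
#' @return Tibble with columns `id`, `subclass`, `offset_I..IV`,
#'   `dbm_I_II`, `dbm_II_III`, `dbm_III_IV`, `score`, `mode`.
#' @export
scan_report <- function(x, profiles = acyl_profiles(), dbm_mode = "soft") {
  if (is.character(x)) {
    ids <- names(x) %||% as.character(seq_along(x))
    x <- tibble(id = ids, sequence = unname(x))
  }
  rows <- pmap(list(x$sequence, x$id), function(s, i) {
    bind_rows(imap(profiles, function(p, nm) {
      ch <- scan_chain(s, p, dbm_mode = dbm_mode)
      cc <- if (is.null(ch)) empty_chain_cols() else chain_cols(ch)
      bind_cols(tibble(id = i, subclass = nm), cc,
                tibble(score = if (is.null(ch)) NA_real_ else chain_score(ch),
                       mode = dbm_mode))
    }))
  })
  bind_rows(rows)
}
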