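# Subclass profiles: four motif patterns plus the three inter-motif distance
# (DBM) ranges for one acyltransferase subclass.

SUBCLASSES <- c("fGPAT-A", "fGPAT-B", "eGPAT", "mitoGPAT", "fGDPAT", "DHAPAT")
FUNGAL_GPAT <- c("fGPAT-A", "fGPAT-B")
GDPAT_BRANCH <- c("mitoGPAT", "fGDPAT", "DHAPAT")
MOTIF_LABELS <- c("I", "II", "III", "IV")
DBM_LABELS <- c("dbm_I_II", "dbm_II_III", "dbm_III_IV")

new_profile <- function(subclass, motifs, dbm) {
  stopifnot(length(motifs) == 4, length(dbm) == 3)
  names(motifs) <- MOTIF_LABELS
  names(dbm) <- DBM_LABELS
  for (d in dbm) {
    if (length(d) != 2 || anyNA(d) || d[1] < 0 || d[1] > d[2]) {
      abort("each DBM range must be an interval [lo, hi] with 0 <= lo <= hi")
    }
  }
  for (m in motifs) {
    if (!inherits(m, "acyl_motif")) abort("motifs must be acyl_motif objects")
    nl <- motif_length(m)
    if (nl < 2 || nl > 12) abort("motif length out of supported range")
  }
  structure(list(subclass = subclass, motifs = motifs,
                 dbm = map(dbm, as.integer)),
            class = "acyl_profile")
}

#' @export
print.acyl_profile <- function(x, ...) {
  cat("<acyl_profile> ", x$subclass, "\n", sep = "")
  for (k in seq_along(MOTIF_LABELS)) {
    cat(sprintf("  motif %-3s %s\n", MOTIF_LABELS[k], x$motifs[[k]]$source))
    if (k < 4) {
      d <- x$dbm[[k]]
      cat(sprintf("    DBM %s..%s\n", d[1], d[2]))
    }
  }
  invisible(x)
}

#' Load the subclass motif profiles
#'
#' Reads the shipped (or a user-supplied) YAML description of the six
#' acyltransferase subclass profiles: four degenerate motif patterns with
#' their hallmark positions and the three inter-motif distance (DBM) ranges.
#' The shipped fixture encodes the consensus signatures of the microsomal
#' yeast-like fGPAT-A/fGPAT-B clades, the metazoan ER-type eGPATs, the
#' mitochondrial GPATs, the fungal GDPATs and the peroxisomal DHAPATs.
#'
#' @param path YAML file; `NULL` loads the shipped fixture.
#' @param classes Residue-class definitions, see [residue_classes()].
#' @return Named list of `acyl_profile` objects, in the canonical subclass
#'   order used for deterministic tie-breaking.
#' @examples
#' profs <- acyl_profiles()
#' names(profs)
#' profs[["fGPAT-A"]]
#' @export
acyl_profiles <- function(path = NULL, classes = residue_classes()) {
  if (is.null(path)) {
    path <- system.file("extdata", "acyl_profiles.yaml", package = "acylscan")
  }
  if (!file.exists(path)) abort(paste0("profile file not found: ", path))
  raw <- yaml::read_yaml(path)
  profs <- imap(raw, function(entry, subclass) {
    needed <- c(paste0("motif_", MOTIF_LABELS), DBM_LABELS)
    missing <- setdiff(needed, names(entry))
    if (length(missing)) {
      abort(paste0("profile '", subclass, "' is missing: ",
                   paste(missing, collapse = ", ")))
    }
    motifs <- map(MOTIF_LABELS, function(lab) {
      spec <- entry[[paste0("motif_", lab)]]
      parse_pattern(spec$pattern, label = lab,
                    hallmark = spec$hallmark %||% integer(),
                    classes = classes)
    })
    dbm <- map(DBM_LABELS, function(lab) as.integer(entry[[lab]]))
    new_profile(subclass, motifs, dbm)
  })
  # canonical order first, any extra user-defined profiles after
  ord <- c(intersect(SUBCLASSES, names(profs)),
           setdiff(names(profs), SUBCLASSES))
  profs[ord]
}

#' Motif-I H-to-D spacing implied by a profile
#'
#' The catalytic motif I of every subclass starts with the invariant
#' histidine and ends with the invariant aspartate; the number of residues
#' between them (HX4D vs HX5D) separates the fungal GPAT clades (five) from
#' the other four subclasses (four).
#'
#' @param prof An `acyl_profile`.
#' @return Integer residue count strictly between the H and the D.
#' @export
profile_hx_spacing <- function(prof) {
  stopifnot(inherits(prof, "acyl_profile"))
  m1 <- prof$motifs[["I"]]
  first <- m1$positions[[1]]$allowed
  last <- m1$positions[[motif_length(m1)]]$allowed
  if (!identical(first, "H") || !identical(last, "D")) {
    abort("motif I does not start with invariant H and end with invariant D")
  }
  motif_length(m1) - 2L
}
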