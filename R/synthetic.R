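# Synthetic proteomes with planted acyltransferase families.  Sequences are
# flank + motif I + gap(dbm1) + motif II + gap(dbm2) + motif III + gap(dbm3)
# + motif IV + flank (+ optional PTS1 tripeptide), with motif residues drawn
# uniformly from each position's allowed set, gaps/flanks from the
# background composition, inter-motif distances uniform within the
# profile's DBM ranges, and optional per-position substitution noise.
# Everything is reproducible from an integer seed.

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# uniform integer draw(s) from [lo, hi]; safe for width-one ranges (R's
# sample() would otherwise treat a scalar as 1:n)
sample_range <- function(lo, hi, n = 1) {
  vals <- seq.int(lo, hi)
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = n > 1)
}

sample_motif_instance <- function(m, optional_prob = 0.5) {
  kept <- integer()
  res <- character()
  for (j in seq_len(motif_length(m))) {
    spec <- m$positions[[j]]
    if (spec$optional && runif(1) >= optional_prob) next
    kept <- c(kept, j)
    res <- c(res, sample(spec$allowed, 1))
  }
  list(string = paste(res, collapse = ""), kept = kept,
       hallmark_local = which(map_lgl(m$positions[kept], "hallmark")))
}

#' Substitute residues of a protein at a fixed per-position rate
#'
#' Each eligible position is replaced, with probability `rate`, by a
#' different residue drawn from the background composition.  Positions in
#' `protect` are never touched (used to preserve hallmark residues and
#' planted targeting signals under the generator's conservative noise
#' mode).  Positions listed in `constraints` evolve under purifying
#' selection: a substitution there is drawn uniformly from the other
#' residues of the position's allowed set, so planted motifs stay
#' pattern-functional while still accumulating sequence divergence --
#' mirroring how signature motifs remain recognisable across deeply
#' diverged orthologues.  A constrained position with a single allowed
#' residue is effectively invariant.
#'
#' @param seq Protein string.
#' @param rate Per-position substitution probability in `[0, 1)`.
#' @param protect Integer positions exempt from substitution.
#' @param constraints Named character vector: names are 1-based positions,
#'   values the allowed residue set as a string (e.g. `"VILFWYM"`).
#' @param composition Background composition (see [generate_decoys()]).
#' @return Mutated sequence string.
#' @export
mutate_protein <- function(seq, rate, protect = integer(),
                           constraints = NULL, composition = "uniform") {
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  eligible <- setdiff(seq_along(chars), protect)
  hit <- eligible[runif(length(eligible)) < rate]
  p <- resolve_composition(composition)
  for (i in hit) {
    ci <- if (is.null(constraints)) NA_character_ else
      unname(constraints[as.character(i)])
    if (!is.na(ci)) {
      pool <- setdiff(strsplit(ci, "")[[1]], chars[i])
      if (length(pool) == 0) next
      chars[i] <- sample(pool, 1)
    } else {
      others <- setdiff(AA_STANDARD20, chars[i])
      chars[i] <- sample(others, 1, prob = p[others] / sum(p[others]))
    }
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic protein family
#'
#' Plants `n` members of one subclass: motifs drawn from the profile's
#' patterns, spacings uniform within its DBM ranges, flanks from the
#' background composition, an optional C-terminal PTS1 tripeptide, and
#' optional substitution noise applied after assembly.  In the default
#' `"conservative"` noise mode the hallmark residues and any planted PTS1
#' tripeptide are exempt and the remaining motif positions evolve under
#' purifying selection (substitutions stay within each position's allowed
#' set, so motifs remain functional while diverging); `"harsh"` mode hits
#' every position without constraint and is the stress test for degraded
#' motifs.
#'
#' @param prof An `acyl_profile`.
#' @param n Number of members (>= 1).
#' @param noise Per-position substitution probability in `[0, 1)`.
#' @param noise_mode `"conservative"` or `"harsh"`.
#' @param pts1 `"none"`, `"canonical"` or `"relaxed"`: append a targeting
#'   tripeptide of that tier.
#' @param length_range Total length interval; the default adds a 40-160
#'   residue flank budget to the profile's maximal core.  An error is
#'   raised when the range cannot fit motifs plus minimal spacings.
#' @param composition Background composition for gaps and flanks.
#' @param optional_prob Probability that an optional motif position is
#'   included in a planted instance.
#' @param dbm_override Optional list of three `[lo, hi]` ranges replacing
#'   the profile's DBM sampling ranges (e.g. to emulate documented spacing
#'   exceptions).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param prefix Id prefix (default derived from the subclass).
#' @return Tibble: `id`, `subclass`, `sequence`, planted motif placements
#'   (`offset_I..IV`, `length_I..IV`, 1-based), planted spacings
#'   (`dbm_I_II`, `dbm_II_III`, `dbm_III_IV`), `pts1_tripeptide` (`NA` when
#'   none), `protected` (list-column of positions exempt from conservative
#'   noise: hallmarks plus the PTS1 tripeptide) and `constraints`
#'   (list-column mapping motif positions to their allowed residue sets,
#'   the purifying-selection map used by [mutate_protein()]).
#' @examples
#' profs <- acyl_profiles()
#' fam <- generate_family(profs[["fGPAT-A"]], n = 3, seed = 11)
#' fam$dbm_II_III
#' @export
generate_family <- function(prof, n, noise = 0,
                            noise_mode = c("conservative", "harsh"),
                            pts1 = c("none", "canonical", "relaxed"),
                            length_range = NULL, composition = "uniform",
                            optional_prob = 0.5, dbm_override = NULL,
                            seed = NULL, prefix = NULL) {
  noise_mode <- match.arg(noise_mode)
  pts1 <- match.arg(pts1)
  stopifnot(inherits(prof, "acyl_profile"), n >= 1)
  dbm <- dbm_override %||% prof$dbm
  if (length(dbm) != 3) abort("dbm_override must give three ranges")
  max_core <- sum(map_int(prof$motifs, motif_length)) +
    sum(map_dbl(dbm, 2)) + if (pts1 == "none") 0 else 3
  min_core <- sum(map_int(prof$motifs, function(m) {
    motif_length(m) - sum(map_lgl(m$positions, "optional"))
  })) + sum(map_dbl(dbm, 1)) + if (pts1 == "none") 0 else 3
  if (is.null(length_range)) length_range <- max_core + c(40, 160)
  if (length_range[2] < min_core + 2) {
    abort("length range too small to fit motifs plus minimal spacings")
  }
  prefix <- prefix %||% gsub("-", "", prof$subclass)

  with_opt_seed(seed, {
    rows <- map(seq_len(n), function(i) {
      repeat {
        inst <- map(prof$motifs, sample_motif_instance,
                    optional_prob = optional_prob)
        lens <- map_int(inst, function(x) nchar(x$string))
        d <- unname(map_int(dbm, function(rg) {
          as.integer(sample_range(rg[1], rg[2]))
        }))
        core <- sum(lens) + sum(d) + if (pts1 == "none") 0 else 3
        lo <- max(length_range[1], core)
        if (lo <= length_range[2]) break
      }
      total <- sample_range(lo, length_range[2])
      flank_total <- total - core
      flank1 <- sample_range(0, flank_total)
      flank2 <- flank_total - flank1
      gaps <- map(d, function(g) paste(sample_background(g, composition),
                                       collapse = ""))
      tp <- if (pts1 == "none") NA_character_ else sample_pts1_tripeptide(pts1)
      seqstr <- paste0(
        paste(sample_background(flank1, composition), collapse = ""),
        inst[[1]]$string, gaps[[1]], inst[[2]]$string, gaps[[2]],
        inst[[3]]$string, gaps[[3]], inst[[4]]$string,
        paste(sample_background(flank2, composition), collapse = ""),
        if (is.na(tp)) "" else tp
      )
      offsets <- integer(4)
      pos <- flank1 + 1
      for (k in 1:4) {
        offsets[k] <- pos
        pos <- pos + lens[k] + if (k < 4) d[k] else 0
      }
      protected <- unlist(map(1:4, function(k) {
        offsets[k] - 1 + inst[[k]]$hallmark_local
      }))
      if (!is.na(tp)) {
        protected <- c(protected, (nchar(seqstr) - 2):nchar(seqstr))
      }
      # purifying-selection map: absolute motif position -> allowed residues
      constraints <- unlist(map(1:4, function(k) {
        kept <- inst[[k]]$kept
        setNames(
          map_chr(prof$motifs[[k]]$positions[kept], function(sp) {
            paste(sp$allowed, collapse = "")
          }),
          offsets[k] - 1 + seq_along(kept)
        )
      }))
      if (noise > 0) {
        seqstr <- if (noise_mode == "conservative") {
          mutate_protein(seqstr, noise, protect = protected,
                         constraints = constraints, composition = composition)
        } else {
          mutate_protein(seqstr, noise, composition = composition)
        }
      }
      tibble(
        id = sprintf("%s_%03d", prefix, i), subclass = prof$subclass,
        sequence = seqstr,
        offset_I = offsets[1], offset_II = offsets[2],
        offset_III = offsets[3], offset_IV = offsets[4],
        length_I = lens[1], length_II = lens[2],
        length_III = lens[3], length_IV = lens[4],
        dbm_I_II = d[1], dbm_II_III = d[2], dbm_III_IV = d[3],
        pts1_tripeptide = tp, protected = list(sort(protected)),
        constraints = list(constraints)
      )
    })
    bind_rows(rows)
  })
}

#' Generate unrelated background (decoy) proteins
#'
#' I.i.d. sequences from the background composition, with nothing planted.
#'
#' @param n Number of decoys (>= 1).
#' @param length_range Length interval, sampled uniformly.
#' @param composition `"uniform"` (the default; it makes motif specificity
#'   weights exact) or a named probability vector over the 20 residues.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param prefix Id prefix.
#' @return Tibble with `id` and `sequence`.
#' @export
generate_decoys <- function(n, length_range = c(200, 500),
                            composition = "uniform", seed = NULL,
                            prefix = "decoy") {
  stopifnot(n >= 1)
  with_opt_seed(seed, {
    lens <- sample_range(length_range[1], length_range[2], n)
    tibble(
      id = sprintf("%s_%04d", prefix, seq_len(n)),
      sequence = map_chr(lens, function(L) {
        paste(sample_background(L, composition), collapse = "")
      })
    )
  })
}

#' Survey membership plans
#'
#' Preset proteome compositions for [generate_survey_set()].  The default
#' eight-proteome opisthokont-flavoured plan covers the characteristic
#' gain/loss patterns: a budding-yeast-like proteome carrying only the two
#' fGPAT-A paralogues ("sack_like": the mitoGPAT/fGDPAT rows are absent, as
#' in the Saccharomycetaceae), a reduced parasite-like proteome with a
#' single eGPAT ("microsporidian_like"), and richer basal lineages carrying
#' most of the complement.
#'
#' @param preset `"opisthokont8"`, `"sack_like"` or `"single_egpat"`.
#' @return Tibble with columns `proteome`, `subclass`, `count`.
#' @export
survey_plan <- function(preset = c("opisthokont8", "sack_like",
                                   "single_egpat")) {
  preset <- match.arg(preset)
  plan_row <- function(proteome, subclass, count = 1) {
    tibble(proteome = proteome, subclass = subclass, count = count)
  }
  sack <- plan_row("sack_like", "fGPAT-A", 2)
  single <- plan_row("microsporidian_like", "eGPAT", 1)
  if (preset == "sack_like") return(sack)
  if (preset == "single_egpat") return(single)
  bind_rows(
    sack,
    plan_row("fission_yeast_like", "fGPAT-A", 1),
    single,
    plan_row("filamentous_fungus_like", c("fGPAT-A", "fGDPAT")),
    plan_row("basidiomycete_like", c("fGPAT-A", "fGPAT-B")),
    bind_rows(plan_row("vertebrate_like", "eGPAT", 2),
              plan_row("vertebrate_like", c("mitoGPAT", "DHAPAT"))),
    plan_row("invertebrate_like", c("eGPAT", "mitoGPAT", "DHAPAT")),
    plan_row("basal_holozoan_like",
             c("fGPAT-A", "fGPAT-B", "eGPAT", "mitoGPAT", "fGDPAT", "DHAPAT"))
  )
}

#' Generate a synthetic survey scenario
#'
#' Builds a directory-of-proteomes analogue in memory: one noise-free
#' founder per subclass (deposited in the reference proteome as the seed),
#' per-proteome orthologues obtained by mutating the founder to the given
#' divergence (hallmarks and planted PTS1 preserved), and background decoys
#' filling each proteome to `proteome_size`.  fGDPAT founders carry a
#' canonical PTS1 tripeptide; no other subclass does.
#'
#' @param plan Membership plan tibble (see [survey_plan()]).
#' @param divergence Per-position substitution probability applied to each
#'   orthologue.
#' @param proteome_size Total proteins per proteome (planted + decoys).
#' @param decoy_length Length interval for decoys, chosen to overlap the
#'   planted families.
#' @param reference_decoys Number of decoys mixed into the reference
#'   proteome alongside the seeds.
#' @param profiles Named list of `acyl_profile`s.
#' @param seed Integer seed driving the entire scenario.
#' @return List: `proteomes` (named list of named sequence vectors),
#'   `reference` (named vector), `seeds` (family -> reference id),
#'   `truth` (`acyl_presence` matrix from the plan), `members` (tibble of
#'   planted orthologues with their family and proteome), `founders`
#'   (the founder family tibble), and `plan`.
#' @export
generate_survey_set <- function(plan = survey_plan(), divergence = 0.05,
                                proteome_size = 300,
                                decoy_length = c(250, 450),
                                reference_decoys = 60,
                                profiles = acyl_profiles(), seed = 1) {
  if (nrow(plan) == 0) abort("plan must be non-empty")
  families <- unique(plan$subclass)
  missing_prof <- setdiff(families, names(profiles))
  if (length(missing_prof)) {
    abort(paste0("no profile for: ", paste(missing_prof, collapse = ", ")))
  }
  with_opt_seed(seed, {
    founders <- bind_rows(map(families, function(f) {
      generate_family(profiles[[f]], n = 1,
                      pts1 = if (f == "fGDPAT") "canonical" else "none",
                      prefix = paste0("seed_", gsub("-", "", f)))
    }))
    proteome_names <- unique(plan$proteome)
    members <- list()
    proteomes <- map(proteome_names, function(pr) {
      rows <- plan[plan$proteome == pr, ]
      planted <- list()
      for (t in seq_len(nrow(rows))) {
        f <- rows$subclass[t]
        fr <- founders[founders$subclass == f, ]
        for (iso in seq_len(rows$count[t])) {
          id <- sprintf("%s_%s_iso%d", pr, gsub("-", "", f), iso)
          mseq <- mutate_protein(fr$sequence, divergence,
                                 protect = fr$protected[[1]],
                                 constraints = fr$constraints[[1]])
          planted[[id]] <- mseq
          members[[length(members) + 1]] <<- tibble(
            proteome = pr, id = id, family = f, isoform = iso
          )
        }
      }
      n_decoy <- proteome_size - length(planted)
      if (n_decoy < 0) abort("proteome_size smaller than planted members")
      dec <- generate_decoys(n_decoy, decoy_length,
                             prefix = paste0(pr, "_decoy"))
      c(unlist(planted), setNames(dec$sequence, dec$id))
    })
    names(proteomes) <- proteome_names
    ref_dec <- generate_decoys(reference_decoys, decoy_length,
                               prefix = "ref_decoy")
    reference <- c(setNames(founders$sequence, founders$id),
                   setNames(ref_dec$sequence, ref_dec$id))
    seeds <- setNames(map(families, function(f) {
      founders$id[founders$subclass == f]
    }), families)
    truth <- bind_cols(
      tibble(subclass = families),
      setNames(as_tibble(map(proteome_names, function(pr) {
        map_lgl(families, function(f) {
          any(plan$proteome == pr & plan$subclass == f & plan$count > 0)
        })
      }), .name_repair = "minimal"), proteome_names)
    )
    class(truth) <- c("acyl_presence", class(truth))
    list(proteomes = proteomes, reference = reference, seeds = seeds,
         truth = truth, members = bind_rows(members), founders = founders,
         plan = plan, divergence = divergence, seed = seed)
  })
}

#' Generate a two-step discovery scenario
#'
#' Constructs a family whose second member is discoverable only through the
#' profile rebuilt after the first member is validated: member A is a
#' lightly diverged orthologue of the seed; member B shares A's motif
#' windows and spacings but has freshly drawn flanks and inter-motif gaps,
#' so its best local alignment against the seed is limited to a single
#' motif block and falls short of the first-pass E-value cutoff, while its
#' intact motif chain scores highly against the family profile.  The
#' reference proteome carries the seed plus a handful of short decoys so
#' that B's reciprocal best hit is still the seed.
#'
#' @param prof Family profile (the mitochondrial-GPAT profile by default:
#'   its motif blocks are individually weak enough for the construction).
#' @param n_decoys Decoys in the survey proteome.
#' @param motif_divergence Constrained substitution rate applied to B's
#'   motif windows relative to A's.
#' @param e_cutoff First-pass E-value cutoff the construction must evade.
#' @param max_attempts Rejection-sampling bound: draws that do not realise
#'   the designed structure (B above the cutoff against the seed, or B's
#'   reciprocal best hit not the seed) are discarded and redrawn; the
#'   accepted draw is still fully determined by `seed`.
#' @param seed Integer seed.
#' @return List with `proteomes`, `reference`, `seeds`, the ids of the
#'   planted members `a_id`/`b_id`, and the founder row.
#' @export
generate_two_step_scenario <- function(prof = acyl_profiles()[["mitoGPAT"]],
                                       n_decoys = 30,
                                       motif_divergence = 0.4,
                                       e_cutoff = 0.05, max_attempts = 40,
                                       seed = 1) {
  with_opt_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      founder <- generate_family(prof, n = 1, length_range = c(950, 1050),
                                 prefix = "twostep_seed")
      a_seq <- mutate_protein(founder$sequence, 0.05,
                              protect = founder$protected[[1]],
                              constraints = founder$constraints[[1]])
      # member B: A's motif windows, further diverged within the patterns'
      # allowed sets, on freshly drawn flanks and inter-motif gaps
      offs <- c(founder$offset_I, founder$offset_II, founder$offset_III,
                founder$offset_IV)
      lens <- c(founder$length_I, founder$length_II, founder$length_III,
                founder$length_IV)
      windows <- map_chr(1:4, function(k) {
        w <- substr(a_seq, offs[k], offs[k] + lens[k] - 1)
        kept <- match_positions(prof$motifs[[k]], nchar(w))
        cons <- setNames(
          map_chr(prof$motifs[[k]]$positions[kept], function(sp) {
            paste(sp$allowed, collapse = "")
          }),
          seq_len(nchar(w))
        )
        hall <- which(map_lgl(prof$motifs[[k]]$positions[kept], "hallmark"))
        mutate_protein(w, motif_divergence, protect = hall,
                       constraints = cons)
      })
      dbms <- unname(map_int(prof$dbm, function(rg) {
        as.integer(sample_range(rg[1], rg[2]))
      }))
      flank1 <- paste(sample_background(sample(40:80, 1)), collapse = "")
      flank2 <- paste(sample_background(sample(40:80, 1)), collapse = "")
      gaps <- map_chr(dbms, function(g) {
        paste(sample_background(g), collapse = "")
      })
      b_seq <- paste0(flank1, windows[1], gaps[1], windows[2], gaps[2],
                      windows[3], gaps[3], windows[4], flank2)
      ref_dec <- generate_decoys(4, c(40, 70), prefix = "twostep_refdecoy")
      reference <- c(setNames(founder$sequence, founder$id),
                     setNames(ref_dec$sequence, ref_dec$id))
      # the construction must realise the two-step structure
      sw_b <- smith_waterman(b_seq, founder$sequence)
      if (sw_b$e_value <= e_cutoff) next
      bh <- best_hit(b_seq, reference, cutoff = Inf)
      if (bh$subject_id != founder$id) next
      if (is.null(scan_chain(b_seq, prof))) next
      dec <- generate_decoys(n_decoys, c(300, 600), prefix = "twostep_decoy")
      proteome <- c(setNames(c(a_seq, b_seq), c("member_A", "member_B")),
                    setNames(dec$sequence, dec$id))
      return(list(
        proteomes = list(twostep = proteome),
        reference = reference,
        seeds = setNames(list(founder$id), prof$subclass),
        a_id = "member_A", b_id = "member_B", founder = founder,
        attempts = attempt
      ))
    }
    abort("could not realise a two-step scenario; try another seed")
  })
}
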