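---
title: "Methods: motif-grammar scanning and the comparative acyltransferase survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-grammar scanning and the comparative acyltransferase survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Glycerol-3-phosphate acyltransferases (GPATs) catalyse the committed step of
glycerolipid synthesis; the related dihydroxyacetone-phosphate
acyltransferase (DHAPAT) performs the analogous acylation in peroxisomes.
All of these enzymes carry the lysophospholipid-acyltransferase signature
domain (pfam01553): four short sequential motifs (I–IV), with motif I
holding the catalytic histidine–aspartate dyad.  Across the opisthokonts
the enzymes fall into six recognisable subclasses — two deep fungal
microsomal clades (fGPAT-A, which contains yeast Sct1/Gpt2, and fGPAT-B), the
metazoan ER-type eGPATs (chordate GPAT3/GPAT4 arose inside this lineage),
the mitochondrial GPATs, the peroxisomal DHAPATs, and a fungal/basal
pre-duplication clade (the "GDPATs") that is homologous to both of the last
two and carries a C-terminal peroxisomal targeting signal.

Two sequence-level features separate these subclasses remarkably cleanly:

* the **motif consensus** itself — e.g. an invariant `FPEGGSHD` motif III in
  fGPAT-A, versus `F φ E G [G/T] R [S/T] R`-type motifs III in the
  mitochondrial/peroxisomal branch; and the motif-I spacing of the
  catalytic dyad, five residues between H and D (HX5D) in the fungal GPATs
  versus four (HX4D) everywhere else;
* the **distance between motifs** (DBM): the number of residues strictly
  between consecutive motifs.  The II–III spacing is around three times
  longer in fGPAT-A (97–132 residues) than in the eGPATs (23–27), and the
  mitochondrial/peroxisomal branch holds its III–IV spacing at exactly 28.

`acylscan` turns these observations into a tested pipeline: a degenerate
motif grammar, a spacing-constrained chain scanner, a subclass classifier,
a rule-based PTS1 call, an iterative homology survey with reciprocal-best-
hit validation, distance-based subfamily clustering, and a synthetic-data
generator that makes every stage testable offline.

## The motif grammar

Patterns are space-delimited tokens: literals, the wildcard `x`, the class
symbols `pi` ({P, G, A, S}, short-chain), `phi` ({V, I, L, F, W, Y, M},
hydrophobic) and `[+]`, and bracketed alternatives (`[T/S]`, `[pi/phi]`).
A `-` alternative (`[-/N]`) marks a position optional, so a motif's match
length can vary by one.  Non-standard residues (B, Z, X, U…) match only the
wildcard; conservative matching avoids spurious hallmark hits.

Design choices that the source notation leaves open:

* **`[+]` membership.**  The basic class is taken as {K, R, H}; histidine
  is included because it is positively chargeable and the contexts where
  the token occurs are basic.  The choice is overridable
  (`residue_classes("+" = …)`).
* **Token granularity.**  One subclass's motif II ends in a compact `xD`
  run whose reading is ambiguous between one token and two; it is
  implemented as two positions (`x` then `D`), the conservative reading
  that keeps the hallmark arginine at position 5.  The shipped YAML fixture
  flags this in a comment.
* **Match weighting.**  A matched position contributes
  `log2(20 / |allowed|)` bits — literals are worth `log2 20 ≈ 4.32`, class
  positions less, wildcards nothing — so chain scores reward specificity
  and are exact under the generator's uniform background.

## Chain placement and DBM

`scan_chain()` places motifs I–IV in order, non-overlapping, by dynamic
programming over the per-motif occurrence lists.  The chain score is the
sum of position weights plus a spacing term: zero inside the profile's DBM
range; in *soft* mode a penalty of 0.5 bits per residue outside the range;
in *hard* mode such chains are discarded.  The DP is checked against
exhaustive enumeration of occurrence combinations in the test suite.
Ties are broken towards the leftmost placements, making reports
deterministic.

DBM counts residues *strictly between* the last residue of the upstream
motif and the first residue of the downstream one.  An inclusive variant is
available (`inclusive_dbm = TRUE`) for sensitivity checks only.

Classification uses soft mode by default: a documented pair of divergent
metazoan/filasterean mitochondrial GPATs carries 65 residues between motifs
II and III where the subclass range is 30–32, and hard mode would reject
such members outright.  The generator can emulate those exceptions through
`dbm_override`.

The shipped profile fixture also records one further discrepancy: the text
account of the fGPAT-A II–III spacing says 99–132 while the tabulated range
is 97–132; the fixture uses the tabulated value.

## Classification rules

Per protein, every profile is scanned in soft mode.  Then:

1. **HX filter (hard).**  The motif-I window of the top-scoring chain gives
   the H→D spacing; HX5D sequences can only be called fGPAT-A/B and HX4D
   sequences only the other four.  On noise-free synthetic members this
   filter alone separates the fungal GPATs from the rest.
2. **Margin rule.**  The best-scoring surviving profile is called when its
   margin over the runner-up is at least `min_margin` (default 2 bits —
   materially larger than a single wildcard-position weight, and small
   relative to typical inter-profile gaps of 5+ bits on synthetic data).
3. **Branch-level fallback.**  The mitoGPAT/fGDPAT/DHAPAT motifs are nearly
   identical; when the within-margin candidates all come from that branch
   the call is `GDPAT-like` plus the PTS1 flag — deliberately refusing to
   assign substrate preference, as the branch's pre-duplication biology
   warrants.
4. **Partial reports.**  A protein placing only three consecutive motifs is
   reported `partial`, never called.

The fGPAT-A versus fGPAT-B boundary deserves a caveat: no published numeric
rule separates them beyond clade membership, so the motif-score rule here is
a stand-in, and reports should treat A/B swaps as soft evidence.  The
chordate-specific divergent paralogue of the mitochondrial enzymes (GPAT2)
is intentionally not a separate profile.

## PTS1 calls

`detect_pts1()` is a rule-based tripeptide classifier: `canonical` for
`[S/A/C][K/R/H][L/M]`, `relaxed` for `[S/A/C/G/P/T][K/R/H][L/M/I/F]`.  It
replaces position-weight-matrix scoring services deliberately: the tiers
capture the consensus biology, are dependency-free, and depend only on the
final three residues (a property the tests enforce).  It does not attempt
organism-specific scoring or PTS2 detection.

## The iterative survey

The survey emulates an iterative comparative-genomic search:

1. **Pass 1 — alignment.**  Every protein of every proteome is scored by
   exact Smith–Waterman (BLOSUM62, gap open 11 / extend 1) against the
   family's seeds; candidates need E ≤ 0.05 under the Karlin–Altschul form
   `E = K·m·n·exp(−λS)` with the published gapped constants λ = 0.267,
   K = 0.041.  Exact alignment is entirely affordable at the proteome
   sizes targeted here, so no heuristic seeding layer exists.
2. **Validation.**  A candidate is admitted only if (a) its best-scoring
   hit in the reference proteome is one of the family's seeds
   (reciprocal-best-hit; **no** E cutoff on the reciprocal direction —
   only the identity of the best hit matters) and (b) it carries a full
   motif chain for the family profile.  The chain requirement mirrors
   motif-level inspection of candidates and is load-bearing: measured on
   uniform-composition decoys, random local-alignment scores sit close to
   the nominal E = 0.05 level (the published constants were fitted to real
   protein composition), so the E cutoff alone would admit a sizeable
   spurious tail.  It is also what guarantees the next step is well posed.
3. **Profile rebuild.**  Validated members are anchored by their motif
   chains — the placement fixes the columns, so no explicit multiple
   alignment is needed — and a PSSM over the concatenated motif windows is
   built with Laplace-style pseudocounts (`α = 0.5`, uniform background):
   `freq = (n_r + α q_r) / (N + α)`, score `log2(freq / q)`.  The single
   optional motif position is occupancy-weighted: estimated from, and
   scored for, only the members that carry it.
4. **Pass ≥ 2 — profile search.**  Remaining proteins are scored by the
   PSSM; candidates need non-negative log-odds (more family-like than
   background), then revalidate as above.  The loop stops when a pass adds
   nothing; validated sets grow monotonically inside a finite universe, so
   termination is guaranteed.

The reciprocal direction deliberately carries no E cutoff (the criterion is
"returned a seed as the best-scoring sequence").  Applying one there would
make profile-mediated discoveries impossible: a homologue found only via
the enriched profile is, by construction, one whose direct alignment to the
seed is statistically marginal in *both* directions.

Seed sets may pool several seeds per family (as joint search matrices
would); the survey takes the best per-seed score.

## Clustering

Identity distances (`1 −` identity of the global Needleman–Wunsch
alignment; a Poisson correction is available but off by default since only
clade structure is interpreted) feed a neighbour-joining implementation
with two determinism/sanity refinements: Q-criterion ties are resolved
towards the lexicographically smallest pair of cluster labels, and negative
branch estimates are clamped to zero with the deficit shifted to the sister
branch so path lengths are preserved.  `is_clade()` checks whether a label
set is an exact bipartition side of the unrooted tree.  The implementation
is cross-checked against an independent NJ implementation and against an
independent split decomposition in the tests.  Bootstrap support, model
selection and Bayesian inference are explicitly out of scope — the tree
stage answers only "do the validated hits of one subclass group together?".

## What the generator emulates — and what it does not

`generate_family()` assembles flank + motif I + gap + … + motif IV + flank
(+ optional PTS1 tripeptide): motif residues uniform within each position's
allowed set, spacings uniform within the DBM ranges, background uniform
over the 20 residues (a Robinson–Robinson-style composition can be
supplied; uniform is the default because it makes the specificity weights
exact).  The truth table records every planted offset, spacing and signal,
and everything is reproducible from one integer seed.

Substitution noise comes in two modes.  *Conservative* (default) models
purifying selection: hallmark residues and planted PTS1 tripeptides are
untouched, and other motif positions mutate only within their allowed sets
— so motifs stay functional while sequences diverge, which is exactly the
regime the comparative survey exploits (motifs recognisable across
lineages separated by hundreds of millions of years).  *Harsh* mode
substitutes anywhere and is the stress test for degraded motifs.

Orthologue sets for the survey scenarios are draws from a single founder
mutated to a target divergence under the conservative model.  The default
eight-proteome plan encodes the characteristic gain/loss patterns: a
budding-yeast-like proteome with two fGPAT-A paralogues and no
mitochondrial/GDPAT branch at all, a reduced parasite-like proteome whose
single acyltransferase is an eGPAT, and basal lineages carrying most of the
complement.  The two-step scenario plants a member discoverable only
through the profile rebuilt after its relative is validated; because the
construction sits inside a narrow alignment-score window, the generator
rejection-samples until the designed structure is realised (the accepted
draw is still a pure function of the seed).

What passing tests on this generator do **not** show about real data: there
is no indel process (beyond the one optional motif position), no rate
heterogeneity or site correlation, no compositional bias, and no
evolutionary relationship between the decoys and the families.  Real
proteomes contain related non-orthologous acyltransferases that the decoy
model does not imitate; classification margins on real sequences will be
tighter than the synthetic ones.

## Numerical choices, sizes and conventions

* Chain-score DBM penalty: 0.5 bits/residue outside the range — arbitrary
  but fixed; only score orderings, never absolute values, are interpreted.
* E-value constants λ = 0.267, K = 0.041 (gapped BLOSUM62 11/1); they are
  configurable, and their miscalibration on uniform backgrounds is treated
  as a feature of the realistic setting the validation layers must cope
  with, not corrected away.
* Deterministic tie-breaks everywhere: occurrences ordered by offset then
  length, subjects by id, subclasses by the canonical fixed order, NJ pairs
  lexicographically.
* In-memory coordinates are 1-based (R convention); every on-disk report
  uses 0-based, half-open coordinates and says so in its header.
* Test/acceptance problem sizes, chosen to exercise each property at
  desk scale: oracle comparisons on 200 sequences up to 400 residues and
  alignments up to 8 residues (where enumeration is exact); six families
  of 50 for recovery; an 8-proteome × 300-protein survey at divergence
  0.05; 20 decoy-only replicate surveys for the zero-false-validation
  check; 50 random 6–10-taxon trees and 20 clustering replicates.

## Known limitations

* The profile HMM of a full iterative search is replaced by a
  motif-anchored PSSM; inter-motif regions contribute nothing to profile
  scores, so family signal outside the motifs is ignored.
* The fGPAT-A/fGPAT-B decision is a motif-score stand-in for clade
  membership (see above).
* Within the mitoGPAT/fGDPAT/DHAPAT branch, a rare member (about one in a
  few hundred synthetic draws) samples motif residues that also satisfy a
  sister profile's stricter patterns; because specificity weights reward
  narrower allowed sets, the sister can then outscore the true subclass
  beyond the margin.  This is inherent to the scoring rule, is confined to
  the branch whose substrate preference the branch-level call already
  declines to predict, and shows up as classification accuracy a fraction
  of a percent below 1 for some generator seeds.
* PTS1 calls are tier-based, not scored; borderline real signals will be
  called coarsely.
* The E-value is a convention anchor, not a calibrated false-positive
  rate; specificity comes from reciprocal validation plus the chain
  requirement.
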