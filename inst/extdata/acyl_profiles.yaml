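# Shipped consensus motif profiles for the six opisthokont GPAT/DHAPAT
# subclasses.  For each subclass: the four sequential acyltransferase
# signature motifs (pfam01553 domain, motif I carries the catalytic H...D
# dyad), the 1-based hallmark positions of each motif, and the distance
# between motifs (DBM) as closed integer ranges [lo, hi] counting residues
# strictly between consecutive motifs.
#
# Token notation: literals; x = any residue; pi = {P,G,A,S}; phi =
# {V,I,L,F,W,Y,M}; [+] = {K,R,H}; [A/B] = alternatives; a "-" alternative
# ("[-/N]") marks the position optional, so the motif length varies by one.
#
# Notes:
#  - fGPAT-A motif II is transcribed as eight positions, reading the final
#    run as two tokens "x" then "D" (the compact source notation is
#    ambiguous between one token and two; two positions is the conservative
#    reading and keeps the hallmark arginine at position 5).
#  - fGPAT-B motif II ends in a run of three wildcards, read as three
#    single-position tokens.
#  - mitoGPAT dbm_II_III is 30-32 for typical members; a documented pair of
#    divergent metazoan/filasterean sequences carries 65 residues between
#    motifs II and III, which is why classification defaults to soft DBM
#    scoring rather than hard rejection.
fGPAT-A:
  motif_I:   {pattern: "H x N Q F phi D",          hallmark: [1, 7]}
  dbm_I_II:   [35, 46]
  motif_II:  {pattern: "phi pi V x R [pi/phi] x D", hallmark: [5]}
  dbm_II_III: [97, 132]
  motif_III: {pattern: "F P E G G S H D",          hallmark: [1, 3, 4]}
  dbm_III_IV: [26, 28]
  motif_IV:  {pattern: "phi phi P [V/C] G",        hallmark: [3]}
fGPAT-B:
  motif_I:   {pattern: "H x N x phi phi D",        hallmark: [1, 7]}
  dbm_I_II:   [36, 40]
  motif_II:  {pattern: "phi P phi x R x x x",      hallmark: [5]}
  dbm_II_III: [21, 104]
  motif_III: {pattern: "F P E G [T/G/I] S [H/Y] x", hallmark: [1, 3, 4]}
  dbm_III_IV: [29, 35]
  motif_IV:  {pattern: "phi phi P [V/C/T] pi",     hallmark: [3]}
eGPAT:
  motif_I:   {pattern: "H [T/S] [S/T] [P/phi] phi D", hallmark: [1, 6]}
  dbm_I_II:   [36, 42]
  motif_II:  {pattern: "phi [W/M] F [-/N] R x",    hallmark: [5]}
  dbm_II_III: [23, 27]
  motif_III: {pattern: "F P E G T C phi N N",      hallmark: [1, 3, 4]}
  dbm_III_IV: [18, 18]
  motif_IV:  {pattern: "phi x P phi A",            hallmark: [3]}
mitoGPAT:
  motif_I:   {pattern: "H [+] S H phi D",          hallmark: [1, 6]}
  dbm_I_II:   [38, 39]
  motif_II:  {pattern: "F F I [+] R [+] phi",      hallmark: [5]}
  dbm_II_III: [30, 32]
  motif_III: {pattern: "F phi E G [G/T/S] R [S/T] R", hallmark: [1, 3, 4]}
  dbm_III_IV: [28, 28]
  motif_IV:  {pattern: "phi phi P phi [pi/N]",     hallmark: [3]}
fGDPAT:
  motif_I:   {pattern: "H [+] S H phi D",          hallmark: [1, 6]}
  dbm_I_II:   [38, 38]
  motif_II:  {pattern: "phi phi I R R x phi",      hallmark: [5]}
  dbm_II_III: [27, 27]
  motif_III: {pattern: "F phi E G [G/T] R [S/T] R", hallmark: [1, 3, 4]}
  dbm_III_IV: [28, 28]
  motif_IV:  {pattern: "phi x P phi pi",           hallmark: [3]}
DHAPAT:
  motif_I:   {pattern: "H [+] [S/T] Y phi D",      hallmark: [1, 6]}
  dbm_I_II:   [38, 39]
  motif_II:  {pattern: "F phi M R R [T/S] F",      hallmark: [5]}
  dbm_II_III: [28, 30]
  motif_III: {pattern: "F phi E G T R S R",        hallmark: [1, 3, 4]}
  dbm_III_IV: [28, 28]
  motif_IV:  {pattern: "phi x P phi pi",           hallmark: [3]}
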