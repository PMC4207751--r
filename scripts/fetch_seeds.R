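#!/usr/bin/env Rscript
# Optional helper: downloads the seven characterised seed proteins (yeast
# Sct1/Gpt2, human GPAT1/GPAT2/GPAT3/GPAT4 and human DHAPAT) from NCBI as a
# FASTA file, for exploring the scanner on real sequences, e.g.
#
#   Rscript scripts/fetch_seeds.R seeds.fasta
#   Rscript -e 'acylscan::scan_report(acylscan::read_fasta("seeds.fasta"))'
#
# Requires network access; nothing in the package or its test suite depends
# on this script.

accessions <- c(
  sct1_yeast   = "NP_009542.1",
  gpt2_yeast   = "NP_012993.1",
  gpat1_human  = "NP_065969.3",
  gpat2_human  = "NP_997211.2",
  dhapat_human = "NP_055051.1",
  gpat3_human  = "NP_116106.2",
  gpat4_human  = "NP_848934.1"
)

out <- commandArgs(trailingOnly = TRUE)
if (length(out) != 1) stop("usage: Rscript scripts/fetch_seeds.R <out.fasta>")

url <- paste0(
  "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
  "?db=protein&rettype=fasta&retmode=text&id=",
  paste(accessions, collapse = ",")
)
download.file(url, out, quiet = TRUE)
cat("wrote", out, "\n")
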