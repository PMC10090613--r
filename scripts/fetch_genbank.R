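#!/usr/bin/env Rscript
# One-time helper: fetches the deposited Bivesicula sequences from NCBI
# (network required), writes per-marker FASTA files, aligns each marker
# with mafft if available, and recomputes the published raw-difference
# anchors with otudelim::verify_published_anchors().
#
# Usage: Rscript scripts/fetch_genbank.R [out_dir]
# The cox1 fragments align without gaps; ITS2 requires trimming to the
# published 453-column window, which this script does not attempt — the
# ITS2 check is only run if mafft produces a gap-free core alignment.

suppressPackageStartupMessages(library(otudelim))

out_dir <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(out_dir) >= 1L) out_dir[[1L]] else "scratch/genbank"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cox1_acc <- sprintf("OM456%d", 615:680)
its2_acc <- sprintf("OM523%d", 325:355)

efetch <- function(accessions, path) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
    "db=nucleotide&rettype=fasta&retmode=text&id=",
    paste(accessions, collapse = ","))
  status <- utils::download.file(url, path, quiet = TRUE)
  if (status != 0L) stop("download failed for ", path)
  path
}

align <- function(raw, aligned) {
  if (nzchar(Sys.which("mafft"))) {
    system2("mafft", c("--auto", "--quiet", raw), stdout = aligned)
  } else {
    message("mafft not found; align ", raw, " externally before verifying")
    return(NA_character_)
  }
  aligned
}

cox1_raw <- efetch(cox1_acc, file.path(out_dir, "cox1_raw.fasta"))
its2_raw <- efetch(its2_acc, file.path(out_dir, "its2_raw.fasta"))
cox1_aln <- align(cox1_raw, file.path(out_dir, "cox1_aligned.fasta"))
its2_aln <- align(its2_raw, file.path(out_dir, "its2_aligned.fasta"))

if (!is.na(cox1_aln)) {
  print(verify_published_anchors(cox1_aln,
                                 if (!is.na(its2_aln)) its2_aln else NULL))
}
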