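#!/usr/bin/env Rscript
# Optional helper (requires network; never run by the test suite or the
# acceptance script): downloads reference FOXP2/FOXP1 ortholog sequences
# from UniProt and runs the repeat caller on them. The human references
# are expected to yield FOXP2 Q1=40, Q2=10 (ratio 4.0) and FOXP1 Q1=6,
# Q2=7.
#
# Usage: Rscript scripts/fetch_orthologs.R [outdir]

suppressPackageStartupMessages(library(polyqvoc))

outdir <- commandArgs(trailingOnly = TRUE)[1]
if (is.na(outdir)) outdir <- "scratch/orthologs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

accessions <- list(
  FOXP2 = c(Homo_sapiens = "O15409"),
  FOXP1 = c(Homo_sapiens = "Q9H334")
)

for (gene in names(accessions)) {
  for (sp in names(accessions[[gene]])) {
    acc <- accessions[[gene]][[sp]]
    url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc)
    dest <- file.path(outdir, sprintf("%s_%s.fasta", gene, acc))
    message(sprintf("fetching %s (%s %s)", acc, gene, sp))
    utils::download.file(url, dest, quiet = TRUE)
    rec <- read_fasta(dest, gene = gene)[[1L]]
    cl <- call_repeats(rec, hinge_config(gene))
    print(cl)
  }
}
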