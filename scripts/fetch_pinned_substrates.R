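#!/usr/bin/env Rscript
# One-time download of the pinned reference substrates (requires network):
# sequences for UniProt P35555 (FBN1, entry version 4), P35556 (FBN2,
# version 3) and Q14766 (LTBP1, version 4) via the UniSave archive, plus
# each entry's current EGF-domain feature table. Output goes to
# inst/extdata/pinned/ (or a directory given as the first argument) where
# load_pinned_substrates() will find it.

suppressPackageStartupMessages(library(jsonlite))

args <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(args)) args[1] else
  file.path("inst", "extdata", "pinned")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

pins <- data.frame(
  accession = c("P35555", "P35556", "Q14766"),
  version = c(4L, 3L, 4L))

for (i in seq_len(nrow(pins))) {
  acc <- pins$accession[i]
  # pinned sequence version from the UniProt version archive
  fasta_url <- sprintf(
    "https://rest.uniprot.org/unisave/%s?format=fasta&versions=%d",
    acc, pins$version[i])
  fasta_path <- file.path(out_dir, paste0(acc, ".fasta"))
  download.file(fasta_url, fasta_path, quiet = TRUE)

  # EGF-domain features from the current entry (UniProt does not archive
  # feature tables per sequence version)
  entry <- fromJSON(sprintf("https://rest.uniprot.org/uniprotkb/%s.json",
                            acc), simplifyVector = FALSE)
  rows <- Filter(function(f) {
    f$type == "Domain" && grepl("EGF", f$description %||% "")
  }, entry$features)
  tab <- do.call(rbind, lapply(rows, function(f) {
    data.frame(accession = acc,
               start = f$location$start$value,
               end = f$location$end$value,
               type = f$description, stringsAsFactors = FALSE)
  }))
  write.table(tab, file.path(out_dir, paste0(acc, "_features.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(acc, ": sequence + ", nrow(tab), " EGF feature rows\n", sep = "")
}
cat("wrote pinned substrate files to ", out_dir, "\n", sep = "")
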