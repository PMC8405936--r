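# The three pinned reference substrates: human fibrillin-1 (FBN1, UniProt
# P35555), fibrillin-2 (FBN2, P35556) and LTBP1 (Q14766). Their sequences
# and EGF-domain feature tables are not shipped with the package; they are
# fetched once with scripts/fetch_pinned_substrates.R and then loaded from
# disk for the reference-scale checks.

#' Pinned reference substrates
#'
#' Accessions and expected on-disk filenames for the three reference
#' substrates used in the consensus-prediction checks.
#'
#' @return Data frame with columns `accession`, `name`, `fasta`, `features`.
#' @export
pinned_substrate_info <- function() {
  data.frame(
    accession = c("P35555", "P35556", "Q14766"),
    name = c("FBN1_HUMAN", "FBN2_HUMAN", "LTBP1_HUMAN"),
    fasta = c("P35555.fasta", "P35556.fasta", "Q14766.fasta"),
    features = c("P35555_features.tsv", "P35556_features.tsv",
                 "Q14766_features.tsv"),
    stringsAsFactors = FALSE)
}

#' Locate the pinned-substrate data directory
#'
#' Looks for the downloaded reference files first in `dir` (if given), then
#' in the package's `extdata/pinned` directory.
#'
#' @param dir Optional explicit directory.
#' @return The directory path, or `NA_character_` if the files are absent.
#' @export
pinned_substrate_dir <- function(dir = NULL) {
  info <- pinned_substrate_info()
  candidates <- c(dir, system.file("extdata", "pinned", package = "egfoglc"))
  for (d in candidates) {
    if (!is.null(d) && nzchar(d) &&
        all(file.exists(file.path(d, info$fasta)))) {
      return(d)
    }
  }
  NA_character_
}

#' Load the pinned reference substrates
#'
#' Reads the downloaded FASTA and EGF feature tables for FBN1, FBN2 and
#' LTBP1. Errors with a pointer to the fetch script when the files are not
#' present (they require a one-time download).
#'
#' @param dir Optional directory holding the files; see
#'   [pinned_substrate_dir].
#' @return List with `records` (named list of [protein_record]) and
#'   `repeats` (combined annotated EGF-repeat table).
#' @export
load_pinned_substrates <- function(dir = NULL) {
  d <- pinned_substrate_dir(dir)
  if (is.na(d)) {
    stop("pinned substrate files not found; run ",
         "scripts/fetch_pinned_substrates.R (requires network access) ",
         "and pass its output directory, or place the files under ",
         "inst/extdata/pinned/")
  }
  info <- pinned_substrate_info()
  records <- list()
  repeats <- list()
  for (i in seq_len(nrow(info))) {
    rec <- read_fasta(file.path(d, info$fasta[i]))[[1]]
    records[[rec$accession]] <- rec
    fpath <- file.path(d, info$features[i])
    if (file.exists(fpath)) {
      repeats[[rec$accession]] <- read_domain_features(rec, fpath)
    }
  }
  list(records = records,
       repeats = if (length(repeats))
         do.call(rbind, c(unname(repeats), list(make.row.names = FALSE)))
       else NULL)
}
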