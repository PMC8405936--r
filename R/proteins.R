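# Protein records and FASTA input.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a protein record
#'
#' A protein record is the basic sequence container used throughout the
#' package: an accession, a display name, and an amino-acid sequence in
#' 1-based residue coordinates.
#'
#' @param accession Accession string (e.g. a UniProt accession).
#' @param name Display name; defaults to the accession.
#' @param sequence Amino-acid sequence restricted to the 20 standard residues.
#' @return An object of class `protein_record` with fields `accession`,
#'   `name` and `sequence`.
#' @examples
#' protein_record("P1", sequence = "MACDEF")
#' @export
protein_record <- function(accession, name = accession, sequence) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[ \t\r\n]", "", sequence))
  if (!nzchar(sequence)) {
    stop("protein '", accession, "': sequence is empty")
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), .AA20)
  if (length(bad)) {
    stop("protein '", accession, "': non-standard residue(s) ",
         paste(sQuote(bad), collapse = ", "),
         "; only the 20 standard amino acids are accepted")
  }
  structure(list(accession = accession, name = name, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$accession, " (", x$name, "), ",
      nchar(x$sequence), " aa\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Accepts both the UniProt `sp|ACC|NAME` header dialect and bare-identifier
#' headers; the accession is the second pipe-delimited field when present,
#' otherwise the first whitespace-delimited token. Sequences are uppercased
#' and validated against the 20-residue standard alphabet.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named list of [protein_record] objects, in file order, named by
#'   accession.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path)
  recs <- lapply(seq_along(aa), function(i) {
    header <- names(aa)[i]
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(fields) >= 3L && fields[1] %in% c("sp", "tr")) {
      acc <- fields[2]
      nam <- strsplit(fields[3], "[ \t]")[[1]][1]
    } else {
      acc <- strsplit(header, "[ \t]")[[1]][1]
      nam <- acc
    }
    protein_record(acc, nam, as.character(aa[[i]]))
  })
  names(recs) <- vapply(recs, `[[`, "", "accession")
  recs
}

#' Write protein records to a FASTA file
#'
#' @param records A list of [protein_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (identical(r$accession, r$name)) r$accession
    else paste0("sp|", r$accession, "|", r$name)
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# residue at a 1-based position (internal)
.residue_at <- function(record, pos) substring(record$sequence, pos, pos)
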