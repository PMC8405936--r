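# Consensus-sequence site prediction for POGLUT2/3 O-glucosylation and
# beta-hydroxylation, proteome scanning, and point mutagenesis.
#
# Consensus numbering: C3 = position 1, the 8 residues of the canonical
# inter-C3-C4 segment = positions 2..9, C4 = position 10. The glucosylated
# serine sits at consensus position 7; the beta-hydroxylated Asn/Asp at
# position 3.

#' Construct a consensus pattern
#'
#' A pattern constrains selected consensus positions (2..9) of the
#' inter-C3-C4 segment to allowed residue sets, and names the consensus
#' position of the acceptor residue.
#'
#' @param name Pattern name.
#' @param constraints Named list: consensus position (as character) ->
#'   character vector of allowed residues.
#' @param modified_pos Consensus position of the acceptor residue.
#' @param length Required inter-C3-C4 segment length (8 for all built-ins).
#' @return An object of class `consensus_pattern`.
#' @export
consensus_pattern <- function(name, constraints, modified_pos, length = 8L) {
  stopifnot(is.list(constraints), length(constraints) >= 1L)
  pos <- as.integer(names(constraints))
  if (any(is.na(pos)) || any(pos < 2L) || any(pos > length + 1L)) {
    stop("constrained positions must be consensus positions in [2, ",
         length + 1L, "]")
  }
  structure(list(name = name,
                 constraints = lapply(constraints, toupper),
                 modified_pos = as.integer(modified_pos),
                 length = as.integer(length)),
            class = "consensus_pattern")
}

#' Built-in consensus patterns
#'
#' Returns the four search patterns used for site prediction, all requiring
#' an 8-residue inter-C3-C4 segment:
#' \describe{
#'   \item{original}{C3-x-N-T-x-G-S-F-x-C4, acceptor S at position 7.}
#'   \item{revised}{as original but allowing Y as well as F at position 8.}
#'   \item{broad}{only S at position 7 (the permissive search string; matches
#'     everything the other glucosylation patterns match, plus sites that may
#'     not be modified).}
#'   \item{beta_hydroxylation}{N or D at position 3 and F or Y at position 8;
#'     acceptor N/D at position 3.}
#' }
#'
#' Threonine is not accepted at position 7 by default: T acceptors are used
#' only at very low stoichiometry and serine is strongly preferred. Set
#' `allow_thr7 = TRUE` for exploratory scans that admit T at position 7 in
#' the glucosylation patterns.
#'
#' @param allow_thr7 Also allow threonine at consensus position 7 of the
#'   glucosylation patterns.
#' @return Named list of [consensus_pattern] objects.
#' @export
builtin_patterns <- function(allow_thr7 = FALSE) {
  s7 <- if (allow_thr7) c("S", "T") else "S"
  list(
    original = consensus_pattern("original",
      list("3" = "N", "4" = "T", "6" = "G", "7" = s7, "8" = "F"),
      modified_pos = 7L),
    revised = consensus_pattern("revised",
      list("3" = "N", "4" = "T", "6" = "G", "7" = s7, "8" = c("F", "Y")),
      modified_pos = 7L),
    broad = consensus_pattern("broad",
      list("7" = s7),
      modified_pos = 7L),
    beta_hydroxylation = consensus_pattern("beta_hydroxylation",
      list("3" = c("N", "D"), "8" = c("F", "Y")),
      modified_pos = 3L)
  )
}

#' Match a consensus pattern against an inter-C3-C4 segment
#'
#' A segment matches iff its length equals the pattern's required length and
#' every constrained consensus position holds an allowed residue. Consensus
#' position p corresponds to segment index p - 1.
#'
#' @param segment The exact inter-C3-C4 residue string.
#' @param pattern A [consensus_pattern].
#' @return The acceptor's index within the segment (an integer), or `NA` if
#'   the segment does not match.
#' @export
match_consensus <- function(segment, pattern) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  if (nchar(segment) != pattern$length) return(NA_integer_)
  chars <- strsplit(toupper(segment), "")[[1]]
  for (p in names(pattern$constraints)) {
    idx <- as.integer(p) - 1L
    if (!(chars[idx] %in% pattern$constraints[[p]])) return(NA_integer_)
  }
  pattern$modified_pos - 1L
}

.empty_sites <- function() {
  data.frame(accession = character(), ordinal = integer(),
             position = integer(), residue = character(),
             pattern = character(), segment = character(),
             stringsAsFactors = FALSE)
}

#' Predict modification sites on one protein
#'
#' Applies a consensus pattern to the inter-C3-C4 segment of every EGF
#' repeat. Repeats whose segment is not the pattern's required length are
#' not evaluable and are reported in the `not_evaluable` attribute rather
#' than force-fit.
#'
#' @param record A [protein_record].
#' @param repeats EGF-repeat data frame for that record (annotated or
#'   detected).
#' @param pattern A [consensus_pattern].
#' @return Data frame of predicted sites (`accession`, `ordinal`, `position`
#'   (absolute acceptor position), `residue`, `pattern`, `segment`), ordered
#'   by ordinal, with attribute `not_evaluable` listing skipped ordinals.
#' @export
scan_protein <- function(record, repeats, pattern) {
  stopifnot(inherits(record, "protein_record"))
  if (nrow(repeats) && !all(repeats$accession == record$accession)) {
    stop("repeats do not belong to record ", record$accession)
  }
  out <- .empty_sites()
  skipped <- integer(0)
  for (k in seq_len(nrow(repeats))) {
    seg <- inter_cysteine_segment(repeats[k, ], record)$segment
    if (nchar(seg) != pattern$length) {
      skipped <- c(skipped, repeats$ordinal[k])
      next
    }
    idx <- match_consensus(seg, pattern)
    if (is.na(idx)) next
    pos <- repeats$c3[k] + idx
    out <- rbind(out, data.frame(
      accession = record$accession, ordinal = repeats$ordinal[k],
      position = pos, residue = .residue_at(record, pos),
      pattern = pattern$name, segment = seg, stringsAsFactors = FALSE))
  }
  out <- out[order(out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "not_evaluable") <- skipped
  out
}

#' Scan a set of proteins for predicted sites
#'
#' Runs [scan_protein] over a collection of records, taking repeats from a
#' supplied table (annotated mode) or from [detect_egf_repeats] (detected
#' mode), and summarises the totals.
#'
#' @param records List of [protein_record] objects.
#' @param pattern A [consensus_pattern].
#' @param repeats Optional EGF-repeat data frame covering all records; if
#'   `NULL`, repeats are detected with `config`.
#' @param config [spacing_config] for detection mode.
#' @return A list of class `proteome_scan` with `n_proteins`,
#'   `n_proteins_with_sites`, `n_sites`, `sites` (combined site table),
#'   and `mode` ("annotated" or "detected").
#' @export
scan_proteome <- function(records, pattern, repeats = NULL,
                          config = spacing_config()) {
  if (inherits(records, "protein_record")) records <- list(records)
  mode <- if (is.null(repeats)) "detected" else "annotated"
  per <- lapply(records, function(rec) {
    reps <- if (is.null(repeats)) detect_egf_repeats(rec, config)
            else repeats[repeats$accession == rec$accession, , drop = FALSE]
    scan_protein(rec, reps, pattern)
  })
  sites <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  if (is.null(sites)) sites <- .empty_sites()
  structure(list(
    n_proteins = length(records),
    n_proteins_with_sites = sum(vapply(per, nrow, 0L) > 0L),
    n_sites = nrow(sites),
    sites = sites,
    mode = mode), class = "proteome_scan")
}

#' @export
print.proteome_scan <- function(x, ...) {
  cat("<proteome_scan> ", x$n_proteins, " proteins scanned (", x$mode,
      " repeats): ", x$n_proteins_with_sites, " with >=1 site, ",
      x$n_sites, " predicted sites total\n", sep = "")
  invisible(x)
}

#' Parse point-mutation notation
#'
#' Parses mutations written in the usual protein notation, e.g. `"L744T"`:
#' reference residue, absolute 1-based position, replacement residue.
#'
#' @param x Character vector of mutation strings.
#' @return Data frame with columns `ref`, `position`, `new`.
#' @export
parse_mutations <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed mutation string(s): ",
                     paste(x[bad], collapse = ", "))
  data.frame(ref = toupper(vapply(m, `[`, "", 2L)),
             position = as.integer(vapply(m, `[`, "", 3L)),
             new = toupper(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Apply point mutations to a protein record
#'
#' Each mutation's reference residue is checked against the sequence; a
#' mismatch is an error naming the position and the expected and found
#' residues. The input record is not modified; the returned record's name is
#' suffixed with the mutation string(s).
#'
#' @param record A [protein_record].
#' @param mutations Character vector of mutation strings (e.g.
#'   `c("L744T", "T747S")`) or a data frame from [parse_mutations].
#' @return A new [protein_record] with the substitutions applied.
#' @export
apply_point_mutations <- function(record, mutations) {
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  stopifnot(all(c("ref", "position", "new") %in% names(mutations)))
  chars <- strsplit(record$sequence, "")[[1]]
  for (k in seq_len(nrow(mutations))) {
    p <- mutations$position[k]
    if (p < 1L || p > length(chars)) {
      stop("mutation position ", p, " outside sequence of ",
           record$accession, " (length ", length(chars), ")")
    }
    if (chars[p] != mutations$ref[k]) {
      stop("reference mismatch at position ", p, ": expected ",
           mutations$ref[k], ", found ", chars[p])
    }
    chars[p] <- mutations$new[k]
  }
  tag <- paste0(mutations$ref, mutations$position, mutations$new,
                collapse = "/")
  protein_record(record$accession,
                 paste0(record$name, "_", tag),
                 paste(chars, collapse = ""))
}

#' Write predicted sites as TSV
#'
#' @param sites Site data frame from [scan_protein] or
#'   `scan_proteome(...)$sites`.
#' @param path Output path.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
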