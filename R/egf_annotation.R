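# EGF-repeat annotation: feature-table import, cysteine-spacing detection,
# and the inter-C3-C4 consensus numbering frame.
#
# An EGF repeat is represented as one row of a data frame with columns
# accession, ordinal, start, end, c1..c6, source. Coordinates are 1-based
# inclusive; c1..c6 are the absolute positions of the six conserved
# cysteines; source is "annotated" (feature table) or "detected"
# (spacing scan).

#' Cysteine-spacing configuration for EGF detection
#'
#' Defines the allowed residue counts strictly between consecutive conserved
#' cysteines of an EGF repeat. The defaults cover the calcium-binding EGF
#' architecture that dominates fibrillins and LTBPs (C1-C2 3-14, C2-C3 3-12,
#' C3-C4 1-16, C4-C5 1-3, C5-C6 4-23 residues).
#'
#' @param gaps A list of five length-2 integer vectors, `min`/`max` residues
#'   between cysteine pairs (C1-C2, C2-C3, C3-C4, C4-C5, C5-C6).
#' @return An object of class `spacing_config`.
#' @export
spacing_config <- function(gaps = list(c(3L, 14L), c(3L, 12L), c(1L, 16L),
                                       c(1L, 3L), c(4L, 23L))) {
  stopifnot(is.list(gaps), length(gaps) == 5L)
  for (g in gaps) {
    stopifnot(length(g) == 2L, g[1] >= 0, g[1] <= g[2])
  }
  gaps <- lapply(gaps, as.integer)
  names(gaps) <- c("c1_c2", "c2_c3", "c3_c4", "c4_c5", "c5_c6")
  structure(list(gaps = gaps,
                 min_length = sum(vapply(gaps, `[`, 0L, 1L)) + 6L,
                 max_length = sum(vapply(gaps, `[`, 0L, 2L)) + 6L),
            class = "spacing_config")
}

.empty_repeats <- function() {
  data.frame(accession = character(), ordinal = integer(),
             start = integer(), end = integer(),
             c1 = integer(), c2 = integer(), c3 = integer(),
             c4 = integer(), c5 = integer(), c6 = integer(),
             source = character(), stringsAsFactors = FALSE)
}

.validate_repeats <- function(repeats, record) {
  if (nrow(repeats) == 0L) return(invisible(repeats))
  cys <- as.matrix(repeats[, paste0("c", 1:6)])
  if (any(t(apply(cys, 1L, diff)) <= 0L)) {
    stop("cysteine positions must be strictly increasing within each repeat")
  }
  if (any(repeats$start > repeats$c1) || any(repeats$c6 > repeats$end)) {
    stop("cysteines must lie within [start, end]")
  }
  res <- matrix(substring(record$sequence, cys, cys), nrow = nrow(cys))
  if (!all(res == "C")) {
    stop("record ", record$accession,
         ": residue at an annotated cysteine position is not 'C'")
  }
  invisible(repeats)
}

#' Import EGF repeats from a domain feature table
#'
#' Reads a tab-separated table with header columns
#' `accession`, `start`, `end`, `type` (1-based inclusive coordinates, as in
#' UniProt feature exports), keeps rows whose type contains "EGF" and whose
#' accession matches `record`, and assigns the six conserved cysteines to the
#' first six cysteine residues inside each span.
#'
#' @param record A [protein_record].
#' @param table_path Path to the TSV feature table.
#' @return A data frame of EGF repeats (columns `accession`, `ordinal`,
#'   `start`, `end`, `c1`..`c6`, `source = "annotated"`), ordered by start
#'   with ordinals 1..n.
#' @export
read_domain_features <- function(record, table_path) {
  if (!file.exists(table_path)) stop("feature table not found: ", table_path)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("accession", "start", "end", "type")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[tab$accession == record$accession & grepl("EGF", tab$type), ,
             drop = FALSE]
  if (nrow(tab) == 0L) return(.empty_repeats())
  tab <- tab[order(tab$start), , drop = FALSE]
  n <- nchar(record$sequence)
  cys_all <- .cysteine_positions(record$sequence)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    s <- as.integer(tab$start[i]); e <- as.integer(tab$end[i])
    if (s < 1L || e > n || s > e) {
      stop("feature row ", i, " (", s, "-", e, ") lies outside sequence of ",
           record$accession, " (length ", n, ")")
    }
    cys <- cys_all[cys_all >= s & cys_all <= e]
    if (length(cys) < 6L) {
      stop("feature row ", i, " (", s, "-", e, ") of ", record$accession,
           " contains only ", length(cys), " cysteines; 6 required")
    }
    c(s, e, cys[1:6])
  })
  m <- do.call(rbind, rows)
  out <- data.frame(accession = record$accession,
                    ordinal = seq_len(nrow(m)),
                    start = m[, 1], end = m[, 2],
                    c1 = m[, 3], c2 = m[, 4], c3 = m[, 5],
                    c4 = m[, 6], c5 = m[, 7], c6 = m[, 8],
                    source = "annotated", stringsAsFactors = FALSE)
  .validate_repeats(out, record)
  out
}

.cysteine_positions <- function(sequence) {
  which(strsplit(sequence, "")[[1]] == "C")
}

#' Detect EGF repeats by cysteine spacing
#'
#' Scans the sequence N- to C-terminal for non-overlapping six-cysteine
#' matches whose four inter-cysteine gaps satisfy the spacing configuration.
#' Matching is greedy left-to-right with shortest-match tie-breaking: at each
#' candidate C1, the lexicographically smallest valid (c2..c6) combination is
#' taken, and scanning resumes after its C6.
#'
#' @param record A [protein_record].
#' @param config A [spacing_config]; the default accepts canonical
#'   calcium-binding EGF spacings.
#' @return A data frame of EGF repeats with `source = "detected"`; zero rows
#'   if no match.
#' @export
detect_egf_repeats <- function(record, config = spacing_config()) {
  stopifnot(inherits(record, "protein_record"),
            inherits(config, "spacing_config"))
  cys <- .cysteine_positions(record$sequence)
  gaps <- config$gaps
  hits <- list()
  i <- 1L
  while (i <= length(cys) - 5L) {
    hit <- .match_from(cys, i, gaps)
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      hits[[length(hits) + 1L]] <- hit
      # non-overlapping: resume after this repeat's C6
      i <- match(hit[6L], cys) + 1L
    }
  }
  if (!length(hits)) return(.empty_repeats())
  m <- do.call(rbind, hits)
  out <- data.frame(accession = record$accession,
                    ordinal = seq_len(nrow(m)),
                    start = m[, 1], end = m[, 6],
                    c1 = m[, 1], c2 = m[, 2], c3 = m[, 3],
                    c4 = m[, 4], c5 = m[, 5], c6 = m[, 6],
                    source = "detected", stringsAsFactors = FALSE)
  .validate_repeats(out, record)
  out
}

# depth-first search for the smallest valid c2..c6 given c1 = cys[i];
# gap is residues strictly between consecutive cysteines
.match_from <- function(cys, i, gaps) {
  pick <- function(prev, depth) {
    if (depth > 5L) return(integer(0))
    rng <- gaps[[depth]]
    for (p in cys[cys > prev]) {
      gap <- p - prev - 1L
      if (gap > rng[2]) break  # cys sorted: gaps only grow
      if (gap < rng[1]) next
      rest <- pick(p, depth + 1L)
      if (!is.null(rest)) return(c(p, rest))
    }
    NULL
  }
  rest <- pick(cys[i], 1L)
  if (is.null(rest)) NULL else c(cys[i], rest)
}

#' Inter-cysteine segment and consensus numbering
#'
#' Extracts the residues strictly between cysteines 3 and 4 of an EGF repeat
#' and the consensus numbering used for modification-site positions: C3 is
#' consensus position 1, the segment residues are positions 2..(L+1), and C4
#' is position L+2. For the canonical 8-residue segment, C4 is position 10
#' and the acceptor serine of the glucosylation consensus sits at position 7.
#'
#' @param egf A single EGF-repeat row (data frame with one row, or a list
#'   with `c3`/`c4`).
#' @param record The [protein_record] the repeat belongs to.
#' @return A list with `segment` (string, possibly empty) and `numbering`
#'   (integer vector of consensus positions named by absolute position,
#'   covering C3..C4).
#' @export
inter_cysteine_segment <- function(egf, record) {
  c3 <- as.integer(egf$c3); c4 <- as.integer(egf$c4)
  stopifnot(length(c3) == 1L, length(c4) == 1L, c3 < c4)
  if (.residue_at(record, c3) != "C" || .residue_at(record, c4) != "C") {
    stop("positions c3/c4 of the repeat are not cysteines in ",
         record$accession)
  }
  segment <- if (c4 == c3 + 1L) "" else
    substring(record$sequence, c3 + 1L, c4 - 1L)
  numbering <- seq_len(c4 - c3 + 1L)
  names(numbering) <- as.character(c3:c4)
  list(segment = segment, numbering = numbering)
}

#' Write / read EGF repeats as TSV
#'
#' @param repeats An EGF-repeat data frame.
#' @param path Output path.
#' @return `path` (writer) or the repeats data frame (reader).
#' @export
write_repeats_tsv <- function(repeats, path) {
  utils::write.table(repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_repeats_tsv
#' @export
read_repeats_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
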