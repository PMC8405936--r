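# Shared fixtures, built in code.

# a protein with two hand-placed EGF scaffolds whose cysteine positions are
# known by construction; segments are the canonical 8-residue loop
fixture_two_egf_record <- function() {
  egf1 <- paste0("C", "ADGH", "C", "EFGQ", "C", "ANTAGSFA", "C", "QD",
                 "C", "LMNQA", "C")                       # original match
  egf2 <- paste0("C", "HILMA", "C", "DEFG", "C", "VNTYGSYE", "C", "AD",
                 "C", "EFGHI", "C")                       # revised-only
  seq <- paste0("MAGKDVR", egf1, "AGKEVR", egf2, "AGKDVR")
  rec <- protein_record("FIX01", sequence = seq)
  list(record = rec,
       egf1_start = 8L,   # first C of egf1
       segments = c("ANTAGSFA", "VNTYGSYE"))
}

# write a features TSV for a record given repeat spans
write_features_fixture <- function(accession, spans, path,
                                   type = "EGF-like") {
  df <- data.frame(accession = accession,
                   start = vapply(spans, `[`, 0L, 1L),
                   end = vapply(spans, `[`, 0L, 2L),
                   type = type)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force digest oracle: enumerate all subsets of <= max_missed skipped
# cut sites between each start/end fragment pair (independent of digest())
oracle_digest_spans <- function(sequence, residues, max_missed,
                                proline_rule = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cuts <- which(chars %in% residues)
  cuts <- cuts[cuts < n]
  if (proline_rule) cuts <- cuts[chars[cuts + 1L] != "P"]
  bounds <- c(0L, cuts, n)
  spans <- list()
  for (i in seq_along(bounds)[-length(bounds)]) {
    for (j in (i + 1):length(bounds)) {
      missed <- j - i - 1L
      if (missed > max_missed) break
      spans[[length(spans) + 1L]] <-
        c(bounds[i] + 1L, bounds[j], missed)
    }
  }
  m <- unique(do.call(rbind, spans))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# random inter-C3-C4 segment of given length
random_segment <- function(len = 8L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# small study manifest reused across tests (kept small for speed)
fixture_manifest <- function(seed = 42L, ...) {
  synthetic_manifest(n_proteins = 2L, egfs_per_protein = 3L, seed = seed,
                     replicates = 2L, ...)
}
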