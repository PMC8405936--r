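# In-silico protease digestion, peptide-to-site assignment, and theoretical
# monoisotopic mass / m/z computation for the four glycoforms.
#
# All masses are monoisotopic, computed from elemental compositions so the
# modification deltas are exact consequences of atomic masses rather than
# transcribed constants.

# monoisotopic atomic masses (Da), CODATA/IUPAC values
.ELEMENT_MASS <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)

# residue (amino-acid minus water) elemental compositions, columns C,H,N,O,S
.RESIDUE_FORMULA <- matrix(c(
  # C   H   N  O  S
    3,  5,  1, 1, 0,  # A
    3,  5,  1, 1, 1,  # C
    4,  5,  1, 3, 0,  # D
    5,  7,  1, 3, 0,  # E
    9,  9,  1, 1, 0,  # F
    2,  3,  1, 1, 0,  # G
    6,  7,  3, 1, 0,  # H
    6, 11,  1, 1, 0,  # I
    6, 12,  2, 1, 0,  # K
    6, 11,  1, 1, 0,  # L
    5,  9,  1, 1, 1,  # M
    4,  6,  2, 2, 0,  # N
    5,  7,  1, 1, 0,  # P
    5,  8,  2, 2, 0,  # Q
    6, 12,  4, 1, 0,  # R
    3,  5,  1, 2, 0,  # S
    4,  7,  1, 2, 0,  # T
    5,  9,  1, 1, 0,  # V
   11, 10,  2, 1, 0,  # W
    9,  9,  1, 2, 0   # Y
), ncol = 5L, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S")))

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Named numeric vector of element counts (elements H, C, N,
#'   O, S), e.g. `c(C = 6, H = 10, O = 5)`. Negative counts are allowed (for
#'   losses).
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 6, H = 10, O = 5))  # hexose delta
#' @export
formula_mass <- function(formula) {
  el <- names(formula)
  if (is.null(el) || !all(el %in% names(.ELEMENT_MASS))) {
    stop("formula must be a named vector over elements ",
         paste(names(.ELEMENT_MASS), collapse = ", "))
  }
  sum(.ELEMENT_MASS[el] * as.numeric(formula))
}

.RESIDUE_MASS <- drop(.RESIDUE_FORMULA %*% .ELEMENT_MASS[colnames(.RESIDUE_FORMULA)])
.WATER <- formula_mass(c(H = 2, O = 1))
.PROTON <- 1.007276466

#' Modification specifications
#'
#' Monoisotopic mass deltas for the modifications used in identification and
#' quantification, each computed from its elemental composition:
#' carbamidomethyl (+C2H3NO at Cys, fixed), oxidation/hydroxylation (+O,
#' variable at M/H/N/D), deamidation (+O -H -N at Asn, variable),
#' ammonia loss (-NH3 at N-terminal Cys, variable), and the O-hexose
#' glycan (+C6H10O5 at Ser).
#'
#' @return Data frame with columns `name`, `delta` (Da), `targets`,
#'   `placement` ("fixed"/"variable"), `terminal` ("none"/"N-term").
#' @export
modification_specs <- function() {
  data.frame(
    name = c("carbamidomethyl", "oxidation", "deamidated", "ammonia_loss",
             "hexose"),
    delta = c(formula_mass(c(C = 2, H = 3, N = 1, O = 1)),
              formula_mass(c(O = 1)),
              formula_mass(c(O = 1, H = -1, N = -1)),
              -formula_mass(c(N = 1, H = 3)),
              formula_mass(c(C = 6, H = 10, O = 5))),
    targets = c("C", "M,H,N,D", "N", "C", "S"),
    placement = c("fixed", "variable", "variable", "variable", "variable"),
    terminal = c("none", "none", "none", "N-term", "none"),
    stringsAsFactors = FALSE)
}

#' Glycoform mass deltas
#'
#' The four glycoforms quantified per site: `UNMOD` (bare peptide), `OH`
#' (beta-hydroxylation, +O), `HEX` (O-hexose), `HEX_OH` (both).
#'
#' @return Named numeric vector of deltas in Da, in fixed glycoform order.
#' @export
glycoform_deltas <- function() {
  oh <- formula_mass(c(O = 1))
  hex <- formula_mass(c(C = 6, H = 10, O = 5))
  c(UNMOD = 0, OH = oh, HEX = hex, HEX_OH = hex + oh)
}

#' Glycoform names in canonical order
#' @return `c("UNMOD", "OH", "HEX", "HEX_OH")`
#' @export
glycoforms <- function() names(glycoform_deltas())

.PROTEASE_RULES <- list(
  trypsin = c("K", "R"),
  v8 = c("E", "D"),
  chymotrypsin = c("Y", "F", "W", "L", "I"))

#' In-silico protease digestion
#'
#' Cleaves C-terminal to the protease's residues (trypsin: K/R; V8: E/D;
#' chymotrypsin: Y/F/W/L/I), optionally suppressing cleavage before proline
#' (the common search-engine default, on by default), and returns all
#' peptides with 0..`max_missed` missed cleavages, deduplicated by span.
#'
#' @param record A [protein_record] (or a bare sequence string).
#' @param protease One of `"trypsin"`, `"v8"`, `"chymotrypsin"`.
#' @param max_missed Maximum missed cleavages (>= 0; default 2).
#' @param proline_rule Suppress cleavage when the next residue is proline.
#' @return Data frame with columns `accession`, `start`, `end`, `sequence`,
#'   `protease`, `missed`, ordered by start then end.
#' @export
digest <- function(record, protease = c("trypsin", "v8", "chymotrypsin"),
                   max_missed = 2L, proline_rule = TRUE) {
  protease <- match.arg(protease)
  if (is.character(record)) record <- protein_record("seq", sequence = record)
  stopifnot(max_missed >= 0L)
  chars <- strsplit(record$sequence, "")[[1]]
  n <- length(chars)
  sites <- which(chars %in% .PROTEASE_RULES[[protease]])
  sites <- sites[sites < n]
  if (proline_rule) sites <- sites[chars[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)            # cut after these positions
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  rows <- list()
  nfrag <- length(starts)
  for (i in seq_len(nfrag)) {
    for (m in 0:min(max_missed, nfrag - i)) {
      rows[[length(rows) + 1L]] <-
        c(starts[i], ends[i + m], m)
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(accession = record$accession,
                    start = m[, 1], end = m[, 2],
                    sequence = substring(record$sequence, m[, 1], m[, 2]),
                    protease = protease, missed = m[, 3],
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$start, out$end), ])
  rownames(out) <- NULL
  out
}

#' Assign one peptide per predicted site
#'
#' For each predicted site, chooses the covering peptide with the fewest
#' missed cleavages; ties are broken by shortest length, then N-terminal-most
#' start. Sites with no covering peptide (within the length cap) are
#' reported as uncovered -- the sites whose glycosylation status cannot be
#' read out from the digest.
#'
#' @param peptides Peptide data frame from [digest].
#' @param sites Site data frame from [scan_protein].
#' @param max_length Maximum peptide length considered quantifiable
#'   (default 50 residues).
#' @return The site table with added columns `pep_start`, `pep_end`,
#'   `peptide`, `missed`, `covered` (logical); uncovered sites have `NA`
#'   peptide fields.
#' @export
assign_peptides_to_sites <- function(peptides, sites, max_length = 50L) {
  pep <- peptides[nchar(peptides$sequence) <= max_length, , drop = FALSE]
  out <- sites
  out$pep_start <- NA_integer_; out$pep_end <- NA_integer_
  out$peptide <- NA_character_; out$missed <- NA_integer_
  out$covered <- FALSE
  for (k in seq_len(nrow(sites))) {
    cand <- pep[pep$accession == sites$accession[k] &
                pep$start <= sites$position[k] &
                pep$end >= sites$position[k], , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand$missed, cand$end - cand$start, cand$start), ,
                 drop = FALSE]
    out$pep_start[k] <- cand$start[1]; out$pep_end[k] <- cand$end[1]
    out$peptide[k] <- cand$sequence[1]; out$missed[k] <- cand$missed[1]
    out$covered[k] <- TRUE
  }
  out
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus any applied
#' modification deltas. With `carbamidomethyl = TRUE` (the default, matching
#' standard reduced/alkylated sample prep) the fixed +57.021464 Da is applied
#' to every cysteine.
#'
#' @param sequence Peptide sequence (standard 20-residue alphabet).
#' @param carbamidomethyl Apply fixed carbamidomethylation at Cys.
#' @param extra_delta Additional summed modification delta in Da.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_neutral_mass <- function(sequence, carbamidomethyl = TRUE,
                                 extra_delta = 0) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0L) stop("empty peptide sequence")
  bad <- setdiff(unique(chars), rownames(.RESIDUE_FORMULA))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  mass <- sum(.RESIDUE_MASS[chars]) + .WATER + extra_delta
  if (carbamidomethyl) {
    mass <- mass + sum(chars == "C") * modification_specs()$delta[1]
  }
  mass
}

#' m/z of a neutral mass at a charge state
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge.
#' @return (M + z * 1.007276466) / z, in Th.
#' @export
mz_for_charge <- function(neutral_mass, charge) {
  if (any(charge < 1L)) stop("charge must be >= 1")
  (neutral_mass + charge * .PROTON) / charge
}

#' Theoretical glycoform masses and m/z values for assigned sites
#'
#' For every covered site, emits the four glycoforms (UNMOD, OH, HEX,
#' HEX_OH) at each configured charge. Beta-hydroxylation is placed on the
#' consensus-position-3 Asn/Asp of the same EGF (absolute position c3 + 2);
#' when the chosen peptide does not cover an N/D at that position, the OH
#' forms are suppressed for that site and `oh_enabled` is `FALSE`.
#'
#' Peptides whose UNMOD m/z falls below `scan_range[1]` at every configured
#' charge are flagged `quantifiable = FALSE`: their unmodified form cannot
#' be observed, so a relative stoichiometry cannot be computed.
#'
#' @param assignments Output of [assign_peptides_to_sites] (must carry the
#'   repeat `c3` positions via `repeats`).
#' @param repeats EGF-repeat data frame used for the site scan.
#' @param records Named list of [protein_record] objects.
#' @param charges Integer charge states to emit (default `c(2, 3, 4)`).
#' @param scan_range MS1 scan m/z range (default `c(350, 2000)`).
#' @return Data frame with one row per site x glycoform x charge: `site_id`
#'   (`accession:EGF<ordinal>`), site and peptide columns, `glycoform`,
#'   `charge`, `neutral_mass`, `mz`, `oh_enabled`, `charge_in_range`
#'   (every glycoform of the site visible at this charge), `quantifiable`.
#' @export
glycoform_table <- function(assignments, repeats, records,
                            charges = c(2L, 3L, 4L),
                            scan_range = c(350, 2000)) {
  if (inherits(records, "protein_record")) records <- list(records)
  names(records) <- vapply(records, `[[`, "", "accession")
  deltas <- glycoform_deltas()
  rows <- list()
  cov <- assignments[assignments$covered, , drop = FALSE]
  for (k in seq_len(nrow(cov))) {
    acc <- cov$accession[k]
    rec <- records[[acc]]
    rep_row <- repeats[repeats$accession == acc &
                       repeats$ordinal == cov$ordinal[k], , drop = FALSE]
    oh_pos <- rep_row$c3[1] + 2L  # consensus position 3
    oh_res <- .residue_at(rec, oh_pos)
    oh_enabled <- oh_pos >= cov$pep_start[k] && oh_pos <= cov$pep_end[k] &&
      oh_res %in% c("N", "D")
    base <- peptide_neutral_mass(cov$peptide[k])
    forms <- if (oh_enabled) glycoforms() else c("UNMOD", "HEX")
    # a charge state is usable only when every glycoform of the site falls
    # inside the scan range; partial visibility would bias the fractions
    charge_ok <- vapply(charges, function(z) {
      mzs <- mz_for_charge(base + unname(deltas[forms]), z)
      all(mzs >= scan_range[1] & mzs <= scan_range[2])
    }, logical(1L))
    quantifiable <- any(charge_ok)
    for (g in forms) {
      for (zi in seq_along(charges)) {
        z <- charges[zi]
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = paste0(acc, ":EGF", cov$ordinal[k]),
          accession = acc, ordinal = cov$ordinal[k],
          position = cov$position[k],
          peptide = cov$peptide[k],
          pep_start = cov$pep_start[k], pep_end = cov$pep_end[k],
          glycoform = g, charge = z,
          neutral_mass = base + deltas[[g]],
          mz = mz_for_charge(base + deltas[[g]], z),
          oh_enabled = oh_enabled, charge_in_range = charge_ok[zi],
          quantifiable = quantifiable,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(site_id = character(), accession = character(),
                      ordinal = integer(), position = integer(),
                      peptide = character(), pep_start = integer(),
                      pep_end = integer(), glycoform = character(),
                      charge = integer(), neutral_mass = numeric(),
                      mz = numeric(), oh_enabled = logical(),
                      charge_in_range = logical(),
                      quantifiable = logical(), stringsAsFactors = FALSE)
  }
  out
}
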