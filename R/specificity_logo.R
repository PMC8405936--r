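# Enzyme-specificity calls from knockout comparisons, and
# position-frequency / information-content summaries of modified sites.

#' Classify POGLUT2- vs POGLUT3-preferred sites
#'
#' Compares the glucosylated fraction (HEX + HEX_OH relative abundance) of
#' each site between wild-type and single-knockout conditions. A site is
#' called preferred for an enzyme when its glucosylation drops by at least
#' `threshold` in that enzyme's knockout but not in the other; `redundant`
#' when neither knockout reaches the threshold; `indeterminate` when both
#' do, when the wild-type glucosylation is below `wt_floor`, or when any
#' condition lacks the minimum two replicates.
#'
#' The reduction is computed on the relative scale by default,
#' `(WT - KO) / WT`, so a 30% threshold means losing 30% of the wild-type
#' glucosylation regardless of its absolute level; `mode = "absolute"`
#' instead uses the drop in percentage points, `WT - KO`.
#'
#' @param summaries Output of [aggregate_replicates] containing `WT`,
#'   `P2KO` and `P3KO` rows for the sites of interest.
#' @param threshold Reduction cutoff (default 0.30, chosen to exceed the
#'   typical 10-20% run-to-run variation of label-free MS quantification).
#' @param wt_floor Minimum wild-type glucosylated fraction for a call
#'   (default 0.05); below it relative reductions are numerically unstable.
#' @param mode `"relative"` or `"absolute"` reduction.
#' @return Data frame: `site_id`, `wt`, `p2ko`, `p3ko` (glucosylated
#'   fractions), `reduction_p2ko`, `reduction_p3ko`, `call`, `threshold`,
#'   `mode`.
#' @export
classify_specificity <- function(summaries, threshold = 0.30,
                                 wt_floor = 0.05,
                                 mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  gluc <- summaries$mean_hex + summaries$mean_hex_oh
  key <- split(seq_len(nrow(summaries)), summaries$site_id)
  rows <- lapply(names(key), function(id) {
    idx <- key[[id]]
    cond <- summaries$condition[idx]
    pick <- function(cc) {
      i <- idx[cond == cc]
      if (length(i) == 1L) gluc[i] else NA_real_
    }
    wt <- pick("WT"); p2 <- pick("P2KO"); p3 <- pick("P3KO")
    red <- function(ko) {
      if (is.na(wt) || is.na(ko)) return(NA_real_)
      if (mode == "relative") {
        if (wt <= 0) return(NA_real_)
        (wt - ko) / wt
      } else wt - ko
    }
    r2 <- red(p2); r3 <- red(p3)
    call <- if (is.na(wt) || is.na(p2) || is.na(p3) || wt < wt_floor ||
                is.na(r2) || is.na(r3)) {
      "indeterminate"
    } else if (r2 >= threshold && r3 < threshold) {
      "POGLUT2_preferred"
    } else if (r3 >= threshold && r2 < threshold) {
      "POGLUT3_preferred"
    } else if (r2 >= threshold && r3 >= threshold) {
      "indeterminate"
    } else "redundant"
    data.frame(site_id = id, wt = wt, p2ko = p2, p3ko = p3,
               reduction_p2ko = r2, reduction_p3ko = r3, call = call,
               threshold = threshold, mode = mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(site_id = character(), wt = numeric(),
                      p2ko = numeric(), p3ko = numeric(),
                      reduction_p2ko = numeric(), reduction_p3ko = numeric(),
                      call = character(), threshold = numeric(),
                      mode = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Build a position frequency matrix of modified-site segments
#'
#' Counts residues at consensus positions 2-9 (the 8 residues between
#' cysteines 3 and 4) across a set of modified-site segments, the input for
#' a sequence logo.
#'
#' @param segments Character vector of 8-residue inter-C3-C4 segments.
#' @return Object of class `pfm`: list with `counts` and `freq` (20 x 8
#'   matrices, rows = residues, columns = consensus positions "2".."9") and
#'   `n` (number of sequences).
#' @export
build_pfm <- function(segments) {
  if (!length(segments)) stop("no segments supplied")
  len <- nchar(segments)
  if (any(len != 8L)) {
    stop("all segments must be 8 residues long (got lengths ",
         paste(unique(len), collapse = ", "), ")")
  }
  n <- length(segments)
  counts <- matrix(0L, nrow = 20L, ncol = 8L,
                   dimnames = list(.AA20, as.character(2:9)))
  chars <- do.call(rbind, strsplit(toupper(segments), ""))
  for (j in 1:8) {
    tab <- table(factor(chars[, j], levels = .AA20))
    counts[, j] <- as.integer(tab)
  }
  structure(list(counts = counts, freq = counts / n, n = n), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$n, " segments, consensus positions 2-9\n", sep = "")
  top <- apply(x$freq, 2L, function(col) {
    i <- which.max(col)
    sprintf("%s(%.2f)", rownames(x$freq)[i], col[i])
  })
  cat("  top residues: ", paste(top, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-position information content of a PFM
#'
#' Computes the sequence-logo information content
#' `R(pos) = log2(20) - H(pos) - e_n`, where `H` is the Shannon entropy of
#' the position's residue frequencies and `e_n = 19 / (2 ln(2) n)` is the
#' small-sample correction (applied when `small_sample_correction = TRUE`).
#' Letter heights are `frequency x R(pos)`.
#'
#' @param pfm A [build_pfm] result.
#' @param small_sample_correction Apply the small-sample correction.
#' @return List with `bits` (information content per position, named "2"
#'   .."9") and `heights` (20 x 8 matrix of letter heights).
#' @export
information_content <- function(pfm, small_sample_correction = TRUE) {
  stopifnot(inherits(pfm, "pfm"))
  H <- apply(pfm$freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  en <- if (small_sample_correction) 19 / (2 * log(2) * pfm$n) else 0
  bits <- pmax(log2(20) - H - en, 0)
  heights <- sweep(pfm$freq, 2L, bits, `*`)
  list(bits = bits, heights = heights)
}

#' Write a PFM as a TSV matrix
#'
#' @param pfm A [build_pfm] result.
#' @param path Output path.
#' @param what `"freq"` or `"counts"`.
#' @export
write_pfm_tsv <- function(pfm, path, what = c("freq", "counts")) {
  what <- match.arg(what)
  m <- pfm[[what]]
  utils::write.table(data.frame(residue = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
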