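# Extracted-ion-chromatogram quantification of glycoform stoichiometry.
#
# A spectra run holds centroided MS1 scans as (retention time, m/z array,
# intensity array) triples, retention times in minutes. Relative abundance
# of a glycoform is its area under the curve divided by the summed AUC of
# all searched glycoforms of the same peptide.

#' Construct a spectra run
#'
#' @param run_id Run identifier.
#' @param condition One of `"WT"`, `"P2KO"`, `"P3KO"`, `"DKO"`.
#' @param replicate Replicate index (integer >= 1).
#' @param scans List of MS1 scans, each a list with `rt` (minutes), `mz`
#'   (ascending numeric vector), `intensity` (same length, >= 0).
#' @param mz_range Instrument scan m/z range (default 350-2000).
#' @return Object of class `spectra_run`.
#' @export
spectra_run <- function(run_id, condition = c("WT", "P2KO", "P3KO", "DKO"),
                        replicate = 1L, scans, mz_range = c(350, 2000)) {
  condition <- match.arg(condition)
  rt <- vapply(scans, `[[`, 0, "rt")
  if (length(rt) && any(diff(rt) <= 0)) {
    stop("scan retention times must be strictly increasing")
  }
  for (s in scans) {
    if (length(s$mz) != length(s$intensity)) {
      stop("scan m/z and intensity arrays differ in length")
    }
    if (length(s$mz) > 1L && any(diff(s$mz) < 0)) {
      stop("scan m/z arrays must be sorted ascending")
    }
  }
  structure(list(run_id = run_id, condition = condition,
                 replicate = as.integer(replicate), scans = scans,
                 mz_range = mz_range),
            class = "spectra_run")
}

#' @export
print.spectra_run <- function(x, ...) {
  rt <- vapply(x$scans, `[[`, 0, "rt")
  cat("<spectra_run> ", x$run_id, " [", x$condition, " rep ", x$replicate,
      "]: ", length(x$scans), " MS1 scans, rt ",
      if (length(rt)) paste0(round(min(rt), 2), "-", round(max(rt), 2))
      else "-", " min\n", sep = "")
  invisible(x)
}

#' Read an LC-MS run
#'
#' Reads either a centroided mzML file (MS1 scans only; MS2 scans are
#' ignored; profile-mode spectra are rejected) or the package's simple JSON
#' run dialect written by [write_run_json] (see that help page for the
#' schema).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mzml"`, or `"runjson"`.
#' @return A [spectra_run].
#' @export
read_run <- function(path, format = c("auto", "mzml", "runjson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("run file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "runjson"
  }
  if (format == "runjson") return(.read_run_json(path))
  .read_run_mzml(path)
}

.read_run_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("run_id", "condition", "replicate", "scans")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("run JSON is missing field(s): ", paste(miss, collapse = ", "))
  }
  scans <- lapply(x$scans, function(s) {
    list(rt = as.numeric(s$rt), mz = as.numeric(unlist(s$mz)),
         intensity = as.numeric(unlist(s$intensity)))
  })
  mz_range <- if (!is.null(x$mz_range)) as.numeric(unlist(x$mz_range))
              else c(350, 2000)
  spectra_run(x$run_id, x$condition, x$replicate, scans, mz_range)
}

.read_run_mzml <- function(path) {
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  ms1 <- which(h$msLevel == 1L)
  if (!length(ms1)) stop("mzML contains no MS1 spectra: ", path)
  if (any(!is.na(h$centroided[ms1]) & !h$centroided[ms1])) {
    stop("profile-mode mzML is not supported; centroid the data first: ",
         path)
  }
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(f, i)
    list(rt = h$retentionTime[i] / 60,  # mzR reports seconds
         mz = as.numeric(pk[, 1]), intensity = as.numeric(pk[, 2]))
  })
  ord <- order(vapply(scans, `[[`, 0, "rt"))
  run_id <- sub("\\.mzml$", "", basename(path), ignore.case = TRUE)
  cond <- .parse_condition_from_id(run_id)
  spectra_run(run_id, cond$condition, cond$replicate, scans[ord])
}

# run ids written by the simulator look like "<name>_WT_rep2"
.parse_condition_from_id <- function(run_id) {
  m <- regmatches(run_id,
                  regexec("_(WT|P2KO|P3KO|DKO)_rep([0-9]+)", run_id))[[1]]
  if (length(m) == 3L) list(condition = m[2], replicate = as.integer(m[3]))
  else list(condition = "WT", replicate = 1L)
}

#' Extract an ion chromatogram
#'
#' Per MS1 scan, sums the intensities of all centroids within the symmetric
#' ppm window around the target m/z; scans with no centroid in the window
#' contribute zero, so the trace has one point per scan.
#'
#' @param run A [spectra_run].
#' @param target_mz Target m/z (Th).
#' @param ppm Mass tolerance in parts per million (default 20, the usual
#'   precursor tolerance on a high-resolution instrument).
#' @return Data frame with columns `rt` (minutes) and `intensity`.
#' @export
extract_eic <- function(run, target_mz, ppm = 20) {
  stopifnot(ppm > 0, length(target_mz) == 1L)
  tol <- target_mz * ppm * 1e-6
  intensity <- vapply(run$scans, function(s) {
    sel <- abs(s$mz - target_mz) <= tol
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, 0)
  data.frame(rt = vapply(run$scans, `[[`, 0, "rt"), intensity = intensity)
}

#' Integrate a chromatogram trace
#'
#' Trapezoidal area under the intensity trace over a retention-time window
#' (intensity x minutes). No baseline subtraction is applied.
#'
#' @param trace Data frame from [extract_eic].
#' @param rt_window Optional `c(start, end)` in minutes; default is the full
#'   trace.
#' @return Area under the curve.
#' @export
integrate_auc <- function(trace, rt_window = NULL) {
  rt <- trace$rt; y <- trace$intensity
  if (!is.null(rt_window)) {
    stopifnot(length(rt_window) == 2L, rt_window[1] < rt_window[2])
    sel <- rt >= rt_window[1] & rt <= rt_window[2]
    if (!any(sel)) stop("retention-time window contains no scans")
    rt <- rt[sel]; y <- y[sel]
  }
  if (length(rt) < 2L) return(0)
  pracma::trapz(rt, y)
}

#' Quantify the glycoforms of one site in one run
#'
#' Extracts an ion chromatogram for every glycoform x charge target of the
#' site, sums areas across the configured charge states, and converts to
#' relative abundances (each glycoform's AUC over the summed AUC of all
#' searched glycoforms). When the total AUC is zero the fractions are all
#' zero and `no_signal` is set.
#'
#' A warning is emitted when the deamidated satellite of the unmodified
#' peptide (target + 0.984016/z) carries more than 10% of the UNMOD AUC,
#' since heavy deamidation can bias the four-glycoform total.
#'
#' @param run A [spectra_run].
#' @param site_targets Rows of a [glycoform_table] for a single site.
#' @param ppm Mass tolerance in ppm (default 20).
#' @param rt_window Optional integration window in minutes.
#' @param deamidation_check Emit the deamidation warning (default TRUE).
#' @return One-row data frame: `site_id`, `run_id`, `condition`,
#'   `replicate`, `auc_<glycoform>` x4, `frac_<glycoform>` x4, `no_signal`.
#' @export
quantify_site <- function(run, site_targets, ppm = 20, rt_window = NULL,
                          deamidation_check = TRUE) {
  stopifnot(length(unique(site_targets$site_id)) == 1L)
  forms <- glycoforms()
  auc <- stats::setNames(numeric(4L), forms)
  for (g in unique(site_targets$glycoform)) {
    rows <- site_targets[site_targets$glycoform == g, , drop = FALSE]
    auc[g] <- sum(vapply(seq_len(nrow(rows)), function(i) {
      integrate_auc(extract_eic(run, rows$mz[i], ppm), rt_window)
    }, 0))
  }
  if (deamidation_check && auc["UNMOD"] > 0) {
    deam <- modification_specs()
    deam <- deam$delta[deam$name == "deamidated"]
    un <- site_targets[site_targets$glycoform == "UNMOD", , drop = FALSE]
    deam_auc <- sum(vapply(seq_len(nrow(un)), function(i) {
      integrate_auc(extract_eic(run, un$mz[i] + deam / un$charge[i], ppm),
                    rt_window)
    }, 0))
    if (deam_auc > 0.10 * auc["UNMOD"]) {
      warning("site ", site_targets$site_id[1], " in run ", run$run_id,
              ": deamidated satellite carries ",
              round(100 * deam_auc / auc["UNMOD"]),
              "% of the unmodified AUC")
    }
  }
  total <- sum(auc)
  frac <- if (total > 0) auc / total else auc * 0
  out <- data.frame(site_id = site_targets$site_id[1], run_id = run$run_id,
                    condition = run$condition, replicate = run$replicate,
                    stringsAsFactors = FALSE)
  for (g in forms) out[[paste0("auc_", tolower(g))]] <- unname(auc[g])
  for (g in forms) out[[paste0("frac_", tolower(g))]] <- unname(frac[g])
  out$no_signal <- total <= 0
  out
}

#' Quantify every site of a glycopeptide table in one run
#'
#' @param run A [spectra_run].
#' @param glyco_table A [glycoform_table]; sites flagged
#'   `quantifiable = FALSE` are skipped (their unmodified form is outside
#'   the scan range, so a stoichiometry would be misleading).
#' @param peak_windows Optional data frame (`site_id`, `rt_start`,
#'   `rt_end`) giving a per-site integration window in minutes; sites
#'   without a row are integrated over the full run.
#' @param ... Passed to [quantify_site].
#' @return Data frame with one row per quantifiable site.
#' @export
quantify_run <- function(run, glyco_table, peak_windows = NULL, ...) {
  gt <- glyco_table[glyco_table$quantifiable, , drop = FALSE]
  if ("charge_in_range" %in% names(gt)) {
    gt <- gt[gt$charge_in_range, , drop = FALSE]
  }
  ids <- unique(gt$site_id)
  if (!length(ids)) {
    out <- data.frame(site_id = character(), run_id = character(),
                      condition = character(), replicate = integer(),
                      stringsAsFactors = FALSE)
    for (g in tolower(glycoforms())) out[[paste0("auc_", g)]] <- numeric()
    for (g in tolower(glycoforms())) out[[paste0("frac_", g)]] <- numeric()
    out$no_signal <- logical()
    return(out)
  }
  do.call(rbind, lapply(ids, function(id) {
    win <- NULL
    if (!is.null(peak_windows) && id %in% peak_windows$site_id) {
      w <- peak_windows[peak_windows$site_id == id, , drop = FALSE]
      win <- c(w$rt_start[1], w$rt_end[1])
    }
    quantify_site(run, gt[gt$site_id == id, , drop = FALSE],
                  rt_window = win, ...)
  }))
}

#' Aggregate glycoform quantifications across replicates
#'
#' Groups per-run quantifications by site and condition and reports the mean
#' and sample standard deviation (n-1 denominator) of each glycoform's
#' relative abundance. Groups with fewer than two replicates are excluded
#' from the summary and listed in the `excluded` attribute, following the
#' at-least-two-replicates reporting rule.
#'
#' @param quants Row-bound output of [quantify_run] across runs.
#' @return Data frame: `site_id`, `condition`, `n`, `mean_<glycoform>` and
#'   `sd_<glycoform>` x4, plus attribute `excluded` (site/condition pairs
#'   with n < 2).
#' @export
aggregate_replicates <- function(quants) {
  forms <- tolower(glycoforms())
  key <- interaction(quants$site_id, quants$condition, drop = TRUE)
  groups <- split(quants, key)
  rows <- list(); excl <- list()
  for (g in groups) {
    row <- data.frame(site_id = g$site_id[1], condition = g$condition[1],
                      n = nrow(g), stringsAsFactors = FALSE)
    if (nrow(g) < 2L) { excl[[length(excl) + 1L]] <- row; next }
    for (f in forms) {
      row[[paste0("mean_", f)]] <- mean(g[[paste0("frac_", f)]])
      row[[paste0("sd_", f)]] <- stats::sd(g[[paste0("frac_", f)]])
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(site_id = character(), condition = character(),
                      n = integer(), stringsAsFactors = FALSE)
    for (f in forms) {
      out[[paste0("mean_", f)]] <- numeric()
      out[[paste0("sd_", f)]] <- numeric()
    }
  }
  out <- out[order(out$site_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <-
    do.call(rbind, c(excl, list(make.row.names = FALSE)))
  out
}
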