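# Synthetic ground-truth generator: proteins built from EGF scaffolds with
# known consensus classes, and simulated centroided MS1 runs with known
# glycoform stoichiometries under WT / single- / double-knockout conditions.
#
# The simulator emits monoisotopic centroids only (no isotope envelopes),
# matching the quantifier's monoisotopic targets, with Gaussian elution
# peaks, multiplicative-free additive intensity noise and ppm-scale m/z
# jitter.

# residues used for unconstrained positions: no C (would break the
# six-cysteine scaffold), no K/R (keeps tryptic cleavage in the linkers),
# no P (keeps the proline rule out of the designed cleavage sites)
.POOL <- setdiff(.AA20, c("C", "K", "R", "P"))

# run RNG-dependent code under a fixed seed without disturbing the caller's
# RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% 2147483647)
  force(expr)
}

.SEGMENT_CLASSES <- c("original", "revised_only", "broad_only", "none")

# 8-residue inter-C3-C4 segment of a given consensus class
# (indices are consensus positions 2..9)
.make_segment <- function(class) {
  x <- sample(.POOL, 8L, replace = TRUE)
  if (class == "original")      { x[2] <- "N"; x[3] <- "T"; x[5] <- "G"; x[6] <- "S"; x[7] <- "F" }
  else if (class == "revised_only") { x[2] <- "N"; x[3] <- "T"; x[5] <- "G"; x[6] <- "S"; x[7] <- "Y" }
  else if (class == "broad_only")   { x[2] <- "N"; x[3] <- "V"; x[5] <- "G"; x[6] <- "S"; x[7] <- "F" }
  else                              { x[2] <- "N"; x[3] <- "T"; x[5] <- "G"; x[6] <- "A"; x[7] <- "F" }
  paste(x, collapse = "")
}

# one EGF scaffold around a segment; gap lengths kept modest so the
# covering tryptic peptide stays under the 50-residue cap
.make_egf <- function(segment) {
  gap <- function(n) paste(sample(.POOL, n, replace = TRUE), collapse = "")
  paste0("C", gap(sample(3:7, 1L)),
         "C", gap(sample(3:7, 1L)),
         "C", segment,
         "C", gap(sample(1:3, 1L)),
         "C", gap(sample(4:8, 1L)), "C")
}

# 6-residue linker with a K and an R cleavage site
.make_linker <- function() {
  paste0("AGK", paste(sample(.POOL, 2L), collapse = ""), "R")
}

#' Generate a synthetic protein set with planted EGF repeats and sites
#'
#' Builds proteins as tandem arrays of six-cysteine EGF scaffolds joined by
#' K/R-containing linkers, so that (i) the scaffolds satisfy the default
#' [spacing_config] and are recoverable by [detect_egf_repeats], and (ii)
#' every inter-C3-C4 segment is covered by a tryptic peptide within two
#' missed cleavages. Each EGF's segment is drawn from one of four consensus
#' classes in the given proportions: `original` (matches the original
#' pattern), `revised_only` (Y at position 8), `broad_only` (S at position 7
#' but a pattern-breaking residue at position 4), and `none` (no serine at
#' position 7).
#'
#' @param n_proteins Number of proteins.
#' @param egfs_per_protein EGF repeats per protein.
#' @param mix Named proportions over the four classes (must sum to 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List with `records` (named list of [protein_record]), `repeats`
#'   (planted EGF table, `source = "detected"` coordinates), and `truth`
#'   (per-EGF data frame: `accession`, `ordinal`, `class`, `segment`,
#'   `position` -- the absolute acceptor position, `NA` for class `none`).
#' @export
generate_protein_set <- function(n_proteins = 3L, egfs_per_protein = 4L,
                                 mix = c(original = 0.4, revised_only = 0.3,
                                         broad_only = 0.15, none = 0.15),
                                 seed = 1L) {
  stopifnot(all(names(mix) %in% .SEGMENT_CLASSES), length(mix) == 4L)
  if (abs(sum(mix) - 1) > 1e-9) stop("class proportions must sum to 1")
  .with_seed(seed, {
    n_total <- n_proteins * egfs_per_protein
    counts <- floor(mix[.SEGMENT_CLASSES] * n_total)
    while (sum(counts) < n_total) {
      i <- which.max(mix[.SEGMENT_CLASSES] * n_total - counts)
      counts[i] <- counts[i] + 1L
    }
    classes <- sample(rep(.SEGMENT_CLASSES, counts))
    records <- list(); rep_rows <- list(); truth_rows <- list()
    ci <- 0L
    for (p in seq_len(n_proteins)) {
      acc <- sprintf("SYN%03d", p)
      seq_parts <- "M"
      pos <- 1L
      for (e in seq_len(egfs_per_protein)) {
        ci <- ci + 1L
        linker <- .make_linker()
        seg <- .make_segment(classes[ci])
        egf <- .make_egf(seg)
        seq_parts <- c(seq_parts, linker, egf)
        start <- pos + nchar(linker) + 1L  # first C of the scaffold
        cys <- start + which(strsplit(egf, "")[[1]] == "C") - 1L
        rep_rows[[ci]] <- data.frame(
          accession = acc, ordinal = e, start = cys[1], end = cys[6],
          c1 = cys[1], c2 = cys[2], c3 = cys[3], c4 = cys[4],
          c5 = cys[5], c6 = cys[6], source = "detected",
          stringsAsFactors = FALSE)
        truth_rows[[ci]] <- data.frame(
          accession = acc, ordinal = e, class = classes[ci], segment = seg,
          position = if (classes[ci] == "none") NA_integer_
                     else cys[3] + 6L,  # consensus position 7
          stringsAsFactors = FALSE)
        pos <- pos + nchar(linker) + nchar(egf)
      }
      seq_parts <- c(seq_parts, .make_linker())
      records[[acc]] <- protein_record(acc, paste0("synthetic_", acc),
                                       paste(seq_parts, collapse = ""))
    }
    list(records = records,
         repeats = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
  })
}

#' Transform true glycoform fractions under a knockout condition
#'
#' When a condition removes the enzyme(s) a site depends on, the
#' glucose-bearing fractions (HEX, HEX_OH) are redistributed to (UNMOD, OH)
#' preserving the hydroxylation marginal: HEX joins UNMOD and HEX_OH joins
#' OH. Sites whose enzyme survives the condition are unchanged; the double
#' knockout removes glucosylation at every site.
#'
#' @param fractions Numeric length-4 simplex in glycoform order
#'   (UNMOD, OH, HEX, HEX_OH).
#' @param dependency Site's enzyme dependency: `"P2"`, `"P3"` or `"both"`.
#' @param condition `"WT"`, `"P2KO"`, `"P3KO"` or `"DKO"`.
#' @return Transformed length-4 fractions.
#' @export
knockout_transform <- function(fractions, dependency = c("P2", "P3", "both"),
                               condition = c("WT", "P2KO", "P3KO", "DKO")) {
  dependency <- match.arg(dependency)
  condition <- match.arg(condition)
  stopifnot(length(fractions) == 4L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-6)
  fractions <- as.numeric(fractions)
  lost <- switch(condition,
                 WT = FALSE,
                 DKO = TRUE,
                 P2KO = dependency == "P2",
                 P3KO = dependency == "P3")
  if (!lost) return(stats::setNames(fractions, glycoforms()))
  stats::setNames(c(fractions[1] + fractions[3], fractions[2] + fractions[4],
                    0, 0), glycoforms())
}

#' Build a synthetic study manifest
#'
#' Assembles the full ground-truth description of a simulated study: a
#' protein set from [generate_protein_set], the planted sites with true
#' glycoform fractions, enzyme dependencies and chromatographic parameters,
#' and the theoretical glycopeptide targets computed with the package's own
#' digestion and mass machinery. Retention-time centers are laid out on a
#' grid several peak-widths apart so no two sites' extraction windows
#' collide.
#'
#' @param n_proteins,egfs_per_protein,mix,seed Passed to
#'   [generate_protein_set].
#' @param replicates Replicates per condition (default 3).
#' @param conditions Conditions to simulate.
#' @param charges Charge states emitted and quantified (default `c(2, 3)`).
#' @param fractions Optional matrix (sites x 4) of true glycoform fractions;
#'   by default each site's fractions are drawn uniformly on the 4-simplex.
#' @param dependencies Optional character vector of per-site enzyme
#'   dependencies; by default drawn from `{P2, P3, both}`.
#' @param rt_sigma Gaussian peak width sigma in minutes (default 0.05, i.e.
#'   3 s).
#' @param rt_spacing Retention-time grid spacing in minutes (default 0.4,
#'   i.e. 8 sigma).
#' @param scan_interval MS1 scan interval in seconds (default 1).
#' @param abundance Total ion abundance per site (default 1e6).
#' @param noise List: `intensity_frac` (Gaussian intensity noise as a
#'   fraction of peak height, default 0.05) and `mz_jitter_ppm` (centroid
#'   m/z jitter sd in ppm, default 3).
#' @param mz_range Instrument scan range (default 350-2000).
#' @return Object of class `synthetic_manifest`.
#' @export
synthetic_manifest <- function(n_proteins = 3L, egfs_per_protein = 4L,
                               mix = c(original = 0.4, revised_only = 0.3,
                                       broad_only = 0.15, none = 0.15),
                               seed = 1L, replicates = 3L,
                               conditions = c("WT", "P2KO", "P3KO", "DKO"),
                               charges = c(2L, 3L), fractions = NULL,
                               dependencies = NULL, rt_sigma = 0.05,
                               rt_spacing = 0.4, scan_interval = 1,
                               abundance = 1e6,
                               noise = list(intensity_frac = 0.05,
                                            mz_jitter_ppm = 3),
                               mz_range = c(350, 2000)) {
  gen <- generate_protein_set(n_proteins, egfs_per_protein, mix, seed)
  pat <- builtin_patterns()$broad
  sites <- do.call(rbind, c(lapply(gen$records, function(rec) {
    reps <- gen$repeats[gen$repeats$accession == rec$accession, , drop = FALSE]
    scan_protein(rec, reps, pat)
  }), list(make.row.names = FALSE)))
  peptides <- do.call(rbind, c(lapply(gen$records, digest,
                                      protease = "trypsin", max_missed = 2L),
                               list(make.row.names = FALSE)))
  assigned <- assign_peptides_to_sites(peptides, sites)
  targets <- glycoform_table(assigned, gen$repeats, gen$records,
                             charges = charges, scan_range = mz_range)
  quant <- unique(targets$site_id[targets$quantifiable])
  n_sites <- length(quant)
  site_tab <- .with_seed(seed + 1L, {
    if (is.null(fractions)) {
      fractions <- t(vapply(seq_len(n_sites), function(i) {
        x <- stats::rexp(4L); x / sum(x)
      }, numeric(4L)))
    }
    stopifnot(nrow(fractions) == n_sites, ncol(fractions) == 4L)
    if (any(abs(rowSums(fractions) - 1) > 1e-9)) {
      stop("each site's true fractions must sum to 1")
    }
    if (is.null(dependencies)) {
      dependencies <- sample(c("P2", "P3", "both"), n_sites, replace = TRUE)
    }
    stopifnot(length(dependencies) == n_sites,
              all(dependencies %in% c("P2", "P3", "both")))
    data.frame(site_id = quant,
               frac_unmod = fractions[, 1], frac_oh = fractions[, 2],
               frac_hex = fractions[, 3], frac_hex_oh = fractions[, 4],
               dependency = dependencies,
               rt_center = 2 + rt_spacing * (seq_len(n_sites) - 1L),
               rt_sigma = rt_sigma, abundance = abundance,
               stringsAsFactors = FALSE)
  })
  structure(list(seed = as.integer(seed),
                 records = gen$records, repeats = gen$repeats,
                 truth = gen$truth, sites = site_tab, targets = targets,
                 charges = as.integer(charges), conditions = conditions,
                 replicates = as.integer(replicates),
                 scan_interval = scan_interval, noise = noise,
                 mz_range = mz_range,
                 rt_end = 2 + rt_spacing * n_sites + 2),
            class = "synthetic_manifest")
}

#' @export
print.synthetic_manifest <- function(x, ...) {
  cat("<synthetic_manifest> seed ", x$seed, ": ", length(x$records),
      " proteins, ", nrow(x$sites), " quantifiable sites, conditions ",
      paste(x$conditions, collapse = "/"), " x ", x$replicates,
      " replicates\n", sep = "")
  invisible(x)
}

#' Expected glycoform fractions under a condition
#'
#' Applies [knockout_transform] to every site's true fractions.
#'
#' @param manifest A [synthetic_manifest].
#' @param condition Condition name.
#' @return Data frame `site_id`, `frac_unmod`..`frac_hex_oh`.
#' @export
expected_fractions <- function(manifest, condition) {
  out <- manifest$sites[, "site_id", drop = FALSE]
  m <- t(vapply(seq_len(nrow(manifest$sites)), function(i) {
    s <- manifest$sites[i, ]
    knockout_transform(c(s$frac_unmod, s$frac_oh, s$frac_hex, s$frac_hex_oh),
                       s$dependency, condition)
  }, numeric(4L)))
  out$frac_unmod <- m[, 1]; out$frac_oh <- m[, 2]
  out$frac_hex <- m[, 3]; out$frac_hex_oh <- m[, 4]
  out
}

#' Expected specificity call per synthetic site
#'
#' The call [classify_specificity] should recover: `POGLUT2_preferred` for
#' P2-dependent sites, `POGLUT3_preferred` for P3-dependent sites,
#' `redundant` for dual-enzyme sites -- provided the wild-type glucosylated
#' fraction clears the caller's floor (sites below it are expected
#' `indeterminate`).
#'
#' @param manifest A [synthetic_manifest].
#' @param wt_floor The caller's wild-type floor (default 0.05).
#' @return Data frame `site_id`, `dependency`, `wt_gluc`, `expected_call`.
#' @export
expected_specificity <- function(manifest, wt_floor = 0.05) {
  s <- manifest$sites
  wt_gluc <- s$frac_hex + s$frac_hex_oh
  call <- ifelse(wt_gluc < wt_floor, "indeterminate",
          ifelse(s$dependency == "P2", "POGLUT2_preferred",
          ifelse(s$dependency == "P3", "POGLUT3_preferred", "redundant")))
  data.frame(site_id = s$site_id, dependency = s$dependency,
             wt_gluc = wt_gluc, expected_call = call,
             stringsAsFactors = FALSE)
}

#' Simulate one LC-MS run
#'
#' For each site x glycoform x charge target, lays down a Gaussian elution
#' peak centered at the site's retention time: the peak area equals the
#' condition-transformed glycoform fraction times the site's total
#' abundance, split equally across charge states. Peaks are sampled at the
#' scan interval into centroided MS1 scans at the theoretical m/z, with
#' Gaussian m/z jitter (ppm scale) and additive Gaussian intensity noise
#' scaled to the peak height. Targets whose m/z falls outside the scan
#' range are dropped with a warning -- such sites cannot be fully observed,
#' which is why the quantifier flags them rather than reporting them as
#' fully modified.
#'
#' Runs are reproducible: the RNG stream is derived from
#' (manifest seed, condition, replicate).
#'
#' @param manifest A [synthetic_manifest].
#' @param condition Condition to simulate.
#' @param replicate Replicate index.
#' @param noiseless Override the manifest noise model with zero noise.
#' @return A [spectra_run].
#' @export
simulate_run <- function(manifest, condition = "WT", replicate = 1L,
                         noiseless = FALSE) {
  stopifnot(inherits(manifest, "synthetic_manifest"),
            condition %in% c("WT", "P2KO", "P3KO", "DKO"))
  cond_idx <- match(condition, c("WT", "P2KO", "P3KO", "DKO"))
  run_seed <- (manifest$seed * 1009L + cond_idx * 131071L +
                 as.integer(replicate) * 7919L) %% 2147483647L
  noise_frac <- if (noiseless) 0 else manifest$noise$intensity_frac
  jitter_ppm <- if (noiseless) 0 else manifest$noise$mz_jitter_ppm
  times <- seq(0, manifest$rt_end, by = manifest$scan_interval / 60)
  nscan <- length(times)
  truth <- expected_fractions(manifest, condition)
  .with_seed(run_seed, {
    scan_mz <- vector("list", nscan)
    scan_int <- vector("list", nscan)
    for (i in seq_len(nrow(manifest$sites))) {
      site <- manifest$sites[i, ]
      fr <- as.numeric(truth[truth$site_id == site$site_id,
                             c("frac_unmod", "frac_oh", "frac_hex",
                               "frac_hex_oh")])
      names(fr) <- glycoforms()
      tg <- manifest$targets[manifest$targets$site_id == site$site_id &
                               manifest$targets$charge_in_range, ,
                             drop = FALSE]
      nz <- length(unique(tg$charge))
      sel <- which(abs(times - site$rt_center) <= 5 * site$rt_sigma)
      for (k in seq_len(nrow(tg))) {
        f <- fr[[tg$glycoform[k]]]
        if (f <= 0) next
        if (tg$mz[k] < manifest$mz_range[1] ||
            tg$mz[k] > manifest$mz_range[2]) {
          warning("target ", tg$site_id[k], " ", tg$glycoform[k], " ",
                  tg$charge[k], "+ m/z ", round(tg$mz[k], 2),
                  " outside scan range; peak dropped")
          next
        }
        area <- f * site$abundance / nz
        height <- area / (site$rt_sigma * sqrt(2 * pi))
        base <- height * exp(-(times[sel] - site$rt_center)^2 /
                               (2 * site$rt_sigma^2))
        if (noise_frac > 0) {
          base <- base + stats::rnorm(length(base), 0, noise_frac * height)
        }
        keep <- base > 0
        if (!any(keep)) next
        mzs <- tg$mz[k] *
          (1 + stats::rnorm(sum(keep), 0, jitter_ppm * 1e-6))
        for (j in seq_along(sel)[keep]) {
          s <- sel[j]
          scan_mz[[s]] <- c(scan_mz[[s]], mzs[match(j, which(keep))])
          scan_int[[s]] <- c(scan_int[[s]], base[j])
        }
      }
    }
    scans <- lapply(seq_len(nscan), function(s) {
      mz <- scan_mz[[s]]; inten <- scan_int[[s]]
      if (is.null(mz)) mz <- numeric(0)
      if (is.null(inten)) inten <- numeric(0)
      ord <- order(mz)
      list(rt = times[s], mz = mz[ord], intensity = inten[ord])
    })
    spectra_run(sprintf("sim%d_%s_rep%d", manifest$seed, condition,
                        as.integer(replicate)),
                condition, replicate, scans, manifest$mz_range)
  })
}

#' Per-site integration windows for a manifest's sites
#'
#' Builds the peak-window table consumed by [quantify_run]: each site's
#' elution window, `rt_center +/- width_sigmas * rt_sigma`.
#'
#' @param manifest A [synthetic_manifest].
#' @param width_sigmas Half-width of the window in peak sigmas (default 6).
#' @return Data frame `site_id`, `rt_start`, `rt_end`.
#' @export
peak_windows <- function(manifest, width_sigmas = 6) {
  data.frame(site_id = manifest$sites$site_id,
             rt_start = manifest$sites$rt_center -
               width_sigmas * manifest$sites$rt_sigma,
             rt_end = manifest$sites$rt_center +
               width_sigmas * manifest$sites$rt_sigma,
             stringsAsFactors = FALSE)
}

#' Simulate the whole study
#'
#' Runs [simulate_run] for every condition x replicate of the manifest.
#'
#' @param manifest A [synthetic_manifest].
#' @param noiseless Disable the noise model.
#' @return List of [spectra_run] objects.
#' @export
simulate_study <- function(manifest, noiseless = FALSE) {
  runs <- list()
  for (cond in manifest$conditions) {
    for (r in seq_len(manifest$replicates)) {
      runs[[length(runs) + 1L]] <-
        simulate_run(manifest, cond, r, noiseless = noiseless)
    }
  }
  runs
}

#' Write / read a run in the package's JSON dialect
#'
#' The run JSON schema is a single object with fields `run_id` (string),
#' `condition` (string), `replicate` (integer), `mz_range` (length-2
#' number array) and `scans`: an array of objects with `rt` (minutes,
#' number), `mz` (ascending number array) and `intensity` (matching number
#' array).
#'
#' @param run A [spectra_run].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(run, path) {
  stopifnot(inherits(run, "spectra_run"))
  x <- list(run_id = run$run_id, condition = run$condition,
            replicate = run$replicate, mz_range = run$mz_range,
            scans = lapply(run$scans, function(s) {
              list(rt = s$rt, mz = as.list(s$mz),
                   intensity = as.list(s$intensity))
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run as minimal centroided mzML
#'
#' Emits the minimal compliant mzML subset: MS1 centroid spectra with scan
#' start times (minutes) and uncompressed 64-bit float m/z / intensity
#' arrays. Round-trips through [read_run].
#'
#' @param run A [spectra_run].
#' @param path Output path (conventionally `.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "spectra_run"))
  enc <- function(x) {
    gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                 size = 8L,
                                                 endian = "little")),
         fixed = TRUE)
  }
  spec <- vapply(seq_along(run$scans), function(i) {
    s <- run$scans[[i]]
    emz <- enc(s$mz); eint <- enc(s$intensity)
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.8f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(s$mz), s$rt, nchar(emz), emz, nchar(eint), eint)
  }, "")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UO" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="egfoglc" version="0.1"/></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="egfoglc"/>',
    '</dataProcessing></dataProcessingList>\n',
    '<run id="%s" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n%s\n',
    '</spectrumList></run></mzML>'),
    run$run_id, length(run$scans), paste(spec, collapse = "\n"))
  writeLines(doc, path)
  invisible(path)
}

#' Write / read a study manifest as JSON
#'
#' Serialises the full ground truth (seed, protein sequences, planted
#' repeats and classes, per-site fractions and chromatographic parameters,
#' glycopeptide targets, study design and noise model) so a study is fully
#' reproducible from the file. `read_manifest` validates the schema: the
#' seed must be present and each site's fractions must sum to 1.
#'
#' @param manifest A [synthetic_manifest].
#' @param path JSON path.
#' @return `write_manifest`: `path`, invisibly. `read_manifest`: the
#'   reconstructed [synthetic_manifest].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "synthetic_manifest"))
  x <- unclass(manifest)
  x$records <- lapply(unname(x$records), function(r) {
    list(accession = r$accession, name = r$name, sequence = r$sequence)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$seed)) stop("manifest is missing the 'seed' field")
  need <- c("records", "repeats", "truth", "sites", "targets", "charges",
            "conditions", "replicates", "scan_interval", "noise",
            "mz_range", "rt_end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("manifest is missing field(s): ", paste(miss, collapse = ", "))
  }
  sites <- as.data.frame(x$sites, stringsAsFactors = FALSE)
  fr <- as.matrix(sites[, c("frac_unmod", "frac_oh", "frac_hex",
                            "frac_hex_oh")])
  if (any(abs(rowSums(fr) - 1) > 1e-9)) {
    stop("manifest validation: site fractions do not sum to 1")
  }
  recs <- lapply(seq_along(x$records$accession), function(i) {
    protein_record(x$records$accession[i], x$records$name[i],
                   x$records$sequence[i])
  })
  names(recs) <- x$records$accession
  structure(list(seed = as.integer(x$seed), records = recs,
                 repeats = as.data.frame(x$repeats),
                 truth = as.data.frame(x$truth), sites = sites,
                 targets = as.data.frame(x$targets),
                 charges = as.integer(x$charges),
                 conditions = as.character(x$conditions),
                 replicates = as.integer(x$replicates),
                 scan_interval = as.numeric(x$scan_interval),
                 noise = as.list(x$noise),
                 mz_range = as.numeric(x$mz_range),
                 rt_end = as.numeric(x$rt_end)),
            class = "synthetic_manifest")
}
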