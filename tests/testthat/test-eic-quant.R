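# a run built scan by scan, no simulator involved
make_run <- function(scans, condition = "WT", replicate = 1L) {
  spectra_run("manual", condition, replicate, scans)
}

test_that("spectra_run validates scan ordering and array shapes", {
  good <- list(list(rt = 1, mz = c(400, 500), intensity = c(1, 2)),
               list(rt = 2, mz = numeric(0), intensity = numeric(0)))
  expect_s3_class(make_run(good), "spectra_run")
  expect_error(make_run(rev(good)), "strictly increasing")
  expect_error(make_run(list(list(rt = 1, mz = c(500, 400),
                                  intensity = c(1, 2)))), "sorted")
  expect_error(make_run(list(list(rt = 1, mz = 400, intensity = c(1, 2)))),
               "length")
})

test_that("EIC windowing keeps centroids inside the ppm tolerance only", {
  tgt <- 1000
  scans <- list(
    list(rt = 1, mz = tgt, intensity = 100),                  # exact hit
    list(rt = 2, mz = tgt * (1 + 50e-6), intensity = 100),    # 50 ppm away
    list(rt = 3, mz = c(tgt * (1 - 10e-6), tgt * (1 + 10e-6)),
         intensity = c(40, 60)))                              # both inside
  eic <- extract_eic(make_run(scans), tgt, ppm = 20)
  expect_equal(eic$intensity, c(100, 0, 100))
  expect_equal(nrow(eic), 3L)
})

test_that("trapezoidal integration matches closed forms", {
  # constant 100 over 2 minutes
  flat <- data.frame(rt = seq(0, 2, by = 0.1), intensity = 100)
  expect_equal(integrate_auc(flat), 200)
  # all-zero trace
  zero <- data.frame(rt = seq(0, 2, by = 0.1), intensity = 0)
  expect_equal(integrate_auc(zero), 0)
  # triangular peak of height h and base b integrates to h*b/2 within 1%
  # at a 1 s scan interval
  h <- 1000; b <- 2 / 60 * 20  # 20-scan base

  rt <- seq(0, 1, by = 1 / 60)
  apex <- 0.5
  y <- pmax(0, h * (1 - abs(rt - apex) / (b / 2)))
  tri <- data.frame(rt = rt, intensity = y)
  expect_equal(integrate_auc(tri), h * b / 2, tolerance = 0.01)
  # window bounds are honoured
  expect_equal(integrate_auc(flat, c(0, 1)), 100)
  expect_error(integrate_auc(flat, c(3, 4)), "no scans")
})

test_that("relative abundance is AUC over summed AUC across charges", {
  d <- glycoform_deltas()
  base <- 1200
  targets <- do.call(rbind, lapply(names(d), function(g) {
    data.frame(site_id = "S1", glycoform = g, charge = 2L,
               mz = mz_for_charge(base + d[[g]], 2L),
               charge_in_range = TRUE, quantifiable = TRUE,
               stringsAsFactors = FALSE)
  }))
  # rectangular signals with per-form intensities 0,0,200,600 over 1 minute
  lvl <- c(UNMOD = 0, OH = 0, HEX = 200, HEX_OH = 600)
  scans <- lapply(seq(0, 1, by = 1 / 60), function(t) {
    keep <- lvl > 0
    list(rt = t, mz = unname(sort(targets$mz[keep])),
         intensity = unname(lvl[keep][order(targets$mz[keep])]))
  })
  q <- quantify_site(make_run(scans), targets)
  expect_equal(q$frac_hex, 0.25, tolerance = 1e-9)
  expect_equal(q$frac_hex_oh, 0.75, tolerance = 1e-9)
  expect_equal(q$frac_unmod + q$frac_oh, 0)
  expect_false(q$no_signal)
  # equal areas give uniform fractions
  lvl2 <- c(UNMOD = 100, OH = 100, HEX = 100, HEX_OH = 100)
  scans2 <- lapply(seq(0, 1, by = 1 / 60), function(t) {
    list(rt = t, mz = sort(targets$mz),
         intensity = unname(lvl2[order(targets$mz)]))
  })
  q2 <- quantify_site(make_run(scans2), targets)
  expect_equal(unlist(q2[paste0("frac_", tolower(glycoforms()))],
                      use.names = FALSE), rep(0.25, 4L), tolerance = 1e-9)
})

test_that("a silent site is flagged no-signal with zero fractions", {
  targets <- data.frame(site_id = "S1", glycoform = glycoforms(),
                        charge = 2L, mz = c(700, 708, 781, 789),
                        charge_in_range = TRUE, quantifiable = TRUE,
                        stringsAsFactors = FALSE)
  empty <- lapply(1:10, function(i) list(rt = i / 10, mz = numeric(0),
                                         intensity = numeric(0)))
  q <- quantify_site(make_run(empty), targets)
  expect_true(q$no_signal)
  expect_equal(sum(unlist(q[paste0("frac_", tolower(glycoforms()))])), 0)
})

test_that("fraction normalisation and linearity under intensity scaling", {
  man <- fixture_manifest()
  run <- simulate_run(man, "WT", 1L, noiseless = TRUE)
  q <- quantify_run(run, man$targets)
  fr <- as.matrix(q[, paste0("frac_", tolower(glycoforms()))])
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # scale every intensity by k: AUCs scale, fractions do not
  k <- 3.7
  scaled <- spectra_run(run$run_id, run$condition, run$replicate,
                        lapply(run$scans, function(s) {
                          s$intensity <- s$intensity * k; s
                        }), run$mz_range)
  q2 <- quantify_run(scaled, man$targets)
  expect_equal(as.matrix(q2[, paste0("auc_", tolower(glycoforms()))]),
               k * as.matrix(q[, paste0("auc_", tolower(glycoforms()))]),
               tolerance = 1e-9)
  expect_equal(as.matrix(q2[, paste0("frac_", tolower(glycoforms()))]), fr,
               tolerance = 1e-12)
})

test_that("replicate aggregation uses sample SD and the n >= 2 rule", {
  template <- data.frame(site_id = "S1", run_id = "r", condition = "WT",
                         replicate = 1L, stringsAsFactors = FALSE)
  for (g in tolower(glycoforms())) template[[paste0("auc_", g)]] <- 1
  mk <- function(rep, fracs) {
    row <- template; row$replicate <- rep
    for (i in seq_along(fracs)) {
      row[[paste0("frac_", tolower(glycoforms())[i])]] <- fracs[i]
    }
    row$no_signal <- FALSE
    row
  }
  quants <- rbind(mk(1L, c(0.4, 0, 0.6, 0)), mk(2L, c(0.6, 0, 0.4, 0)))
  s <- aggregate_replicates(quants)
  expect_equal(s$n, 2L)
  expect_equal(s$mean_unmod, 0.5)
  expect_equal(s$sd_unmod, stats::sd(c(0.4, 0.6)))
  # three identical replicates: SD 0
  q3 <- rbind(mk(1L, c(0.25, 0.25, 0.25, 0.25)),
              mk(2L, c(0.25, 0.25, 0.25, 0.25)),
              mk(3L, c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(aggregate_replicates(q3)$sd_hex, 0)
  # single replicate: excluded but listed
  one <- mk(1L, c(1, 0, 0, 0)); one$site_id <- "S2"
  s2 <- aggregate_replicates(rbind(quants, one))
  expect_false("S2" %in% s2$site_id)
  expect_true("S2" %in% attr(s2, "excluded")$site_id)
})

test_that("runjson round-trips and mzML files load with MS1 scans only", {
  man <- fixture_manifest()
  run <- simulate_run(man, "P2KO", 2L, noiseless = TRUE)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_run_json(run, jpath)
  back <- read_run(jpath)
  expect_equal(back$condition, "P2KO")
  expect_equal(back$replicate, 2L)
  expect_equal(length(back$scans), length(run$scans))
  i <- which(vapply(run$scans, function(s) length(s$mz) > 0L, TRUE))[1]
  expect_equal(back$scans[[i]], run$scans[[i]], tolerance = 1e-12)
  mpath <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, mpath)
  back2 <- read_run(mpath)
  expect_equal(length(back2$scans), length(run$scans))
  expect_equal(back2$scans[[i]]$mz, run$scans[[i]]$mz, tolerance = 1e-9)
  expect_equal(back2$scans[[i]]$rt, run$scans[[i]]$rt, tolerance = 1e-6)
  # quantification is identical through either container
  q1 <- quantify_run(run, man$targets)
  q2 <- quantify_run(back2, man$targets)
  # run id / condition metadata come from the filename; compare the numbers
  expect_equal(q2[, -(2:4)], q1[, -(2:4)], tolerance = 1e-9)
})

test_that("mzML readers keep MS1 and reject malformed run JSON", {
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(run_id = "x", scans = list()), jpath,
                       auto_unbox = TRUE)
  expect_error(read_run(jpath), "missing field")
  expect_error(read_run("/nonexistent/file.json"), "not found")
})
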