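patterns <- builtin_patterns()

test_that("built-in patterns encode the published constraints", {
  expect_equal(match_consensus("ANTAGSFA", patterns$original), 6L)
  # tyrosine at position 8: accepted by revised, rejected by original
  expect_equal(match_consensus("ANTAGSYA", patterns$revised), 6L)
  expect_true(is.na(match_consensus("ANTAGSYA", patterns$original)))
  # broad pattern only demands the serine acceptor
  expect_equal(match_consensus("QQQQQSQQ", patterns$broad), 6L)
  # beta-hydroxylation: N/D at 3, F/Y at 8, acceptor at position 3
  expect_equal(match_consensus("ADAAAAFA", patterns$beta_hydroxylation), 2L)
  expect_true(is.na(match_consensus("AAAAAAFA", patterns$beta_hydroxylation)))
})

test_that("segments of the wrong length never match", {
  expect_true(is.na(match_consensus("ANTAGSF", patterns$original)))
  expect_true(is.na(match_consensus("ANTAGSFAA", patterns$broad)))
})

test_that("the EGF11-style conversion needs both position-4 and -7 changes", {
  # wild-type loop: L at position 4, T at position 7, Y at position 8
  wt <- "ANLAGTYE"
  pos4 <- "ANTAGTYE"   # L -> T at consensus position 4
  pos7 <- "ANLAGSYE"   # T -> S at consensus position 7
  both <- "ANTAGSYE"
  expect_true(is.na(match_consensus(wt, patterns$revised)))
  expect_true(is.na(match_consensus(pos4, patterns$revised)))
  expect_true(is.na(match_consensus(pos7, patterns$revised)))
  expect_equal(match_consensus(both, patterns$revised), 6L)
})

test_that("threonine at position 7 is only matched when explicitly allowed", {
  thr <- "ANTAGTFA"
  expect_true(is.na(match_consensus(thr, patterns$original)))
  expect_equal(match_consensus(thr, builtin_patterns(allow_thr7 = TRUE)$original),
               6L)
})

test_that("pattern matches are monotone: original < revised < broad", {
  set.seed(404)
  segs <- c(vapply(1:1000, function(i) random_segment(8L), ""),
            "ANTAGSFA", "ANTAGSYA", "QQQQQSQQ")  # force each match tier
  o <- !is.na(vapply(segs, match_consensus, 0L, patterns$original))
  r <- !is.na(vapply(segs, match_consensus, 0L, patterns$revised))
  b <- !is.na(vapply(segs, match_consensus, 0L, patterns$broad))
  expect_true(all(r[o]))
  expect_true(all(b[r]))
  expect_true(any(b))
})

test_that("scan_protein reports acceptor serines with correct coordinates", {
  fix <- fixture_two_egf_record()
  det <- detect_egf_repeats(fix$record)
  s_orig <- scan_protein(fix$record, det, patterns$original)
  s_rev <- scan_protein(fix$record, det, patterns$revised)
  expect_equal(s_orig$ordinal, 1L)            # only the F-at-8 repeat
  expect_equal(s_rev$ordinal, c(1L, 2L))      # revised adds the Y-at-8 one
  expect_true(all(s_rev$residue == "S"))
  expect_equal(s_rev$position, det$c3 + 6L)   # consensus position 7
  # empty repeats give an empty site table
  empty <- scan_protein(fix$record, det[0, ], patterns$broad)
  expect_equal(nrow(empty), 0L)
})

test_that("proteome scan totals equal sums over per-protein site lists", {
  gen <- generate_protein_set(3L, 3L,
                              mix = c(original = 1, revised_only = 0,
                                      broad_only = 0, none = 0), seed = 2L)
  scan <- scan_proteome(gen$records, patterns$original,
                        repeats = gen$repeats)
  expect_equal(scan$n_proteins, 3L)
  expect_equal(scan$n_sites, 9L)              # all planted segments match
  expect_equal(scan$n_proteins_with_sites, 3L)
  expect_equal(scan$n_sites, nrow(scan$sites))
  expect_identical(scan$mode, "annotated")
  # detected mode finds the same planted sites
  scan2 <- scan_proteome(gen$records, patterns$original)
  expect_identical(scan2$mode, "detected")
  expect_equal(scan2$sites$position, scan$sites$position)
})

test_that("broad-pattern scans find at least as many sites as revised", {
  gen <- generate_protein_set(4L, 4L, seed = 13L)
  n_rev <- scan_proteome(gen$records, patterns$revised,
                         repeats = gen$repeats)$n_sites
  n_broad <- scan_proteome(gen$records, patterns$broad,
                           repeats = gen$repeats)$n_sites
  expect_gte(n_broad, n_rev)
  # ground truth: broad finds every planted serine-at-7 segment
  expect_equal(n_broad, sum(!is.na(gen$truth$position)))
})

test_that("point mutations check the reference residue and leave the
           original record untouched", {
  rec <- protein_record("MUT", sequence = "MALTSEV")
  out <- apply_point_mutations(rec, "L3T")
  expect_identical(out$sequence, "MATTSEV")
  expect_identical(rec$sequence, "MALTSEV")
  expect_match(out$name, "L3T")
  out2 <- apply_point_mutations(rec, c("L3T", "T4S"))
  expect_identical(out2$sequence, "MATSSEV")
  expect_error(apply_point_mutations(rec, "A3T"),
               "expected A, found L")
  expect_error(apply_point_mutations(rec, "L99T"), "outside")
  expect_error(parse_mutations("L3"), "malformed")
})

test_that("a consensus-creating double mutation adds exactly one site", {
  # build a protein whose second EGF carries the EGF11-style loop
  egf_ok <- paste0("C", "ADGH", "C", "EFGQ", "C", "ANTAGSFA", "C", "QD",
                   "C", "LMNQA", "C")
  egf11 <- paste0("C", "HILMA", "C", "DEFG", "C", "ANLAGTYE", "C", "AD",
                  "C", "EFGHI", "C")
  rec <- protein_record("EGF11", sequence = paste0(
    "MAGKDVR", egf_ok, "AGKEVR", egf11, "AGKDVR"))
  det <- detect_egf_repeats(rec)
  before <- scan_protein(rec, det, patterns$revised)
  expect_equal(before$ordinal, 1L)
  # consensus positions 4 and 7 of repeat 2 in absolute coordinates
  pos4 <- det$c3[2] + 3L
  pos7 <- det$c3[2] + 6L
  single <- apply_point_mutations(rec, sprintf("L%dT", pos4))
  expect_equal(scan_protein(single, det, patterns$revised)$ordinal, 1L)
  dbl <- apply_point_mutations(rec, c(sprintf("L%dT", pos4),
                                      sprintf("T%dS", pos7)))
  after <- scan_protein(dbl, det, patterns$revised)
  expect_equal(after$ordinal, c(1L, 2L))
  # the pre-existing site is unchanged
  expect_equal(after[after$ordinal == 1L, ], before[1, ],
               ignore_attr = TRUE)
})
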