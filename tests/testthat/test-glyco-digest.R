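test_that("tryptic cleavage follows the K/R rule with proline suppression", {
  d0 <- digest("ACKDEFRGH", "trypsin", max_missed = 0L)
  expect_identical(d0$sequence, c("ACK", "DEFR", "GH"))
  # K before P is not cleaved
  dp <- digest("ACKPDE", "trypsin", max_missed = 0L)
  expect_identical(dp$sequence, "ACKPDE")
  # proline rule can be disabled
  dnp <- digest("ACKPDE", "trypsin", max_missed = 0L, proline_rule = FALSE)
  expect_identical(dnp$sequence, c("ACK", "PDE"))
  d1 <- digest("ACKDEFRGH", "trypsin", max_missed = 1L)
  expect_true(all(c("ACKDEFR", "DEFRGH") %in% d1$sequence))
})

test_that("digest agrees with a brute-force cut-subset oracle", {
  rules <- list(trypsin = c("K", "R"), v8 = c("E", "D"),
                chymotrypsin = c("Y", "F", "W", "L", "I"))
  set.seed(11)
  for (prot in names(rules)) {
    for (rep in 1:5) {
      seq <- random_segment(sample(20:60, 1L))
      for (mm in 0:2) {
        got <- digest(seq, prot, max_missed = mm)
        want <- oracle_digest_spans(seq, rules[[prot]], mm)
        expect_equal(as.matrix(got[, c("start", "end", "missed")]),
                     want, ignore_attr = TRUE)
      }
    }
  }
})

test_that("zero-missed-cleavage peptides reconstruct the protein", {
  set.seed(21)
  for (rep in 1:10) {
    seq <- random_segment(sample(30:80, 1L))
    for (prot in c("trypsin", "v8", "chymotrypsin")) {
      d <- digest(seq, prot, max_missed = 0L)
      expect_identical(paste(d$sequence, collapse = ""), seq)
    }
  }
})

test_that("peptide masses match composition-summation oracle values", {
  # values frozen from an independent elemental-composition calculation
  expect_equal(peptide_neutral_mass("G", carbamidomethyl = FALSE),
               75.032028, tolerance = 1e-6)
  expect_equal(peptide_neutral_mass("C", carbamidomethyl = TRUE) -
                 peptide_neutral_mass("C", carbamidomethyl = FALSE),
               57.021464, tolerance = 1e-6)
  expect_equal(peptide_neutral_mass("CVNTYGSYECK"),
               1379.548587, tolerance = 1e-5)
  expect_error(peptide_neutral_mass("ABZ"), "unknown residue")
})

test_that("mass additivity holds for any split of a peptide", {
  water <- formula_mass(c(H = 2, O = 1))
  set.seed(31)
  for (rep in 1:20) {
    pep <- random_segment(sample(4:30, 1L))
    k <- sample(nchar(pep) - 1L, 1L)
    a <- substr(pep, 1L, k); b <- substr(pep, k + 1L, nchar(pep))
    expect_equal(peptide_neutral_mass(pep),
                 peptide_neutral_mass(a) + peptide_neutral_mass(b) - water,
                 tolerance = 1e-9)
  }
})

test_that("modification deltas derive from elemental compositions", {
  mods <- modification_specs()
  get <- function(n) mods$delta[mods$name == n]
  expect_equal(get("carbamidomethyl"), 57.021464, tolerance = 1e-6)
  expect_equal(get("oxidation"), 15.994915, tolerance = 1e-6)
  expect_equal(get("deamidated"), 0.984016, tolerance = 1e-6)
  expect_equal(get("ammonia_loss"), -17.026549, tolerance = 1e-6)
  expect_equal(get("hexose"), 162.052824, tolerance = 1e-6)
  d <- glycoform_deltas()
  expect_equal(unname(d["HEX"] - d["UNMOD"]), unname(get("hexose")))
  # commutativity of the two deltas
  expect_equal(unname(d["HEX_OH"] - d["OH"]), unname(d["HEX"] - d["UNMOD"]))
})

test_that("m/z conversion uses the proton mass and is monotone in charge", {
  expect_equal(mz_for_charge(1000, 1L), 1001.007276, tolerance = 1e-6)
  expect_equal(mz_for_charge(1000, 2L), 501.007276, tolerance = 1e-6)
  expect_lt(mz_for_charge(1000, 2L), mz_for_charge(1000, 1L))
  expect_error(mz_for_charge(1000, 0L), "charge")
})

test_that("the doubly charged glycoform ladder matches the oracle", {
  # frozen 2+ values for the carbamidomethylated EGF33 tryptic peptide
  base <- peptide_neutral_mass("CVNTYGSYECK")
  d <- glycoform_deltas()
  got <- mz_for_charge(base + unname(d), 2L)
  expect_equal(got, c(690.781570, 698.779028, 771.807982, 779.805440),
               tolerance = 1e-5)
})

test_that("peptide assignment prefers fewest missed cleavages, then shortest", {
  sites <- data.frame(accession = "X", ordinal = 1L, position = 10L,
                      residue = "S", pattern = "broad", segment = "AAAAASAA",
                      stringsAsFactors = FALSE)
  peptides <- data.frame(
    accession = "X",
    start = c(5L, 5L, 8L),
    end = c(20L, 30L, 20L),
    sequence = c(strrep("A", 16L), strrep("A", 26L), strrep("A", 13L)),
    protease = "trypsin",
    missed = c(1L, 0L, 0L), stringsAsFactors = FALSE)
  asg <- assign_peptides_to_sites(peptides, sites)
  # 0-missed wins over 1-missed; then the shorter of the 0-missed pair
  expect_equal(asg$pep_start, 8L)
  expect_equal(asg$missed, 0L)
  # a site nothing covers is reported uncovered
  far <- sites; far$position <- 100L
  expect_false(assign_peptides_to_sites(peptides, far)$covered)
  # the length cap excludes long peptides
  capped <- assign_peptides_to_sites(peptides[2, ], sites, max_length = 20L)
  expect_false(capped$covered)
})

test_that("glycoform table covers the EGF33-style peptide end to end", {
  fix <- fixture_two_egf_record()
  det <- detect_egf_repeats(fix$record)
  sites <- scan_protein(fix$record, det, builtin_patterns()$revised)
  pep <- digest(fix$record, "trypsin", max_missed = 2L)
  asg <- assign_peptides_to_sites(pep, sites)
  expect_true(all(asg$covered))
  gt <- glycoform_table(asg, det, list(fix$record), charges = c(2L, 3L))
  expect_equal(nrow(gt), 2L * 4L * 2L)   # 2 sites x 4 forms x 2 charges
  expect_true(all(gt$oh_enabled))        # both segments carry N at position 3
  # HEX exceeds UNMOD by exactly the hexose delta at every charge
  for (z in c(2L, 3L)) {
    un <- gt[gt$glycoform == "UNMOD" & gt$charge == z, "neutral_mass"]
    hx <- gt[gt$glycoform == "HEX" & gt$charge == z, "neutral_mass"]
    expect_equal(hx - un, rep(glycoform_deltas()[["HEX"]], 2L))
  }
})

test_that("glycoform m/z values never collide within an EIC window", {
  # across a synthetic peptide set, the four forms at z <= 2 stay >= 0.49 Th
  # apart, so 20 ppm windows below m/z 2000 cannot overlap
  gen <- generate_protein_set(3L, 4L, seed = 17L)
  man_sep <- Inf
  for (rec in gen$records) {
    det <- detect_egf_repeats(rec)
    sites <- scan_protein(rec, det, builtin_patterns()$broad)
    asg <- assign_peptides_to_sites(digest(rec, "trypsin", 2L), sites)
    gt <- glycoform_table(asg, det, list(rec), charges = c(1L, 2L))
    for (id in unique(gt$site_id)) {
      for (z in c(1L, 2L)) {
        mzs <- sort(gt$mz[gt$site_id == id & gt$charge == z])
        if (length(mzs) > 1L) man_sep <- min(man_sep, diff(mzs))
      }
    }
  }
  expect_gte(man_sep, 0.49)
})

test_that("peptides invisible at every charge are flagged unquantifiable", {
  # a tiny peptide whose UNMOD m/z sits below the 350 Th scan floor
  rec <- protein_record("TINY", sequence = "MKGSKAAAAAAAAAAAAAAAAAAAAR")
  sites <- data.frame(accession = "TINY", ordinal = 1L, position = 4L,
                      residue = "S", pattern = "broad", segment = "AAAASAAA",
                      stringsAsFactors = FALSE)
  reps <- data.frame(accession = "TINY", ordinal = 1L, start = 1L, end = 27L,
                     c1 = 1L, c2 = 2L, c3 = 3L, c4 = 12L, c5 = 13L, c6 = 14L,
                     source = "annotated", stringsAsFactors = FALSE)
  pep <- digest(rec, "trypsin", 0L)
  asg <- assign_peptides_to_sites(pep, sites)
  gt <- glycoform_table(asg, reps, list(rec), charges = c(1L, 2L))
  expect_true(all(!gt$quantifiable))
})
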