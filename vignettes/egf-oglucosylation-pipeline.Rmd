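---
title: "Mapping and quantifying O-glucosylation of EGF repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying O-glucosylation of EGF repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfoglc)
```

## The biological problem

Fibrillins (FBN1, FBN2) and latent TGF-β binding proteins (LTBP1) are
extracellular matrix glycoproteins built largely from tandem calcium-binding
EGF repeats — roughly 40-residue domains with six conserved cysteines forming
three disulfides. Two glycosyltransferases, POGLUT2 and POGLUT3, attach an
O-linked glucose to a serine between the third and fourth cysteines of EGF
repeats that carry a short consensus sequence; the same inter-cysteine loop
can also be β-hydroxylated on an Asn/Asp. Because the modified serine lies on
a tryptic peptide, the occupancy ("stoichiometry") of each site can be read
out by LC-MS: for one peptide there are four glycoforms — unmodified, +OH
(β-hydroxylation, +15.994915 Da), +hexose (+162.052824 Da) and
+hexose+OH — and the relative abundance of each is its extracted-ion
chromatogram (EIC) area divided by the summed area of all four.

`egfoglc` implements this workflow end to end as reusable, tested code:

1. **EGF annotation** — locate EGF repeats and their six cysteines, either
   from a UniProt-style feature table (*annotated*) or by a cysteine-spacing
   scan (*detected*), and expose the consensus numbering in which C3 is
   position 1, the canonical 8-residue loop occupies positions 2–9, the
   acceptor serine is position 7, and C4 is position 10.
2. **Consensus prediction** — match the *original*
   (C³-x-N-T-x-G-S-F-x-C⁴), *revised* (F or Y at position 8) and *broad*
   (only S at position 7) glucosylation patterns plus the β-hydroxylation
   pattern (N/D at 3, F/Y at 8) against each loop; scan whole protein sets;
   apply point mutations for consensus-conversion experiments.
3. **Digestion and masses** — in-silico trypsin/V8/chymotrypsin digestion,
   one covering peptide chosen per site, and theoretical monoisotopic
   masses/m/z for all four glycoforms at several charge states, computed
   from elemental compositions.
4. **EIC quantification** — ppm-window ion chromatograms from centroided
   MS1 data (mzML via `mzR`, or the package's JSON run dialect),
   trapezoidal areas, per-site glycoform fractions, replicate means ± SD.
5. **Specificity and logos** — classify each site as POGLUT2-preferred,
   POGLUT3-preferred, redundant or indeterminate from wild-type vs
   single-knockout comparisons, and summarise modified-site loops as
   position frequency matrices with sequence-logo information content.
6. **Synthetic data** — a ground-truth generator and LC-MS run simulator so
   that every stage, and the pipeline as a whole, is testable without any
   download.

## The quantification model

For a site with covering peptide mass $M$ and glycoform deltas
$\Delta_g \in \{0, 15.994915, 162.052824, 178.047739\}$ Da, the targets are
$m/z_{g,z} = (M + \Delta_g + z\,m_p)/z$ with proton mass
$m_p = 1.007276466$ Da. An EIC at tolerance $t$ ppm sums, per MS1 scan, all
centroid intensities within $|m/z - \text{target}| \le t \cdot 10^{-6}
\cdot \text{target}$. Areas are trapezoidal integrals over retention time
(minutes), with no baseline subtraction or peak fitting — the simplest
deterministic reading of "area under the curve". The relative abundance of
glycoform $g$ is $A_g / \sum_h A_h$, with areas first summed over the
configured charge states.

Specificity calls compare the glucosylated fraction
$f = f_\text{HEX} + f_\text{HEX\_OH}$ between conditions. The default rule
calls a site enzyme-preferred when the *relative* reduction
$(f_\text{WT} - f_\text{KO})/f_\text{WT}$ reaches 0.30 in one single
knockout but not the other. The 30% cutoff reflects the 10–20% run-to-run
variability typical of label-free MS quantification; whether "reduced by
30%" should be read as relative or as percentage points is genuinely
ambiguous, so `classify_specificity(mode = "absolute")` computes the other
reading. The relative scale is the default because a site at ~50% wild-type
occupancy that loses almost all glucosylation in one knockout should be
called, which only works cleanly on the relative scale.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| EIC tolerance | 20 ppm | matches the usual high-resolution precursor tolerance |
| scan m/z range | 350–2000 Th | Q-Exactive-style MS1 window |
| charge states | 2+, 3+ (4+ available) | typical tryptic glycopeptide charges |
| max missed cleavages | 2 | standard search-engine setting |
| peptide length cap | 50 residues | longer peptides are poor EIC material in this m/z range |
| specificity threshold | 0.30 (relative) | exceeds typical quantification variability |
| wild-type floor | 0.05 | below it relative reductions blow up numerically |
| replicate rule | n ≥ 2 | mean ± SD are only reported with at least two replicates |

Threonine at consensus position 7 is *not* matched by the glucosylation
patterns by default: T acceptors occur but at very low stoichiometry, and
serine is strongly preferred. `builtin_patterns(allow_thr7 = TRUE)` admits
it for exploratory scans. Loops that are not exactly 8 residues long are
reported as not evaluable rather than force-fit, since the consensus
numbering and all built-in patterns assume the canonical 8-residue loop.

## Numerical and design choices

* **Masses from compositions.** Residue and modification masses are derived
  from monoisotopic atomic masses (H, C, N, O, S), so the carbamidomethyl
  (+57.021464), oxidation (+15.994915), deamidation (+0.984016), ammonia
  loss (−17.026549) and hexose (+162.052824) deltas are consequences of the
  element table, accurate to 1e-6 Da against an independent
  composition-summation oracle.
* **β-hydroxylation placement.** The OH forms are placed on the
  consensus-position-3 Asn/Asp of the same EGF. If the chosen peptide does
  not cover an N/D there, the OH glycoforms are suppressed for that site
  (`oh_enabled = FALSE`) instead of being attributed to an arbitrary
  residue.
* **Charge states must be fully visible.** A charge state contributes to
  quantification only when *all* of the site's glycoform targets fall
  inside the scan range (`charge_in_range`). If, say, only the unmodified
  form of a 2+ peptide were visible, the fractions would be biased toward
  it. Sites with no fully visible charge state are flagged
  `quantifiable = FALSE` — the analogue of a peptide whose unmodified m/z
  is too small for the instrument — rather than being reported as 100%
  modified.
* **Integration windows.** By default a trace is integrated over the full
  run; a per-site peak-window table (`peak_windows()` for synthetic
  studies) restricts integration to the elution window, which both mirrors
  per-peak manual integration and keeps coincidental near-isobaric peptides
  from leaking into each other's areas.
* **Deamidation guard.** Deamidated satellites (+0.984016 Da) are not
  folded into the four-glycoform total, but a warning is raised when the
  satellite of the unmodified peptide carries more than 10% of its area.
* **Detection heuristics.** EGF detection by cysteine spacing uses gap
  ranges C1–C2 3–14, C2–C3 3–12, C3–C4 1–16, C4–C5 1–3, C5–C6 4–23
  residues (covering calcium-binding EGF architecture), greedy
  left-to-right with shortest-match tie-breaking; tandem EGF arrays are
  non-overlapping, so greedy resolution is safe. Both annotated and
  detected modes are first-class because published repeat numbering does
  not always coincide with database domain boundaries; every scan records
  which mode produced its repeats.
* **Logo mathematics.** Information content is
  $R = \log_2 20 - H - e_n$ with the small-sample correction
  $e_n = 19/(2 \ln 2 \cdot n)$, clamped at zero (with very few sequences
  the correction exceeds the uncorrected content).
* **Proline rule.** No cleavage before proline, for all proteases, matching
  the common search-engine default; it can be disabled.

## What the simulator emulates — and what it does not

`synthetic_manifest()` + `simulate_run()` produce centroided MS1 runs in
which each site × glycoform × charge target is a Gaussian elution peak whose
area equals the (condition-transformed) true fraction times the site's total
abundance. Knockout conditions transform the truth exactly as the biology
dictates: removing a site's enzyme(s) moves HEX into UNMOD and HEX_OH into
OH, preserving the hydroxylation marginal; the double knockout abolishes
glucosylation everywhere. Defaults: 1 s scan interval, peak σ = 3 s (0.05
min), retention-time grid spacing 0.4 min (8 σ, so co-isobaric sites cannot
overlap), additive Gaussian intensity noise at 5% of peak height, 3 ppm m/z
jitter, 10⁶ ion-count total abundance per site — sized so a multi-condition,
multi-replicate study simulates in seconds.

The simulator deliberately omits isotope envelopes (targets are
monoisotopic, and so are the simulated centroids), chromatographic tailing
and drift, co-eluting interferences, MS2 spectra and identification error.
Passing the recovery tests therefore demonstrates that the extraction,
integration, normalisation, knockout logic and classification are correct —
not that the pipeline is robust to peak-shape pathology or
misidentification on real instrument data, where integration bounds and
identification quality dominate.

## Problem sizes used in the checks

The recovery properties are exercised on a 9-protein × 12-EGF study (108
quantifiable sites, fractions drawn uniformly on the 4-form simplex):
noiseless maximum absolute fraction error ≤ 0.01, and mean absolute error
≤ 0.05 under the default 5% noise. Specificity recovery uses a 2-replicate,
3-condition study and requires exact recovery of every planted dependency
at wild-type glucosylation ≥ 0.2. Digest/mass invariants run on randomized
sequences against brute-force oracles, and pattern monotonicity
(original ⊆ revised ⊆ broad) on 1000 random loops.

## Reference substrates

The consensus patterns were defined against human FBN1 (UniProt P35555),
FBN2 (P35556) and LTBP1 (Q14766). Those sequences are not shipped;
`scripts/fetch_pinned_substrates.R` downloads the pinned sequence versions
and EGF feature tables once, after which `load_pinned_substrates()` and the
reference-scale tests operate on them (original-pattern predictions of
12/10/5 EGFs; 47/18 repeats for FBN1/LTBP1; 112 repeats in total). Note the
domain-boundary caveat above: published repeat counts assume a particular
EGF numbering convention, which is why both annotation modes exist.

## Known limitations

* Exact numeric replication of published stoichiometries from archived raw
  data is out of scope: manual per-peak integration bounds in vendor
  software are unrecorded, and identifications are taken as given.
* When several N/D residues share a peptide, single-consensus-site
  placement of the β-hydroxyl is an assumption, noted in the output.
* No FDR-controlled identification, no isotope-envelope or retention-time
  modelling, no deconvolution of co-eluting species.

## A minimal worked example

```{r example, eval = FALSE}
man <- synthetic_manifest(n_proteins = 2, egfs_per_protein = 3,
                          seed = 11, replicates = 2)
run <- simulate_run(man, condition = "WT", replicate = 1)
quant <- quantify_run(run, man$targets, peak_windows = peak_windows(man))
summary <- aggregate_replicates(rbind(
  quant,
  quantify_run(simulate_run(man, "WT", 2), man$targets,
               peak_windows = peak_windows(man))))
head(summary)
```
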