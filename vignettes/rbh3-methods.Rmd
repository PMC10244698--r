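---
title: "Methods: rBH3 motif scanning, CSP mapping and FP curve fitting"
author: "rbh3tools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rBH3 motif scanning, CSP mapping and FP curve fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbh3tools)
```

# Scope

`rbh3tools` packages the three computational stages used to characterise a
reverse-BH3 (rBH3) mediated protein-protein interaction, with PTBP1
RRM1 / MCL1 as the motivating system:

1. a **motif scanner** for the conserved BH3/rBH3 residue register in
   protein sequences and domain sets;
2. a **chemical-shift perturbation (CSP)** analysis for apo vs bound
   2D [^1^H,^15^N]-HSQC peak lists, with significance calling, replicate
   consensus and structure mapping;
3. **fluorescence-polarization (FP) binding-curve fitting** with the
   four-parameter logistic (4PL) model for direct and competitive
   titrations.

A seeded synthetic-data generator backs all three stages so that every
analysis step is testable against a known ground truth without any
external downloads.

# The motif model

The BH3 motif of Bcl-2 family proteins presents a conserved acidic residue
(Asp, forming a salt bridge with Arg263 of MCL1) and four hydrophobic
residues H1-H4 that insert into the p1-p4 sub-pockets of the MCL1 groove.
The rBH3 presents the same register in reverse: read C-to-N it aligns with
the forward BH3. We encode both as *position-offset patterns*: a set of
allowed residues at the anchor (offset 0) and at signed offsets from it.

The default offsets are derived from the labelled PTBP1 instance — anchor
E105, H3 A107 (+2), H2 M110 (+5), H1 Y114 (+9) — and mirror the BAK BH3
register (H1/H2/H3 at −9/−5/−2 from the conserved Asp). H4 (−2 for rBH3,
+2 for BH3) is optional: the known rBH3 instances in PTBP1 and
p18/CDKN2C lack a hydrophobic H4, so requiring it would reject the very
motifs of interest. The match `score` is the fraction of optional
positions satisfied.

Allowed residue classes are deliberately conservative:

* anchor `{D,E}` (the rBH3 instances substitute Glu for the canonical Asp);
* H2 `{L,M,I,V,F}` (the documented Leu→Met substitution included);
* H3 `{A,V,I,L,M,F,Y}` (Ala occurs at H3 in the PTBP1 instance);
* H1 and H4 `{A,F,I,L,M,V,W,Y}` (Tyr occurs at H1 in PTBP1).

These sets cover every residue observed at the corresponding positions in
the documented BH3/rBH3 instances without admitting polar residues. They
are defaults, not claims of completeness: `motif_pattern()` accepts any
register. There is deliberately *no* statistical enrichment model, PSSM
score or structure prediction behind the scanner (matches in unstructured
regions are not penalised); the optional `require_helix` filter accepts a
user-supplied secondary-structure string because known rBH3s occur in
pre-formed helices.

```{r motif}
pats <- default_patterns()
pep <- sequence_record("RRM1_rBH3", "NTEEAANTMVNYYTSVTPVLRGQ",
                       numbering_offset = 102)
scan_sequence(pep, pats$rbh3)
```

All overlapping matches are reported (downstream consumers filter);
coordinates are 1-based parent-protein (UniProt) numbering via each
record's `numbering_offset`. `X` parses but never matches a class.

The bundled PTBP1 fixtures (`inst/extdata/`) carry the full-length
sequence and the four RRM domain windows; scanning the domains flags only
RRM1, with the match at anchor 105 / H2 110 / H1 114.

# CSP analysis

## The statistic and peak matching

For each backbone amide the CSP is the ^15^N-scaled euclidean shift
distance, in ppm:

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 5)^2}$$

The same metric defines the distance used to transfer assignments from the
apo to the bound spectrum. `match_peaks()` pairs each assigned apo peak
with its nearest bound peak when (i) the scaled distance is at most the
`cutoff` (default 0.05 ppm — about half a typical linewidth; the source
workflow gives no number, so this is a package default) and (ii) the
pairing is **mutual**-nearest; ties break towards the smaller residue
number, which makes matching fully deterministic. Apo peaks with no
admissible partner are *missing in bound*; unpaired bound peaks are
reported as orphans (candidate side peaks). On resolved spectra this
reproduces the exhaustive minimum-total-distance assignment (a tested
property); on overlapped peaks no coordinate-only matcher is reliable,
which is why assignment transfer in practice is checked against prior
knowledge.

## Reporting conventions and significance

* Matched residues carry their CSP (≥ 0).
* Residues identifiable in apo but not in the bound spectrum carry the
  sentinel **−0.005** with status `missing_in_bound`. The sentinel is a
  plotting convention (it renders as a small negative bar, visually
  distinct from a zero CSP) and **never** enters any statistic.
* Residues expected but unassignable in the apo spectrum are
  `missing_in_apo`: no CSP, excluded from everything.
* A bound peak accompanied by an orphan within 0.10 scaled ppm at an
  intensity ratio ≥ 0.5 (both configurable; the defaults operationalise
  "a side peak of near-equivalent intensity") flags the residue as a
  predominant-`conformation_shift`; such residues are reported but kept
  out of the mean/SD, since their CSP measures the displacement of one
  member of a split resonance.

Per spectrum, the mean and **sample** standard deviation (n−1, matching
the spreadsheet workflow this replaces) are computed over matched residues
only, and a residue is significant when its CSP **strictly exceeds**
mean + 1 SD (`n_sd` configurable; 2 SD never enlarges the set — a tested
monotonicity property). With replicated spectra, `csp_consensus()`
intersects the per-replicate significant sets; only residues significant
in *every* replicate survive, which is the rule used to select residues
for structure mapping.

## Detection limits of the consensus rule

The intersection rule trades sensitivity for specificity. Synthetic
triplicates show that when the injected shift is only ~3-4x the
per-dimension jitter SD (injected CSP ≈ 0.010 ppm against data-driven
thresholds ≈ 0.006), single true residues fall below threshold in one of
three replicates often enough that exact recovery of the injected set
happens in only ~75-80% of seeds. At 6x the jitter (injected CSP ≈ 0.017)
recovery is essentially always exact, and that is the regime the package's
recovery property test exercises. Users should read the consensus set as
high-confidence, not exhaustive.

## Structure mapping

`map_to_structure()` writes per-residue CSPs into the B-factor column of a
PDB file (via `bio3d`) and emits a PyMOL selection sidecar for the
consensus set. The PDB B-factor field is fixed-format with two decimals,
so raw amide CSPs (~0.01 ppm) should be written with `scale = 100`;
the default `scale = 1` keeps B-factors numerically equal to the CSP for
values that survive the format. Residues absent from the coordinates go
to a skip report instead of aborting the run.

# FP binding curves

Both assay modes are fitted with the same 4PL on
$X = \log_{10}(\text{concentration, M})$:

$$Y = \text{bottom} + \frac{\text{top} - \text{bottom}}
      {1 + 10^{(\log EC_{50} - X)\,\text{HillSlope}}}$$

In **direct** mode the titrated binder saturates a labelled probe and the
signal rises (EC50 read as K~D~); in **competitive** mode the titrated
competitor displaces the probe from a preformed complex and the signal
falls (EC50 read as IC50). No Cheng-Prusoff conversion is applied — IC50s
are reported raw.

Numerical choices: Levenberg-Marquardt (`minpack.lm::nlsLM`), multi-start
over Hill slopes {±0.5, ±1, ±2} with bottom/top initialised from the data
range and log EC50 from the concentration nearest the signal midpoint;
best residual sum of squares wins. The 4PL is invariant under swapping the
plateaus and negating the slope, so fits are canonicalised to
top ≥ bottom. Unweighted least squares is the default (per-point weights
optional). Data whose signal range is below a noise floor (default 5 mp)
are rejected as having no dose response rather than fitted. Fits report
asymptotic standard errors, whether the EC50 lies inside the sampled
range, and a **tight-binding flag** in direct mode whenever
EC50 < 2 x probe concentration: there the probe is not trace relative to
the affinity and the 4PL EC50 is only an apparent (upper-bound) K~D~ — the
package deliberately fits no ligand-depletion quadratic model, matching
the source workflow, and the flag marks exactly the regime in which a
"K~D~ below X nM" statement is the honest readout.

Titration designs are generated as n log-equispaced points between the
printed endpoints (`fp_design()`); for the eight-point 1 nM-3 µM and
ten-point 30 pM-1 µM designs this is exactly a half-log dilution ladder,
and for the seven-point designs it is the closest even spacing to the
printed range (whose printed point count and endpoints are not mutually
consistent with exact half-log steps).

```{r fit}
design <- fp_design(3e-10, 3e-6, 7)
g <- gen_titration("competitive",
                   c(bottom = 40, top = 120, log_ec50 = log10(8.8e-8),
                     hill = -1),
                   design, noise_sd = 2, replicates = 1, seed = 42)
fit <- fit_titration(g$series[[1]])
fit
summarize_displacement(fit)$estimate_nM
```

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Sequences** (`gen_sequences()`): uniform composition over the 20
  residues (no proteome frequency model), optional implants that satisfy
  the pattern exactly; `clean_background` rejection-samples accidental
  matches so truth sets are unambiguous.
* **Peak lists** (`gen_peaklist_pair()`): apo peaks uniform in the folded
  amide envelope (^1^H 7.0-9.5 ppm, ^15^N 105-130 ppm) with a minimum
  pairwise scaled separation of 0.06 ppm — the generator emulates a
  resolved, assignable spectrum, because assignment transfer between
  overlapped peaks is ill-posed for any coordinate-only matcher. Bound
  peaks add the injected shift, Gaussian jitter (defaults 0.002 ppm ^1^H,
  0.01 ppm ^15^N), dropouts and unassigned side peaks. Bound lists are
  unassigned, as after a real titration.
* **Titrations** (`gen_titration()`): 4PL plus Gaussian noise, default
  σ = 2 mp.

Defaults were chosen once to make the published effect sizes comfortably
detectable at realistic noise; they are all arguments. Every generator is
bit-deterministic under its seed and emits a truth record sufficient to
score the downstream stage.

What passing synthetic tests does **not** show: robustness to peak
overlap, exchange broadening or intensity loss in real spectra; FP
artifacts (quenching, nonspecific binding, depletion); or motif scanning
specificity on real proteome backgrounds with biased composition. The
problem sizes used in the shipped tests (up to 200 Monte-Carlo titration
fits per design, 60-residue peak lists, 100 scanned sequences) were chosen
as comfortably informative at interactive runtimes.

# Known limitations

* Register offsets and residue classes are calibrated on two documented
  instances (PTBP1 rBH3, BAK BH3); true registers of other rBH3 proteins
  may differ.
* Only nearest-neighbour assignment transfer is implemented; the
  complementary "comparison to previous analysis" step of a manual
  workflow has no automated counterpart here.
* Direct-mode fits in the tight-binding regime report apparent K~D~ only.
* The NMR-STAR reader covers assigned chemical-shift loops (the deposited
  form of HSQC peak lists), not full spectral-peak loops or multiline
  values.
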