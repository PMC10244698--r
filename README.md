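# rbh3tools

Analysis toolkit for **rBH3-mediated protein–protein interactions** — the
class of interaction in which a folded, helical sequence presenting the
conserved BH3 residues in *reverse* order (an rBH3 motif) binds the
BH3-binding groove of the prosurvival Bcl-2 family protein MCL1. The
motivating system is the first RNA recognition motif (RRM1) of the
splicing regulator PTBP1, whose α2-helix rBH3 binds MCL1; MCL1 binding in
turn perturbs the RNA-contact sequences (RNP1/RNP2) on the opposite face
of the domain and displaces target RNA.

The package is aimed at structural biologists and biochemists who want to
run, or critically re-run, the three computational stages of such a
characterisation:

1. **Motif scanning.** The BH3/rBH3 register is encoded as a
   position-offset pattern: an acidic anchor (D/E, the Arg263 salt-bridge
   partner) plus hydrophobic positions H1–H4 that engage the p1–p4
   sub-pockets of the MCL1 groove. For the rBH3, H3/H2/H1 sit at +2/+5/+9
   from the anchor (H4, optional, at −2); the forward BH3 is the exact
   mirror. `scan_sequence()` / `scan_domains()` report all matching
   placements in parent-protein numbering.

2. **Chemical-shift perturbation (CSP) mapping.** For apo vs ligand-bound
   ¹⁵N-HSQC peak lists, per-residue CSPs are computed as
   √(Δδ_H² + (Δδ_N/5)²) after mutual-nearest-neighbour assignment
   transfer. Residues identifiable in apo but not in the bound spectrum
   are reported with the −0.005 sentinel (a plotting convention, excluded
   from all statistics). Significance is CSP strictly above mean + 1·SD
   (sample SD over matched residues); replicated spectra are combined by
   set intersection, and the consensus can be written into PDB B-factors
   for structure colouring.

3. **Fluorescence-polarization (FP) curve fitting.** Direct (saturation)
   and competitive (displacement) titrations are fitted with the
   four-parameter logistic on X = log₁₀ [titrant]:

   `Y = bottom + (top − bottom) / (1 + 10^((logEC50 − X)·HillSlope))`

   with multi-start Levenberg–Marquardt. Direct-mode EC50 is the
   (apparent) K_D, competitive-mode EC50 the IC50; a tight-binding flag
   marks fits where EC50 < 2 × probe concentration, i.e. where the fitted
   value is only an upper bound on K_D.

A fully seeded **synthetic-data generator** (`gen_sequences()`,
`gen_peaklist_pair()`, `gen_titration()`) produces ground-truthed inputs
for every stage, so the whole pipeline is testable at desk scale. See the
methods vignette (`vignettes/rbh3-methods.Rmd`) for the models,
assumptions and numerical choices.

## Worked example

```r
library(rbh3tools)
pats <- default_patterns()

# 1. Scan the PTBP1 rBH3 peptide (parent numbering starts at residue 102)
pep <- sequence_record("RRM1_rBH3", "NTEEAANTMVNYYTSVTPVLRGQ",
                       numbering_offset = 102)
scan_sequence(pep, pats$rbh3)
#>   sequence_id anchor_position anchor_residue H1_position H1_residue H2_position
#> 1   RRM1_rBH3             105              E         114          Y         110
#>   H2_residue H3_position H3_residue H4_position H4_residue h4_satisfied score
#> 1          M         107          A         103          T        FALSE     0
```

One match: anchor E105 with H2 = M110 and H1 = Y114 — the rBH3 register on
the α2 helix. `h4_satisfied = FALSE` records that this rBH3 (like the
p18/CDKN2C one) has no hydrophobic H4.

```r
# 2. Fit a simulated competitive displacement titration (true IC50 88 nM,
#    seven points 300 pM - 3 uM, 2 mp noise)
g <- gen_titration("competitive",
                   c(bottom = 40, top = 120, log_ec50 = log10(8.8e-8),
                     hill = -1),
                   fp_design(3e-10, 3e-6, 7), noise_sd = 2, seed = 42)
fit <- fit_titration(g$series[[1]])
fit
#> <fp_fit> competitive mode: EC50 = 8.31e-08 M (log10 = -7.080), hill = -1.061
#>   plateaus: bottom 42.7, top 120.5 mp; RSS 11.1
summarize_displacement(fit)$estimate_nM
#> [1] 83.1
```

A single noisy seven-point curve recovers the generating IC50 to within a
few percent (83.1 vs 88 nM); medians over replicate simulations land on
the true value (see below).

```r
# 3. CSP triplicate with three injected shifts
g0 <- gen_peaklist_pair(60, seed = 11)                  # learn the labels
shift <- g0$apo$label[c(10, 20, 30)]
g2 <- gen_peaklist_pair(60, shift_residues = shift,
                        shift_magnitude = c(0.012, 0.06),
                        replicates = 3, seed = 11)
summaries <- lapply(g2$bound, function(b) summarize_csp(csp_table(g2$apo, b)))
summaries[[1]]
#> <csp_summary> n=60 matched, mean=0.0031 ppm, sd=0.0036 ppm
#>   thresholds: mean+1SD=0.0066, mean+2SD=0.0102
#>   significant (> mean+1SD): G16, I30, M20, Q10
csp_consensus(summaries)
#> [1] "I30" "M20" "Q10"
```

Replicate 1 alone also calls a noise residue (G16); the all-replicates
intersection removes it, returning exactly the three injected residues.

Bundled fixtures under `inst/extdata/` include the PTBP1 sequence with the
four RRM windows: scanning them flags **only RRM1** as rBH3-containing.
A command-line wrapper for the scan/csp/fit/simulate stages is installed
at `system.file("scripts", "rbh3.R", package = "rbh3tools")`.

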