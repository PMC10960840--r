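---
title: "Methods: ion-mobility glycomics of mucin-type O-glycan alditols"
author: "glycomob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion-mobility glycomics of mucin-type O-glycan alditols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomob)
```

## The problem

Mucins carry dense mucin-type *O*-glycosylation: glycans extended from a
GalNAc that is α-linked to Ser/Thr. Released by reductive β-elimination,
they become alditols (open-chain reduced ends, +H₂O +2H relative to the
residue sum), which prevents peeling and anomer splitting. The analytical
difficulty is isomerism — identical compositions differing in core
topology (eight cores on the root GalNAc-ol), linkage position (1-3 vs
1-6, type I vs type II chains) and anomericity. Ion mobility
spectrometry separates such isomers in minutes and yields a collision
cross section (CCS, Å²), an instrument-independent molecular property
that can replace irreproducible porous-graphitized-carbon LC retention
times as the identification coordinate.

`glycomob` implements the computational side of that workflow: mass and
composition arithmetic, CCS calibration for trapped (TIMS) and
travelling-wave (TWIMS) instruments, mobilogram deconvolution and isomer
quantification, negative-mode fragment annotation with core scoring,
CCS-library matching, and sample-level profiling. Synthetic-data
generators make every stage testable without instrument data.

## Mass arithmetic

All masses are monoisotopic, assembled from atomic masses to well beyond
six decimals. Residue (dehydrated monomer) masses follow from elemental
formulas — Hex C₆H₁₀O₅ (162.052823 Da), HexNAc C₈H₁₃NO₅ (203.079373 Da),
dHex C₆H₁₀O₄ (146.057909 Da), NeuAc C₁₁H₁₇NO₈ (291.095417 Da); sulfation
adds SO₃ (79.956815 Da) as a count, not a residue, because position
information for sulfate is rarely available from MS alone. A reduced
composition's neutral mass is

```
M = Σ count·residue + n_S·SO₃ + H₂O + H₂
```

and negative-mode ions are [M − zH]⁻ with the 1.007276 Da proton
convention (electron mass folded in), so computed m/z values match the
convention used when annotating deprotonated glycan spectra.
`search_compositions()` enumerates the full bounded count lattice
(defaults Hex ≤ 8, HexNAc ≤ 8, dHex ≤ 4, NeuAc ≤ 4, S ≤ 2, covering the
≲2500 Da range of mucin alditols) and filters by a ppm tolerance and the
biosynthetic constraint HexNAc ≥ 1 (every mucin-type alditol contains
the root GalNAc). The tolerance default of 10 ppm is our own choice for
TOF-class mass accuracy; it is a parameter everywhere. Doubly
deprotonated ions are expected only above 1200 Da (`allowed_charges()`),
with the threshold inclusive below and overridable.

## Structures, cores, motifs

Structures are condensed IUPAC-like strings,
`Fuc(a1-2)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol`, parsed into residue trees.
We chose this text form over GlycoCT for readability in CSV libraries;
`?` encodes unknown anomer/position and acts as a wildcard in matching,
since MS/MS cannot always fix them. Canonical serialisation orders
branches by linkage position (lowest first as the main chain), which
makes tree equality and round-tripping testable; sialic acids link
through their anomeric C2 (`Neu5Ac(a2-3)`), so the grammar accepts
anomeric carbons 1 and 2. Core classification matches only the residues
directly attached to GalNAc-ol against the eight standard templates
(core 1 Galβ1-3; core 2 Galβ1-3 + GlcNAcβ1-6; core 3 GlcNAcβ1-3; core 4
GlcNAcβ1-3 + GlcNAcβ1-6; core 5 GalNAcα1-3; core 6 GlcNAcβ1-6; core 7
GalNAcα1-6; core 8 Galα1-3), so extensions never change the label; the
core 5–8 templates follow the standard definitions and are replaceable
via the `templates` argument because they are conventionally drawn, not
universally fixed, in the literature. Motif detection flags the blood
group H epitope (Fucα1-2→Gal), type I (Galβ1-3→GlcNAc) and type II
(Galβ1-4→GlcNAc) chains, and composition-level sialylation/fucosylation.

## Negative-mode fragments and core scoring

Glycosidic cleavages follow Domon–Costello bookkeeping: B = non-reducing
residue sum, C = B + H₂O, Y = reducing side + H₂O (+2H when the alditol
is retained), Z = Y − H₂O; B+Y and C+Z reconstruct the precursor
exactly, which is enforced as an invariant test. Cross-ring A-type ions
carry the linkage information; their masses are the C-ion equivalent of
the cleaved residue plus an offset from a configurable table. The
defaults are the classic 0,2A (−C₄H₈O₄, −120.042259 Da) and 2,4A
(−C₄H₈O₄−C₂H₄O₂, −180.063388 Da) cleavages of Hex/HexNAc/dHex rings,
computed from elemental formulas; NeuAc gets no default A ions. With
`max_cleavages = 2`, internal fragments are labelled with compound kinds
(`"Y/Y"`, `"B/Y"`, …). Only 1− fragments are generated, matching the
predominantly singly deprotonated precursors.

Diagnostic scoring is rule-based. `derive_diagnostic_rules()` builds,
for each candidate structure, the set of fragment masses absent from
every candidate carrying a *different* label; a rule fires only when all
its discriminating fragments are observed. Discrimination is against
competing labels rather than all other candidates because pure linkage
isomers of the same core (e.g. type I vs type II extensions) can share
their entire glycosidic mass set — evidence for the shared core should
not cancel. Rules are plain lists and can be hand-written or loaded from
JSON/YAML, since the literature does not enumerate exactly which
cross-ring ions separate each core pair; the engine is deliberately
configurable on this point.

## CCS calibration

TWIMS drift times are first EDC-corrected, t_D′ = t_D − C·√(m/z)/1000
with the instrument constant C = 1.41 by default, and calibrated by an
unweighted least-squares line in log space, ln CCS′ = lnA + B·ln t_D′,
against calibrants of known drift-tube CCS. Weighting is not applied
because no weighting scheme is standard for this curve. The
mass/charge correction is CCS′ = CCS·√µ/z with reduced mass
µ = mM/(m+M). Whether m is the bare deprotonated ion mass (mz·z) or its
neutral equivalent (mz·z + z·1.007276) is a convention the field leaves
implicit; we default to the neutral equivalent and expose
`mass_convention = "ion"` — the difference is below 0.2 % of √µ for
glycan-sized ions. The drift gas default is the average N₂ molecular
mass 28.0134 Da (switchable to monoisotopic 28.00615). TIMS reversed
mobilities 1/K₀ are proportional to CCS′ (Mason–Schamp), so the default
fit is a zero-intercept line; a free intercept is available because an
affine fit is sometimes preferred, and forcing the origin on truly
affine data leaves a visible residual pattern that the calibration
object retains for inspection. Cross-instrument agreement is summarised
by the two-value %STD, |a−b|/√2 divided by the pair mean; sub-1 %
agreement between TIMS and TWIMS CCS values of the same structure is
the benchmark for treating libraries as transferable, and 0.5 % (half
that bound) is the default library-matching CCS tolerance.

Reference CCS values for real dextran ladders are instrument-lab data
not shipped here; the packaged calibrant table is synthetic (named so),
generated from a square-root size law CCS = 9.5·√m anchored near 285 Å²
at 900 Da — the compact-carbohydrate regime — and all calibration tests
use such synthetic ladders by design.

## Mobilograms and deconvolution

`extract_eim()` sums frame intensity within an m/z window on the native
mobility grid (or 1000 fixed-width bins when the frame is not gridded),
conserving total intensity. `detect_peaks()` fits 1..k Gaussian
mixtures by Levenberg–Marquardt least squares, selects the component
count by BIC (n·log(RSS/n) + 3k·log n), and discards components whose
amplitude is below `min_snr` times the noise (MAD of residuals).
Starting centroids come from local maxima of a Savitzky–Golay-smoothed
trace; further components seed at the largest residual, so fits are
deterministic. Vendor software performs this step undocumented; BIC
with an MAD noise floor is our explicit, testable replacement. Areas
are A·σ·√(2π); isomer abundances are areas as percentages of the summed
area at the same m/z. Charge gating assigns frame points to per-charge
mobility trendline bands (linear centre ± half-width) and refuses
overlapping bands. Resolving power is CCS/FWHM with
FWHM = 2√(2 ln 2)·σ in CCS space.

The canonical validation scenario is four isomers of the
dHex₁Hex₂HexNAc₂ alditol (m/z 895.34) at CCS 273, 275, 290 and 297 Å²,
taken through a synthetic TIMS calibration of slope 1250 Å²·(V·s/cm²)⁻¹
— chosen so dextran-like calibrants and these analytes all fall inside
a 0.6–1.6 V·s/cm² scan window. Peak widths use σ(CCS) = 0.6 Å²
(resolving power ≈ 190, mid-range for TIMS and narrow enough that the
2 Å²-spaced pair shows a dip, as resolved instrument data does), with
1 % multiplicative noise, on a zoomed 1.0–1.4 V·s/cm² window of 1000
grid points so each peak spans ~6 samples as on native instrument
sampling. Recovery to <0.5 Å² centroid error and <5 % area error, and
correct core-1/core-2 ranking of the four structures from their own
noiseless fragment spectra, are asserted in the test suite.

## Libraries and profiling

Library CSVs carry fixed columns (composition, structure, z, mz,
ccs_tims, ccs_twims, source, accession); unknown extra columns pass
through untouched so exports from external databases load best-effort.
Validation rejects rows whose m/z disagrees with their composition by
more than 5 ppm or that carry no CCS. Matching ranks candidates within
joint tolerances by d = √((Δppm/tolₘ)² + (ΔCCS%/tol_c)²). The packaged
49-record demo library is synthetic — typical porcine-gastric-mucin
compositions with about two isomers each and plausible CCS values
agreeing across instruments well under 1 % — built for examples and
tests, not measured data.

Profiles aggregate assigned peaks per sample. Core grouping reports
cores 1–4 individually and folds rarer cores and unassigned structures
into "other"; percentages are of summed mobility area and total 100.
Feature grouping (sialylated, fucosylated, sulfated) counts a peak once
per feature it carries, so the three bars can exceed 100 % combined —
features are reported independently. Summaries are computed over
assigned peaks (the default; switchable by constructing the profile
differently) and are invariant under uniform area scaling. The isomer
ratio comparator matches peaks across samples by CCS order at each m/z
and flags rank-order inversions — the situation where the dominant
isomer in one sample is the minor one in the other. No statistical
testing is attempted: single-sample comparisons admit none.

## Synthetic data and what passing tests show

Generators take mandatory seeds, restore the caller's RNG state, and
return their ground truth alongside the data; oracle comparisons never
re-derive truth from data. Intensity noise is multiplicative log-normal
(mass-spec-like heteroscedasticity). The frame generator emulates an
accumulated direct-infusion frame: Gaussian mobility profiles at exact
theoretical m/z. It does not emulate isotope envelopes, chimeric
spectra, fucose migration, tailing peak shapes, detector saturation or
m/z error — so green tests demonstrate the correctness of the
algorithms under their stated model, not robustness to every instrument
artifact. Problem sizes in the suite (≤1000-point grids, ≤100 random
trees/targets, 8–9-point calibrant ladders) were chosen as the smallest
sizes at which the asserted tolerances are meaningful.

## Known limitations

- Glycosidic masses cannot separate pure linkage isomers; with the
  default offset table the cross-ring ions are position-independent
  too, so distinguishing, e.g., β1-3 from β1-4 extensions requires a
  hand-curated rule set or relies on CCS.
- The structure grammar does not place sulfates on residues; sulfation
  is composition-level.
- mzML reading (via mzR) is a best-effort convenience; CSV triples are
  the canonical, tested input path.
- TIMS transit-time-to-1/K₀ conversion is vendor-internal and out of
  scope; frames are expected already in 1/K₀ (or drift-time) form.
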