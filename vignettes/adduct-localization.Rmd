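---
title: "Methods: adduct mass arithmetic, site localization and depletion kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adduct mass arithmetic, site localization and depletion kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napadduct)
```

`napadduct` analyzes covalent adducts of reactive naphthalene metabolites
on model peptides from high-resolution MS/MS data. This vignette is the
package's own account of the underlying model, the choices made where the
design was genuinely open, and what the bundled tests do and do not
demonstrate.

## Mass model

All arithmetic is monoisotopic. Element masses are the IUPAC values to at
least six decimals (¹H 1.0078250319, ¹²C 12 exactly, ¹⁴N 14.0030740052,
¹⁶O 15.9949146221, ³²S 31.97207069) and the proton mass constant
(`proton_mass`, 1.007276 Da) converts neutral masses to singly-protonated
m/z. Only 1+ ions are modeled: every annotated species in the reference
experiments — peptides of 7–8 residues on an Orbitrap in positive mode —
was singly charged, and `simulate_spectrum()` emulates the same regime.

The four adduct species are defined by elemental deltas: the 1,2-epoxide
adds C₁₀H₈O, the diol epoxide C₁₀H₁₀O₃, and either naphthoquinone
C₁₀H₆O₂ in the reduced hydroquinone state. The diol-epoxide composition
follows from epoxide ring-opening addition retaining both diol oxygens;
it is the only composition consistent with the reported nominal shift of
+178.06 Da. The nominal shifts are treated as rounded monoisotopic
masses (an Orbitrap context), not averages. For the quinones, a
`variant = "quinone"` delta two hydrogens lighter is computable because
oxidized (quinoid) adduct states are chemically plausible and some
multi-adduct precursors sit below all-hydroquinone theory; the package
computes both states and asserts neither for those ambiguous species.

Fragments follow standard CID conventions: `b_i` = sum of the first *i*
residue masses + proton; `y_j` = sum of the last *j* residue masses +
terminus (H₂O for a free acid, NH₃ for a C-terminal amide) + proton. A
fragment carries exactly the placement adducts inside its span, with the
N-terminal amine (site 0) belonging to b ions only. `theoretical_ions()`
also generates the neutral-loss precursor species seen for these adducts:
loss of water and loss of one or more intact adduct moieties ("X").
A-ions, immonium ions, internal fragments and fragment-level adduct
losses are not generated; none were needed to interpret the reference
spectra. Water-gain/-loss fragment satellites (e.g. dehydrated adducted
b ions) exist behind `water_satellites = TRUE`, off by default because
they are non-canonical and would otherwise inflate the hypothesis space.

## Placements

A placement assigns *n* ≤ 3 copies of one adduct species to allowed sites:
the N-terminal amine plus Cys/Lys/His side chains (the target table in
`inst/extdata/adducts.tsv` is data, so other site rules can be swapped
in). A site may carry at most two moieties, and more than one only for a
naphthoquinone on cysteine — the only doubly-adducted single residue for
which fragment evidence exists (doubly-shifted y ions covering the Cys).
Mixed-species placements are not modeled; no mixed adduct was observed.
Proline and other side chains are non-targets by default: their adduction
cannot be excluded in principle, but the reactivity evidence makes them
unlikely preferred sites, and the undetermined-interval reporting (below)
keeps that caveat visible.

## Annotation

`annotate_peaks()` performs greedy one-to-one matching: candidate
peak–ion pairs within tolerance are ranked by |ppm| (ties broken by lower
theoretical then observed m/z) and accepted while both partners are free.
The default tolerance is 10 ppm — generous against the few-ppm accuracy
of a 30,000-resolving-power instrument, tight enough that uniform noise
peaks almost never match. An absolute `tol_da` override exists for
matching values printed at two decimals. Intensity is carried through but
never used: no intensity thresholds are defensible for the reference
data, and the simulator deliberately draws noise-peak intensities below
the median true-ion intensity so that intensity-blind matching remains
the hard case. One-to-one rather than all-within-window assignment
mirrors single-assignment annotation practice; whether near-isobaric b/y
coincidences should be deduplicated differently is unresolved, and the
greedy-|ppm| order is this package's policy.

## Localization

`feasible_sites()` keeps a placement iff every annotated b/y ion carries
exactly the adduct count the placement implies. In the default **strict**
mode unmodified fragments constrain too — the reference interpretations
repeatedly use unmodified ions as bounds. **Lenient** mode constrains
only adduct-shifted ions, because unmodified fragments can also arise
from a co-eluting unadducted peptide or positional isomer; several
reference monoadduct spectra do contain unmodified fragments that
contradict the adducted series under strict counting, which is exactly
the situation lenient mode names.

`localize()` layers judgment on the feasible set:

* One placement left → `unambiguous`.
* Several single-adduct candidates → the configurable reactivity ranking
  (`reactivity_ranking()`: quinones Cys > N-term > Lys > His; epoxides
  Cys > His > Lys > N-term) assigns the top-ranked site *only when that
  class is uniquely ranked* (`interval_resolved_by_reactivity`);
  rank-ties (e.g. two lysines) stay `undetermined`.
* An empty feasible set (self-contradictory strict evidence) is
  `undetermined`, and the reported interval is recomputed from the
  lenient feasible set so the adduct-bearing region is still described.
* No adduct-shifted **fragment** annotation → `undetermined`, always.
  Precursor-level adduct evidence (shifted [M+H]⁺ or its neutral losses)
  proves adduction happened but says nothing about where; making a site
  call from reactivity alone in that situation would dress prior belief
  up as measurement. This rule is why spectra whose printed fragment
  values deviate too far from theory to annotate come out undetermined
  rather than reactivity-assigned.

The interval reported is the minimal contiguous site range covering the
candidate sites (0 denotes the N-terminus), matching the way undetermined
assignments are conventionally described (e.g. "one of the three
C-terminal residues").

`oracle_feasible_sites()` is a deliberately independent implementation —
exhaustive enumeration plus direct m/z comparison against regenerated ion
sets — used by the test suite to cross-check the count-based logic over
48,000 seeded random evidence sets (six peptides × four adducts ×
n ∈ {1,2} × 1000 sets).

## Kinetics

The SIM depletion experiments are qualitative in origin; the
pseudo-first-order model here is this package's formalization, chosen as
the simplest mechanism consistent with an excess-electrophile incubation.
`fit_depletion()` fits a least-squares line through (t, ln A/A₀) — slope
−k, intercept free so that time-zero noise does not bias the rate — and
clamps k at zero. Because the model is an extension, the model-free
fraction remaining at the last time point (`f_end`, the "% remaining at
8 min" framing of the source experiments) is always reported alongside.
Control-drift correction divides the signal pointwise by the control's
fraction remaining; a control identical to the signal therefore yields
k = 0 exactly. Zero areas are excluded from the log fit with a warning;
fewer than three positive points is an error. `compare_depletion()`
declares one course faster than the next only when approximate 95%
intervals (k ± 1.96·se) are disjoint — a deliberately conservative rule
given six-point grids.

## The simulator and what passing tests mean

`simulate_spectrum()` draws Gaussian m/z error (default σ = 2 ppm),
i.i.d. ion dropout (default 0.2), and uniform noise peaks (default 20)
inside the m/z 200–1500 instrument window, with log-uniform true-ion
intensities; `simulate_depletion()` uses the experimental time grid
{0, 0.5, 1, 2, 4, 8} min, linear control drift (default 3.6% over the
course, the loss observed for the stable control peptides; 15% emulates
the cysteine peptide) and multiplicative lognormal noise (default CV
5%). All generators are reproducible from their parameters and seed
alone. These defaults are the study conditions the test suite asserts
under: site recovery ≥ 90% over 100 seeds per peptide case, and median
relative error of k̂ below 10% over 200 simulated courses.

The simulator does *not* emulate isotopologue envelopes, chimeric
spectra, charge states above 1, correlated (calibration-drift) mass
error, intensity-dependent dropout, or retention-time structure. Passing
its tests shows the inference is correct under the stated error model,
not that real spectra of arbitrary complexity will localize as reliably.

## Numerical choices and degenerate inputs

* Printed-table reproduction uses an absolute 0.011 Da bound: 0.005 for
  two-decimal rounding plus ~5 ppm observed error at m/z ≈ 1200. Curated
  entries whose printed values deviate further are flagged in
  `inst/extdata/printed_ions.tsv` with per-entry notes (internally
  inconsistent value families, redox-ambiguous multi-adduct species, and
  a few presumed misprints) and excluded from the reproduction test.
* Matching ties are broken deterministically (lower theoretical, then
  observed, m/z); annotation output is invariant to peak order.
* Empty evidence leaves every placement feasible; contradictory evidence
  returns an empty set rather than raising; `n = 0` pipelines flag
  "no adduct evidence".
* Fits on noiseless exponentials recover k to numerical precision; the
  perfect-fit warning from `lm()` is suppressed as that case is
  legitimate here.

## Problem sizes in the test suite

The bundled suite runs the full oracle-equivalence sweep (48,000 evidence
sets), 600 end-to-end noisy-spectrum recoveries (six cases × 100 seeds)
and 200 kinetics recoveries — sizes chosen so the whole suite completes
in about a minute on one core while keeping Monte-Carlo assertions
well away from their thresholds.

## Known limitations

Charge states above 1, isotope envelopes, fragment-level adduct losses,
probabilistic localization scores (Ascore-style), chromatographic
separation of positional isomers, and raw-file/mzML input are out of
scope. The reactivity ranking is qualitative prior knowledge, not a
fitted quantity — which is precisely why it is shipped as data and why
`interval_resolved_by_reactivity` is reported as a distinct, weaker
confidence class.
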