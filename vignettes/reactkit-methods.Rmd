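---
title: "Methods: mass annotation, reactivity descriptors and DPPH IC50 estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass annotation, reactivity descriptors and DPPH IC50 estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactkit)
```

reactkit chains four desk-scale computations that together make up the data
analysis of a typical natural-product antioxidant study: tentative LC-MS
identification by exact mass, conceptual-DFT reactivity descriptors,
DPPH dose–response analysis, and descriptor–activity rank correlation. This
vignette records the models behind each stage, the parameters that matter,
the numerical choices, and what the synthetic-data generators do and do not
emulate.

## Monoisotopic mass and ppm annotation

An elemental formula is a multiset of element counts with an optional +1
charge (`"C18H22NO5+"`). `monoisotopic_mass()` sums count × monoisotopic
atomic mass over a fixed table embedded in the package
(`atomic_masses()`; C = 12 exactly, H = 1.00782503, N = 14.00307401,
O = 15.99491462, …). Embedding the table, rather than depending on an
external element database, keeps calculated masses bit-reproducible across
installations; the table is versioned with the package and extendable.

Two conventions deserve note:

* **Electron correction.** The physically strict mass of a cation is the
  atomic-mass sum minus one electron mass (0.00054858 Da) per unit charge.
  Published "calculated for" values for protonated natural products are,
  in practice, plain atomic-mass sums of the cation formula written as
  `[M+H]+`, so the correction defaults to off and is exposed as
  `electron_correction = TRUE` for users who want the strict value. At
  *m/z* 300 the difference is about 1.8 ppm — larger than a modern
  instrument's calibration error, so which convention a table used is
  detectable from the data.
* **ppm sign and print precision.** `ppm_error()` returns the signed value
  (observed − calculated)/calculated × 1e6; comparisons with tables that
  print non-negative errors use the absolute value. Published tables also
  typically print the calculated mass at 4 decimals, and their ppm column is
  then consistent with the *rounded* calculated mass rather than the
  full-precision one. The package computes at full precision by default;
  when checking against a printed table, round the calculated mass first
  (`round_half_up(calc, 4)`), which is what the test suite does for the
  twelve-peak reference table (eleven of its twelve printed ppm values are
  reproduced exactly under that convention, versus roughly half at full
  precision).

`annotate_peaks(peaks, library, tolerance_ppm)` is a dense search: every
peak is compared against every candidate (peak lists and candidate
libraries at this scale are tens of rows, so no indexing is warranted).
Candidates within tolerance are ranked by |ppm error| with ties broken
lexicographically by name, so output is deterministic; peaks with no
candidate in tolerance remain in the output as unannotated rows. Only
singly charged cations are modelled — every species in the motivating data
is a +1 cation — and multiply charged markers are rejected rather than
silently mis-handled. Isotope patterns, adducts other than the
cation-as-written, and MS/MS fragments are out of scope.

## Energy-vertical reactivity descriptors

`compute_descriptors()` implements the energy-vertical method: with
single-point energies of the cation and anion *at the neutral geometry*,

* I = E(cation) − E(neutral), A = E(neutral) − E(anion),
* hardness η = (I − A)/2, softness σ = 1/(2η),
* electronegativity χ = (I + A)/2, chemical potential μ = −χ,
* electrophilicity Ω, electrodonating ω⁻ = (3I + A)²/(16(I − A)) and
  electroaccepting ω⁺ = (I + 3A)²/(16(I − A)).

All descriptors are reported in eV. Energies tagged `hartree` are converted
exactly once with the CODATA-2018 factor 27.211386245988 eV/hartree
(`hartree_to_ev()`).

**The Ω variant.** The canonical Parr electrophilicity is μ²/(2η). The
study this package reproduces prints and tabulates μ²/2 instead — a
deliberate reproduction target, not an error in this package — so
`variant = "paper"` (default) puts μ²/2 in the `omega` column while the
Parr form is always available as `omega_std`. Set `variant = "standard"`
to make `omega` the Parr form.

**Degenerate and unusual inputs.** I = A makes η = 0, so σ, ω⁻ and ω⁺ are
undefined: the functions raise a degenerate-hardness error rather than
return infinities. I < A (negative hardness) is computed with a warning —
it can occur with vertical energies on unrelaxed ions. Negative electron
affinities are legitimate vertical values (two of the reference compounds
have them in gas phase) and are never clamped.

**Identities as tests.** μ = −χ and ω⁻ − ω⁺ = χ hold algebraically; the
suite verifies them to 1e-9 eV over 10⁴ random (I, A) pairs, and verifies
that the hartree and eV input paths agree to 1e-9 eV.

**Known irregularities in the reference table.** Recomputing the reference
descriptor table from its own printed I and A reproduces the internally
consistent cells to within 5×10⁻⁴ eV (plus the half-unit quantisation of
each printed cell). Two irregularities are documented and handled
explicitly rather than guessed at: the softness and electronegativity rows
are transposed for part of the table (the printed "σ" equals (I+A)/2 and
the printed "χ" equals 1/(2η) there), and one printed chemical-potential
cell contradicts μ = −χ against its own χ by 1e-3 (treated as a typo). The
package always computes per the equations; the acceptance tests encode the
transposition when comparing.

`extract_scf_energy()` parses only one fixture log dialect — the last line
matching `SCF Done: ... <value> A.U.` — because real QM output formats vary
too much to parse generically; running or wrapping a QM program is out of
scope, and energies are inputs, not results, of this package.

## DPPH dose–response and IC50

`percent_inhibition(blank, sample)` is the relative loss of DPPH absorbance
at 517 nm: (A_blank − A_sample)/A_blank × 100. It is strictly decreasing in
the sample absorbance and invariant to rescaling both absorbances, which
the suite checks. Values outside [0, 100] are *flagged, never clipped*:
clipping would bias the IC50 whenever the curve approaches the extremes.

`build_curve()` aggregates replicate records per concentration (mean, with
per-replicate values retained), and `estimate_ic50()` offers three curve
readings:

* `"bracket"` (default): linear interpolation between the two consecutive
  concentrations straddling 50%. This is the most conservative reading of
  "IC50 obtained from plotting concentration against % inhibition" — it
  assumes nothing about the functional form. Non-monotone curves that cross
  50% more than once use the first crossing, with a warning.
* `"linear_ls"`: a least-squares line through all points, solved for 50%.
* `"4pl"`: a four-parameter log-logistic (Hill) fit,
  inhibition = bottom + (top − bottom)/(1 + (mid/c)^hill), reporting the
  concentration at which the fitted curve reaches 50%. A logistic is a
  different family from a straight line, so on noiseless *linear* data
  `"4pl"` agrees with the other two only approximately (to about 0.1% on a
  symmetric design), whereas on noiseless logistic data it recovers the
  midpoint to solver precision; the tests assert exactly these properties.

Interpolation is on the linear concentration axis (matching how such
curves are plotted in the assay literature at these concentration ranges);
concentrations are nominal sample concentrations, without the 10/210
in-well dilution correction, since published IC50s of this assay format are
conventionally nominal. Curves entirely below 50% are censored
`">max tested"`, entirely above, `"<min tested"`; censored estimates carry
`NA` rather than an extrapolated number, because extrapolating outside the
tested range with an unknown curve shape is not defensible.

**Replicate spread.** The "±" in published IC50s of duplicate assays is
rarely defined. reactkit re-estimates the IC50 per replicate and reports
half the range for two replicates (labelled `half_range`) and the standard
deviation for three or more (`sd`), so the label always says what the
number is.

## Rank correlation and report

`spearman_rho()` validates and delegates to `stats::cor(method =
"spearman")` (average ranks for ties); the test suite checks it against an
independent direct rank computation, including the worked example where
gas-phase I versus the four published IC50s gives ρ = 0.8 (Σd² = 2, n = 4;
the two orderings differ by one adjacent transposition). Correlation is on
IC50 directly, not log IC50 — rank correlation is invariant to any strictly
monotone transform, so the choice is cosmetic and documented for clarity.
With n = 4 compounds no p-value is printed anywhere: the design can support
an ordering, not inference. The donor/acceptor reading of ω⁻ and ω⁺ is
reported as values and ordering only; no classification cutoff is applied
because none is established.

`render_tables()` writes the descriptor table (rows = descriptors,
columns = compounds, one block per phase, 4-decimal cells) and the
activity table (IC50 ± spread), ordered by compound id and phase so output
is byte-deterministic.

## Synthetic data: what it emulates, what it does not

The three generators produce exactly the dialects their consuming modules
read, with known ground truth:

* `gen_energy_triples(I, A, E_neutral, phase)` inverts the descriptor
  equations: E(cation) = E(neutral) + I/27.211386245988, E(anion) =
  E(neutral) − A/27.211386245988. Round-tripping through
  `compute_descriptors()` recovers I and A to 1e-9 eV (tested at 10³
  draws). `write_qm_logs()` additionally emits fixture `SCF Done:` log
  files (values printed at 1e-9 hartree, so the log path round-trips to
  about 3e-8 eV).
* `gen_peaklist(formulas, ppm_offset, ppm_noise_sd, seed)` displaces each
  calculated mass by a systematic ppm offset plus Gaussian ppm noise and
  records the injected truth per peak.
* `gen_plate(true_ic50, model, concentrations, replicates, noise_sd,
  blank_abs, seed)` simulates plate records. True inhibition follows either
  a line through 50% at `true_ic50` (`inhibition = 50 c/IC50`) or a Hill
  logistic with that midpoint; Gaussian noise is expressed in percentage
  points of inhibition and converted to absorbance through the blank, so
  `noise_sd` keeps its meaning whatever the blank level. Defaults mirror
  the assay protocol the package was built around: duplicate wells
  ("duplo"), six concentrations spanning 50–400 µg/mL, 2 pp noise, blank
  absorbance 0.8 (a typical A517 for a 1.0 mM DPPH working solution read in
  a microplate; the protocol metadata — 1.0 mM DPPH, 10 µL sample + 200 µL
  reagent, 30 min dark incubation — is carried on the records).

Each generator seeds its own RNG stream locally (the caller's RNG state is
untouched) and identical arguments give identical output, which the suite
checks by construction.

What the generators deliberately do **not** emulate: chromatographic peak
shapes and co-elution, isotope envelopes, detector saturation,
heteroscedastic or drifting plate noise, solvent blanks that differ between
wells, and QM convergence behaviour. Passing the recovery tests therefore
shows the *estimators* are correct under the stated models — unbiased
50%-crossing recovery under additive Gaussian noise, exact ppm recovery
under a pure offset model — not that real instruments satisfy those models.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for interactive runs: 10⁴
random (I, A) pairs for the identity suite, 10³ round-trip draws, 100
seeded duplicate plates for IC50 recovery (truth 182.5 µg/mL, the
mean-recovery check allows 5% and typically lands within a few tenths of a
percent), and the 12-row peak table. Display rounding everywhere is
half-away-from-zero (`round_half_up()`, with an epsilon guard so decimal
halves stored just below .5 in binary still round up), 4 decimals for
masses and descriptors, 1 for ppm — matching how such tables are printed.

## Limitations

* Tentative identification by exact mass alone cannot distinguish isomers;
  the annotation is a candidate ranking, not an identification.
* The descriptor stage consumes energies; their quality (functional, basis
  set, solvation model) is entirely upstream of this package.
* Bracket IC50 estimates depend on the concentration grid near 50%; a
  sparse grid inflates replicate spread. The 4PL fit needs points on both
  shoulders to be identifiable.
* With four compounds, ρ is descriptive. Adding compounds, not descriptors,
  is the only way to make the correlation stage inferential.
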