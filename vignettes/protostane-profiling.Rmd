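---
title: "Profiling protostane triterpenoids: models, defaults and design notes"
author: "ProtostaneMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protostane triterpenoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtostaneMS)
```

# The problem

*Alismatis Rhizoma* (AMR), the dried rhizome of *Alisma orientale*, owes
most of its pharmacology to protostane triterpenoids — the alisols, a
family of C30 tetracyclic terpenoids that occur as a few dozen closely
related hydroxylation/acetylation/epoxidation variants. Profiling them
takes two instruments playing different roles: a QTOF gives accurate
masses and fragment spectra for *identifying* the components, and a
triple-quadrupole in MRM mode gives sensitive, selective peak areas for
*quantifying* the major ones across sample batches. ProtostaneMS
implements everything downstream of peak picking: the raw vendor files,
chromatogram processing and peak integration are out of scope — the
pipeline starts from peak lists and integrated areas.

# Qualitative stage

## Mass arithmetic and the adduct convention

All masses derive from fixed monoisotopic constants (C 12.000000,
H 1.00782503, O 15.99491462 Da), chosen once and documented so that every
derived number in the package and its tests is bit-stable.

Positive electrospray produces [M+H]+ ions, and there are two conventions
for the added mass: the neutral hydrogen atom (+1.007825 Da) or the true
proton (+1.007276 Da, i.e. corrected for the electron carried away with
the charge). The difference, 0.55 mDa, is about 1.1 ppm at m/z 500 —
large enough to matter when reproducing tabulated 1-decimal ppm errors.
Recomputing the packaged library's mass errors shows the hydrogen-atom
convention reproduces the recorded values at 1-decimal rounding for
nearly every entry, while the proton convention does not; the package
therefore defaults to the hydrogen-atom convention and exposes the choice
as a flag (`adductMass()`, `convention =` arguments). Reported ppm values
round halves away from zero, matching the tabulation convention.

## Formula enumeration

`enumerateFormulas()` searches CHO formulas whose [M+H]+ lies within a
ppm tolerance of an observed m/z. Default bounds — C 5–40, H 10–64,
O 0–10, RDBE (C − H/2 + 1) 0–15, even-electron species only — are wide
enough to contain every protostane in the library yet small enough that
an exhaustive scan is instantaneous. Rather than a triple loop, the
implementation solves for the feasible hydrogen-count interval per (C, O)
pair; the test suite holds it equal to an independent triple-loop oracle
over 50 random (m/z, tolerance) instances, and checks that widening the
tolerance never removes a hit. Results are ordered deterministically:
ascending |ppm|, then lexicographic formula string.

## Neutral-loss chains

Protostane fragmentation is dominated by successive/simultaneous losses
of H2O (18.011 Da) and acetic acid (HAc, 60.021 Da), plus the side-chain
fragments C4H8O, C4H10O2, C6H10O2, C6H12O3 and ketene C2H2O released by
C-23–C-24 bond dissociation. `annotateLosses()` explains each fragment as
a multiset of vocabulary losses whose total mass matches
precursor − fragment within max(15 ppm, 3 mDa) — QTOF fragment accuracy
is looser than MS1 accuracy, and the absolute floor protects low-mass
fragments. The search is exhaustive to depth 4 (330 multisets over the
7-loss vocabulary), so "breadth-first" is literal, and ties resolve
deterministically: shortest chain, then smallest |ppm|, then
lexicographic label.

Two numerical notes. First, the vocabulary is mass-degenerate by
construction: H2O + C4H8O has exactly the atoms (hence exactly the mass)
of C4H10O2, and similarly C2H2O + C4H8O = C6H10O2 and HAc + C4H8O =
C6H12O3. The shortest-chain rule collapses these onto the composite
loss; consequently the package's tests compare annotations by *total
loss composition* (the summed elemental formula — the physically
observable quantity) rather than by label multiset. Second, chain masses
are computed with `sum()` over the multiset rather than by incremental
accumulation: the two differ in the final ulp, which is enough to flip
the |ppm| tie-break between mass-degenerate chains.

## The seven structural types

C-23–C-24 dissociation leaves a charged skeleton fragment whose m/z is a
fingerprint of the core oxidation pattern, and the UV chromophore
separates skeletons that fragment identically:

| type | skeleton ion (m/z) | UV class |
|------|--------------------|----------|
| I    | 397.2745           | 287 nm   |
| II   | 397.2745           | 245 nm   |
| III  | 383.2983           | none     |
| IV   | 339.2684           | none     |
| V    | 385.3102           | none     |
| VI   | 399.2896           | none     |
| VII  | 399.2896           | 245 nm   |

The skeleton ions are stored as the *empirical* instrument values and
matched at ±15 ppm; they are deliberately not recomputed from candidate
fragment compositions, because no fragment formulas are assigned in the
reference characterisation and recomputation contradicts the recorded
values for one family by ~8–10 ppm. UV classes bin λmax into
287 ± 5 nm, 245 ± 5 nm, or "none" (absent or below 200 nm). Rules are
evaluated in the order IV, V, III, VI, VII, I, II — rarer ions first —
stopping at the first rule whose ion and UV class both match;
classification depends only on which m/z are present, so it is invariant
to fragment order and intensity scaling. A feature whose characteristic
ion matches but whose UV class fits no rule is returned unclassified with
a diagnostic reason rather than forced into a type.

## Identification and its failure modes

`identifyFeature()` is two-tier. A standard-match needs a
standard-confirmed library entry within ±0.5 min retention time, ±5 ppm
on the precursor against the entry's *formula*, and at least 2 matched
expected fragments; the retention-time window is deliberately tight
because the alisols elute as near-isomers (23- vs 24-acetates differ by
minutes, but type III compounds 16/17 elute 1.3 min apart). Failing
that, the feature is tentatively assigned the best enumeration formula
and the rule-based type; only a feature yielding neither is
unidentified.

One library entry (alisol A 23-acetate, peak 17) carries a recorded
precursor m/z that is ~13 ppm away from its own formula — an apparent
transcription error in the source characterisation, flagged
`mass_anomaly` in the fixture. Run on the packaged feature set, it is
the one standard-confirmed compound that resolves through the tentative
tier (type III via its 383.2983 skeleton ion) instead of as a
standard-match; all 25 features are identified. A handful of recorded
*fragment* m/z values are likewise inconsistent with their own loss
arithmetic (they fail even a 15 ppm/3 mDa window against the recorded
precursor); they are stored as recorded, enumerated in the test helpers,
and excluded from round-trip assertions rather than silently corrected.

# Quantitative stage

## Calibration and content conversion

Calibration is unweighted ordinary least squares of the analyte/IS
area ratio Y on concentration X (µg/mL), with r the Pearson correlation;
1/x and 1/x² weighting exist as options for strongly heteroscedastic
data but are off by default because the reference method states none.
Degenerate designs (fewer than 3 distinct concentrations, constant X,
zero-variance Y) are errors, not silent NaNs.

X refers to the analyte concentration in the *injected* solution — after
the 1:1 mix with the internal-standard working solution — so a sample's
back-calculated X is multiplied by the mix dilution (2) and the
extraction volume (25 mL), and divided by the sample mass (0.20 g):
mg/g = 0.25 · X with the defaults. This reading is the one that keeps
the highest observed batch contents (alisol B 23-acetate up to
2.032 mg/g ↔ 8.1 µg/mL injected) inside the tabulated linear ranges;
the pre-mix reading would push them above. `quantifyBatch()` averages
replicate injections (n = 3 by default), logs the replicate RSDs and
linear-range flags into the result's metadata, reports back-calculated
concentrations below the analyte's LOD as ND (`NA`), and skips — with a
warning and a metadata record — any injection whose IS area is missing
or non-positive.

## LOD/LOQ

The limits correspond to S/N ≈ 3 and ≈ 10. Since "about 3" prescribes no
procedure, the package interpolates: log-concentration linearly in
log(S/N) between the bracketing points of a dilution series, which is
exact whenever signal is proportional to concentration over a constant
noise floor. A series that does not bracket the target S/N raises an
error advising a wider series instead of extrapolating.

## Validation statistics and origin comparison

`validationReport()` reproduces the standard validation table layout per
analyte: intra-day RSD (6 injections), inter-day RSD (duplicates × 3
days), repeatability RSD and mean (6 independent preparations),
stability RSD (7 timepoints across 24 h), and spike recovery
mean ± sd and RSD, with recovery = (detected − original) × 100/added.
RSD uses the n−1 standard deviation; arms with fewer than 2 values fail
loudly, naming the arm.

`compareOrigins()` runs a two-sided two-sample t-test per analyte. The
default is pooled-variance Student's t (the variant named in the source
analysis), with Welch as an option; ND cells are excluded pairwise, not
by deleting samples; no multiple-testing correction is applied by
default (matching the reference analysis), with Benjamini–Hochberg as an
option. On the packaged 43-batch table this flags nine analytes higher
in the Sichuan batches and 11-deoxy-alisol B lower, with no flag for the
remaining four — the directional pattern the acceptance tests assert.
Only directions and the α = 0.05 flags are asserted, never the p-values
themselves, since no reference p-values exist to compare against.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested; its defaults are not tuning knobs. Noise models are the simplest
ones consistent with the instruments' reported behaviour:

* **MS1 mass error**: multiplicative, ε ~ N(0, 2 ppm) — the reference
  characterisation's molecular-ion errors all fall within ±5 ppm.
* **Fragment mass error**: N(0, 5 ppm), plus Bernoulli dropout with
  probability 0.2 per fragment (fragment detection is intensity-limited
  in ways the package does not model mechanistically).
* **Retention time**: uniform ±0.1 min jitter.
* **Areas**: multiplicative N(0, 5%) on the analyte area; the IS area is
  drawn per injection (mean 1e5 counts, CV 5%) — together these give
  ratio CVs of the same few-percent order as the reported validation
  RSDs (1.2–4.3%).
* **Contents**: lognormal around per-analyte, per-origin means taken
  from the packaged batch table (CV 30%), so simulated effect sizes
  match the study's; an explicit per-analyte Sichuan/Fujian ratio can
  override the template.

One global seed expands into fixed per-stage substreams
(seed × 7919 + stage offset, reduced mod 2³¹ − 1), so stages regenerate
independently and every generator is a pure function of (inputs, seed).
With all noise parameters zero, each generator composes with its
analysis stage to the identity: simulated features reproduce the library
exactly, and simulate→quantify recovers true contents to ≤1e-9 relative
error — the inverse-pair property the test suite asserts.

What the generator does *not* emulate: chromatographic peak shapes and
integration error, isotope envelopes, in-source fragmentation, matrix
effects and ionisation suppression, carryover, and drift correlated
across analytes. Passing the simulation suites therefore demonstrates
that the *computational* pipeline is correct and robust at realistic
noise scales — not that the analytical method itself would validate on a
different instrument or matrix.

A note on the simulated identification benchmark: recovery is scored as
"standard-match with the correct name, or tentative with the correct
formula". Under the stated dropout rate, library entries with only two
recorded fragments fail the ≥2-fragment standard-match requirement in
roughly a third of draws, and the four compounds without reference
standards can never standard-match, so name-level recovery is
structurally capped near 84%; formula-level recovery is the meaningful
"assigned to the right compound" criterion for tentative
identifications, and it is what the ≥95% assertion measures.

# Problem sizes and runtime choices

The test suite runs the full fixture set (25 features, 43 × 14 batch
table) everywhere it is cheap, and uses 20-seed Monte Carlo repetitions
for the stochastic properties (identification recovery, batch content
recovery at 5% CV, LOD recovery, validation RSD distribution, 10 seeds
for the origin-flag reproduction). These sizes put every Monte Carlo
mean within a comfortably narrow sampling band of its target while
keeping the whole suite under a minute on one CPU core.

# Interfaces and configuration

Spectra move as a minimal MGF dialect (TITLE/PEPMASS/RTINSECONDS plus a
non-standard UVLAMBDAMAX key) or as per-feature CSV; contents as wide
CSV with the literal "ND" sentinel; areas as long CSV; run summaries as
JSON. All CSV dialects use the period decimal separator and UTF-8
regardless of locale. The pipeline's tunables live in one serializable
`pipelineConfig()` object that round-trips through YAML, so a run's
effective configuration can be echoed next to its outputs. The package
is used from R — functions, fixtures and this vignette are the
interface; there is deliberately no shell wrapper.

# Known limitations

* Only CHO formulas are enumerated; N/S-containing contaminants would be
  assigned a wrong CHO formula or none.
* Single-charge [M+H]+ only; sodium adducts observed in spectra are not
  scored, and negative mode is out of scope.
* Type assignment is a fingerprint rule, not structure elucidation: a
  novel protostane with an unusual skeleton ion lands in "unclassified",
  and a non-protostane sharing a skeleton ion mass would be mistyped.
* The t-test treats batches as independent samples; plantation or
  harvest-year structure within an origin is not modelled.
* LOD/LOQ interpolation assumes a monotone S/N series; a non-monotone
  series (e.g. from carryover) errors rather than guessing.
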