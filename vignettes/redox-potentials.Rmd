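---
title: "From electronic energies to biochemical redox potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From electronic energies to biochemical redox potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcredox)
```

qcredox turns quantum-chemistry electronic energies of small metabolites
into biochemical standard transformed reduction potentials, calibrates them
against experimental measurements, and supports the downstream analyses that
such potentials enable: screening experimental compilations for suspect
values, enumerating candidate redox pairs, and asking which couples an
electron carrier such as NAD(P) can drive reversibly. This vignette explains
the model the package implements, the conventions and defaults it commits
to, and what its synthetic data can and cannot establish.

## The model

### Oxidoreductase categories

Two-electron redox transformations of carbon functional groups fall into
four generalized categories, each balanced here as a reduction with
molecular hydrogen, `ox + H2 -> red` (n = 2):

* **G1** — carboxylic acid to carbonyl (with a water co-product). The
  *activated* variant starts from a thioester or phosphoanhydride.
* **G2** — carbonyl to hydroxycarbon (alcohol).
* **G3** — carbonyl to amine, consuming one ammonia and releasing water.
* **G4** — hydroxycarbon to hydrocarbon.

### From conformer energies to E0

The electronic energy of each compound is a Boltzmann average over its
geometric conformers (`boltzmann_average()`), weighted by
`exp(-(E - Emin)/RT)` after conversion from Hartree (1 Ha = 2625.50 kJ/mol).
The weighting temperature is 298.15 K; it is configurable because the
equilibration stage the weights describe is not observable separately. The
reaction energy subtracts the H2 electronic energy computed with the same
model chemistry, which realizes the standard-hydrogen-electrode reference,
and the chemical standard potential of the pH-0 major species follows as
`E0 = -dE/(nF)` (`electronic_to_potential()`). Rovibrational enthalpies and
entropies are deliberately omitted from this map; their systematic effect is
absorbed by the per-category calibration below.

### The Legendre transform to E'm

A biochemical reactant at fixed pH is an ensemble of protonation species.
Each compound's ladder is built from its pH-0 major species (the most
protonated relevant form, `species_ladder()`): removing the j-th proton
costs the cumulative `RT ln(10) pKa` energy and decrements charge and
hydrogen count by one. Each species is Legendre-transformed,

```
dG' = dG0 + N_H RT ln(10) pH - alpha (z^2 - N_H) sqrt(I) / (1 + B sqrt(I)),
```

with the extended Debye-Huckel coefficients fixed at Alberty's standard
298.15 K parameterization (alpha = 2.91482 kJ mol^-1 M^-1/2, B = 1.6
M^-1/2; no temperature dependence of alpha is modeled because the pipeline
operates at 298.15 K). The ladder is aggregated into one pseudoisomer
energy by an overflow-safe log-sum-exp (`pseudoisomer_energy()`).

The transformed potential of a couple is then

```
E'0 = E0 - [G'(red) - G'(ox)] / (nF),
```

with the hydrogen-electrode reference pinned at its pH-0 standard state so
that it contributes no correction (`transformed_potential()`). Under this
convention the familiar `-RT ln(10)/F x (protons transferred / n)` pH slope
(-59.16 mV/pH for a 2H+/2e- couple) emerges from the hydrogen-count
difference between the reduced and oxidized ladders, which is how standard
transformed formation-energy calculators behave. An equivalent formulation
that Legendre-transforms H2 at the solution pH would cancel this slope for
hydrogen-balanced couples; we document the pinned-reference choice because
it reproduces both the textbook pH dependence and the closed-form worked
examples in the test suite. Transform corrections from the implied
co-reactants (water for G1/G3/G4, ammonia for G3) are constant within a
category and are therefore absorbed by the calibration intercept rather
than modeled per reaction.

Only pKa values inside [0, 14] generate species: forms that dominate only
outside the aqueous window cannot materially affect a pH-7 pseudoisomer
sum. Only deprotonations from the pH-0 major species are modeled — no
super-acidic protonations, tautomers, or metal complexes.

Finally, the reactant standard state moves from 1 M to 1 mM
(`millimolar_standard()`), which better matches physiological metabolite
levels. For 1:1 couples this is the identity; for G3 the ammonia substrate
shifts the potential by `RT ln(10^3)/(nF)` = 88.7 mV. The sign is fixed by
the requirement that the G2 and G3 distributions — identical in the
oxidation state of the transformed group — coincide at the 1 mM state: the
conversion lowers G3 potentials, and a dedicated test asserts this.

### Calibration

Raw transformed predictions carry category-specific systematic error. A
two-parameter ordinary least squares fit of experimental on predicted
potentials per category (`fit_calibration()`) removes it; the diagnostics
(MAE, Pearson r, R^2, with R^2 = 0 the score of the constant mean
predictor) are recomputed at fit time and never cached. The metrics are
in-sample, since no cross-validation scheme is part of the published
procedure; a leave-one-out variant can be built from the exposed pieces but
is not the default. Activated-G1 records share the G1 model — too few
activated measurements exist to identify a separate slope — and activation
is then applied as a flat, configurable +250 mV offset
(`activation_correction()`): the hydrolysis energy of the activating group
(~50 kJ/mol over two electrons, 259.1 mV unrounded) uniformly raises the
distribution, and the conventional rounded constant is the default.

### The fingerprint alternative and outlier screening

An independent predictor encodes each half-reaction as a 332-bit
concatenation of the substrate and product MACCS 166-key fingerprints
(`maccs_keys()`, `reaction_fingerprints()`), fed to L1-regularized
regression per category (`fit_fingerprint_model()`, glmnet). MACCS keys
rather than richer circular fingerprints keep the design small relative to
the available training sets. The penalty lambda is not specified by the
published procedure; the default here is seeded k-fold cross-validation
(lambda.min, deterministic fold assignment), with the grid and fold count
recorded on the fitted object. Fingerprints are computed on the pH-0
major-species SMILES, the one structure the data model carries. The keys
are evaluated through OpenBabel's MACCS SMARTS dictionary (ChemmineOB); the
test suite pins its output against on-bit sets frozen from RDKit's
reference implementation on molecules where the two dictionaries agree
bit-for-bit (one key, the aromatic-nitrogen count 125, is known to differ
on fused heteroaromatics).

Prediction errors from the quantum and fingerprint routes are normalized to
z-scores with the sample standard deviation (ddof = 1; the published
formula does not fix the estimator, so the conventional unbiased one is
used). A reaction is reported as a likely experimental error only when
|z| > 2 under **both** methods (`joint_outliers()`): consistent deviation
from two very different predictors implicates the measurement, not the
models. The absolute value is used although the published rule is written
one-sidedly, because a measurement can err in either direction; both known
flagged examples happen to deviate in the same direction.

### Enumeration and carrier analysis

Candidate pairs are generated by matching functional-group difference
vectors between compounds (`match_pairs()`): product-minus-substrate counts
must equal the category signature exactly, and both compounds must have
fewer than 7 carbon atoms. Group vectors are inputs on the compound table —
no structure-decomposition engine is implemented, which sidesteps the
decomposition failures that plague group-contribution bookkeeping. Two
name-convention filters then remove stereochemically wrong pairs: a
chirality-token match on R/S and L/D prefixes, and a sugar name-root table
(`default_sugar_rules()`) that removes cross-family pairs such as
L-xylonate -> L-arabinose, which an L/L token match wrongly keeps. The rule
table is small and user-extensible; it approximates, with explicit logged
rules, manual curation that cannot be reproduced mechanically.

Carrier compatibility (`classify_vs_carrier()`) compares a couple's E'm
with the carrier's physiological window widened by the concentration span
its partners can explore: `w = RT ln(span)/(nF)`, 118.3 mV for the default
10^4 span (metabolites between 1 uM and 10 mM). The NAD(P) default is
-380 to -250 mV (standard potential ~ -330 mV at pH 7, I = 0.25 M), all
configurable through `carrier_profile()`. Couples below the widened window
can only be oxidized by the carrier; couples above it can only be reduced;
the boundary classifies as reversible (closed interval). Subgroup contrasts
use Welch's unequal-variance t-test with raw two-sided p-values; a
Benjamini-Hochberg option exists behind the `p_adjust` flag but is off by
default to match the reporting convention for these analyses.

## Conditions, units, display

`aqueous_conditions()` carries the transformed standard state: pH 7, ionic
strength 0.25 M, 298.15 K, and a 1 mM reactant standard by default. Units
are Hartree at the file boundary, kJ/mol internally, volts at the potential
boundary. Category means are conventionally displayed rounded to the
nearest 5 mV; `round_to_nearest()` implements this at the reporting layer
only — no internal value is ever rounded.

## Synthetic data: what it shows and what it cannot

The package is fully testable offline through three generators:

* `simulate_conformer_ensembles()` builds conformer tables with truth means
  computed by direct summation; `toy_base_energies()` anchors the toy
  compound set so each planted couple sits at a chemically sensible E0.
  Conformer offsets are half-Gaussian with a 6 kJ/mol scale — the range
  over which room-temperature populations actually shift.
* `simulate_calibration_set()` draws raw potentials uniformly and applies a
  prescribed affine law (default slope 0.8, intercept 30 mV) plus Gaussian
  noise of 10 mV, the scale of scatter in curated potential compilations.
* `synthetic_reference_tables()` is a deterministic stand-in for the
  curated 105-reaction experimental compilation, which is distributed as a
  supplementary spreadsheet and not redistributed here. It reproduces the
  published per-category summary statistics exactly — counts 8/59/23/15,
  calibrated MAE 45/31/17/34 mV, G2 mean -225 mV, and the two suspect G2
  measurements (EC 1.1.1.110 at -400 mV experimental vs -190 mV predicted,
  and EC 1.1.1.61) planted as joint outliers — by constructing calibration
  residuals orthogonal to the raw predictions and solving the residual
  scale so each category MAE hits its target to machine precision.

Tests against the mirror therefore verify the *machinery* — that OLS
calibration, MAE computation and joint z-score flagging recover the
published summaries from data constructed to embody them — not the paper's
raw measurements. Likewise, passing tests on the simulated conformer and
calibration sets show correct estimation under the stated noise model, not
that the noise model matches any particular experimental archive. Nothing
synthetic can validate the electronic energies themselves: those enter the
pipeline as inputs.

## Numerical choices

* Log-sum-exp aggregations (pseudoisomer energies, Boltzmann weights) shift
  by the extreme input before exponentiating; both are tested against
  direct summation at 1e-10.
* Ties in the dominant-species diagnostic (a pKa exactly at the pH) resolve
  toward the more protonated species, with a 1e-9 kJ/mol tolerance guarding
  against floating-point near-ties.
* The Lasso fit canonicalizes training-row order before fold assignment, so
  the model is invariant to how rows arrive.
* Degenerate inputs fail loudly: empty ensembles, calibration sets with
  fewer than two pairs or zero predictor variance, zero-spread error
  vectors, and group vectors with unnamed entries are all rejected with
  messages naming the offender. A constant experimental vector makes
  Pearson r undefined and is reported as `NA`, not an error.

## Problem sizes

The test suite runs entirely on generated data: 15 toy compounds, conformer
ensembles of up to 10 members, calibration sets of 23-59 rows (the mirror)
and 30-300 rows (recovery and learning-curve checks), and 332-bit designs
with up to 300 training rows. These sizes keep every check well inside a
second or two while leaving each estimator identifiable.

## Limitations

* Electronic energies, pKa values and functional-group vectors are inputs;
  the package runs no quantum chemistry, no pKa estimation and no group
  decomposition.
* Half-reactions only; there is no general Gibbs formation-energy
  bookkeeping, no temperature extrapolation, and no activity model beyond
  extended Debye-Huckel.
* The enumeration name filters are heuristics; a curated reaction atlas
  still needs human review.
* Calibrations transfer only within their category and model chemistry;
  applying a G2 model to G4 chemistry is unsupported by construction.
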