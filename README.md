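# qcredox

Calibrated prediction of biochemical standard transformed redox potentials
from quantum-chemistry electronic energies.

Most of metabolism is redox chemistry, yet only on the order of a hundred
biochemical reduction potentials can be inferred from experiments, measured
under inconsistent conditions. qcredox implements the computational half of
a hybrid strategy for anyone — metabolic engineers, enzyme designers,
biochemists curating thermodynamic databases — who needs potentials for
reactions nobody has measured: take electronic energies of the reacting
compounds from quantum chemistry, convert them to biochemical potentials
under physiological conventions, and remove the systematic error with a
minimal per-category linear calibration against the measurements that do
exist.

## The method in brief

For a two-electron reduction balanced with molecular hydrogen,
`ox + H2 -> red`, the chain is:

1. **Ensemble energies.** Boltzmann-average each compound's conformer
   electronic energies, subtract the H2 energy (same model chemistry), and
   map to the chemical standard potential of the pH-0 major species:
   `E0 = -ΔE_electronic / (nF)`.
2. **Legendre transform.** Build each compound's protonation-species ladder
   from its pKa list, transform every species with
   `ΔG' = ΔG0 + N_H·RT·ln(10)·pH − α(z² − N_H)√I/(1 + B√I)`
   (extended Debye–Hückel), aggregate by log-sum-exp, and obtain the
   standard transformed potential `E'° = E0 − [G'_red − G'_ox]/(nF)` at
   pH 7, I = 0.25 M.
3. **1 mM standard state.** Standardize reactant concentrations to 1 mM
   (`E'^m`); only carbonyl→amine reductions shift (their ammonia substrate
   contributes `RT·ln(10³)/(nF)` ≈ 89 mV).
4. **Calibration.** Fit `E_exp = α·E_pred + β` per oxidoreductase category
   (G1 acid→carbonyl, G2 carbonyl→alcohol, G3 carbonyl→amine,
   G4 alcohol→alkane); activated acids (thioesters, phosphoanhydrides) are
   the G1 distribution shifted by +250 mV.

Around that core the package provides a structure-based alternative
predictor (MACCS 166-key reaction fingerprints + Lasso), cross-method
z-score screening for suspect experimental values (|z| > 2 under both
predictors), rule-based enumeration of candidate redox pairs from
functional-group vectors with chirality and sugar-name filters, and
carrier-window analysis (which couples NAD(P) can drive reversibly given a
10⁴ metabolite concentration span). See the methods vignette
(`vignettes/redox-potentials.Rmd`) for conventions, defaults and
limitations.

## Worked example

Everything below runs offline on the package's synthetic fixtures: a toy
compound table with hand-assigned functional-group vectors and conformer
ensembles anchored to sensible reaction energies.

```r
library(qcredox)
library(dplyr)

compounds <- simulate_compound_set()
pairs <- enumerate_redox_pairs(compounds) |>
  chirality_filter(compounds) |>
  sugar_name_filter(compounds)

ens <- simulate_conformer_ensembles(
  n_compounds = nrow(compounds), seed = 1, ids = compounds$id,
  base_energies_hartree = toy_base_energies())

predictions <- predict_potentials(pairs, compounds, ens$energies,
                                  h2_reference = -1.1675)
predictions |> select(pair_id, category, e0_v, e_prime_m_v)
#> # A tibble: 7 × 4
#>   pair_id  category    e0_v e_prime_m_v
#>   <chr>    <chr>      <dbl>       <dbl>
#> 1 C01__C02 G1       -0.552      -0.627
#> 2 C11__C13 G1       -0.520      -0.629
#> 3 C02__C03 G2        0.191      -0.231
#> 4 C06__C07 G2        0.161      -0.262
#> 5 C08__C10 G2        0.130      -0.292
#> 6 C02__C05 G3        0.703      -0.226
#> 7 C03__C04 G4       -0.0118     -0.0118
```

Nine candidate pairs matched the four group signatures; the filters
removed an (R)→(S) chirality conflict and the cross-family sugar pair
L-xylonate → L-arabinose, and two 7-carbon compounds never entered. Note
the chemistry the numbers encode: chemical E0 at pH 0 sits ~0.4 V above
the biochemical E'ᵐ for proton-coupled couples (−59.2 mV per pH unit over
7 units), the G1 acid reductions are far more negative than everything
else, and the alcohol→alkane couple barely moves because its two protons
leave with the water co-product.

Calibrating against the packaged synthetic mirror of the experimental
compilation (n = 59 for G2) and classifying against the NAD(P) window:

```r
models <- fit_calibration_by_category(synthetic_reference_tables()$experimental)
glance(models$G2)
#> # A tibble: 1 × 5
#>   category     n   mae pearson_r r_squared
#> 1 G2          59 0.031     0.852     0.726

calibrated <- apply_calibration(predictions, models)
classify_vs_carrier(calibrated, potential_col = "calibrated_v") |>
  count(carrier_class)
#> # A tibble: 3 × 2
#>   carrier_class      n
#> 1 oxidation_only     2
#> 2 reduction_only     1
#> 3 reversible         4
```

The G2 model's 31 mV mean absolute error is the mirror's built-in value;
the classification says NAD(P) can run the carbonyl reductions in both
directions, can only oxidize the two carboxylic-acid couples (E'ᵐ below
−500 mV after concentration adjustment), and can only reduce the
alcohol→alkane couple.

A thin command-line front end over the same functions lives at
`inst/cli/qcredox.R` (subcommands `fixtures`, `predict`, `calibrate`,
`outliers`, `enumerate`, `analyze`).

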