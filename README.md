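# h4zip — kinetic modeling of combinatorial histone H4 tail acetylation

The N-terminal tail of histone H4 carries four acetylatable lysines (K5,
K8, K12, K16), so each tail occupies one of 16 combinatorial acetylation
**motifs**. Targeted mass spectrometry with heavy chemical acetylation
(D3-acetyl, +3.0188 Da vs the enzymatic acetyl) quantifies all of them as
relative abundances. In vitro, a MYST-family acetyltransferase complex
acetylates K16 quickly and selectively, then walks N-terminally along the
tail (K12 → K8 → K5) on tails that already carry K16ac — "zip"-like,
processive acetylation.

This package is for researchers who want to model such combinatorial PTM
time courses mechanistically. It provides:

* the 16-motif acetylation lattice and its single-site transition network
  (no deacetylation edges; the fully acetylated motif is the absorbing
  sink), including site-restricted spaces such as the 8-motif K16R lattice;
* three competing ODE model families over that lattice —
  **mass action** (`dS_m/dt = Σ k_{m'i} S_{m'} − Σ k_{mi} S_m`, enzyme in
  excess), **Michaelis–Menten**
  (`v_{mi} = kcat_{mi} E_tot S_m / (Km + Σ_j S_j)`, one shared limiting
  enzyme pool), and **processive**
  (explicit `E + S_m ⇌ C_m`, on-complex catalysis `C_m → C_{m+e_i}`, and an
  optional within-array hand-off `C_m + S_n → S_m + C_n`);
* multi-start maximum-likelihood calibration on log10-scaled bounded
  parameters, AIC ranking with the ΔAIC ≥ 10 rejection rule;
* posterior sampling under bounded uniform priors (affine-invariant
  ensemble sampler) with 99% credibility intervals, ensemble prediction
  bands, per-motif site-preference profiles, and the **K16R
  counterfactual** — predictions with every reaction at K16 disabled;
* an MS-quantification layer (MS1 peak areas → relative motif abundances,
  light/heavy acetyl bookkeeping, strict-below 0.003% detection-limit
  masking) and a synthetic-data generator that emulates the experiments'
  measurement structure so the entire pipeline is testable offline.

## Worked example

```r
library(h4zip)

# simulate the wild-type scenario: processive enzyme, K16-dominant rates
bundle <- generate_dataset(preset_library()$wildtype)
round(100 * bundle$truth$y[c("K16ac", "K12acK16ac", "K12ac"), ], 1)
#>            0    5   15   30   60
#> K16ac      0 53.8 45.1 22.1  4.9
#> K12acK16ac 0 17.5 39.5 52.7 51.0
#> K12ac      0  0.1  0.0  0.0  0.0

# fit the three families and rank them by AIC
spec <- likelihood_spec("fixed", sigma = 0.01)
fits <- lapply(c("mass_action", "michaelis_menten", "processive"),
               fit_model, data = bundle$dataset, spec = spec,
               n_starts = 3, seed = 11)
compare_models(fits)
#>             family       aic delta_aic n_params rejected
#> 1       processive -1491.063    0.0000        6    FALSE
#> 2      mass_action -1349.457  141.6066        4     TRUE
#> 3 michaelis_menten -1347.457  143.6066        5     TRUE
```

K16ac rises to ~54% within 5 min and then declines in favor of
K16-anchored di-/tri-acetylation — the zip signature — and the processive
family wins the AIC comparison by a wide margin on data generated with a
processive mechanism, while both non-processive families fall past the
ΔAIC ≥ 10 rejection threshold.

The numbered scripts under `analysis/` run the full study line:
`01_simulate.R` (scenarios), `02_quantify.R` (MS-style quantification and
report aggregates), `03_fit_compare.R` (calibration + ΔAIC table),
`04_posterior.R` (credibility intervals, prediction bands, site-preference
profile), `05_k16r_prediction.R` (the K16R counterfactual). Each writes its
tables under `results/`.

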