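---
title: "Modeling combinatorial H4 tail acetylation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling combinatorial H4 tail acetylation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h4zip)
```

## The scientific problem

The histone H4 N-terminal tail carries four acetylatable lysines — K5, K8,
K12 and K16 — so a tail occupies one of $2^4 = 16$ combinatorial acetylation
states ("motifs"). Targeted mass spectrometry can quantify these motifs
directly: after chemical acetylation of all unmodified lysines with a heavy
(D3) acetyl donor, enzymatic (light) and chemical (heavy) acetyl groups
differ by 3.0188 Da while behaving identically in chromatography, so each
motif maps to a distinct peptide species whose MS1 area is read off relative
to the summed areas of all H4 species.

In vitro, a MYST-family acetyltransferase complex acetylates K16 first and
with strong selectivity, then progressively acetylates K12, K8 and K5 on
tails that already carry K16ac — a "zip" running from the internal lysine
outward. The package asks which reaction mechanism explains those motif time
courses, using the motif lattice plus three competing ODE model families,
maximum-likelihood calibration, AIC ranking, posterior sampling, and
counterfactual prediction.

## State space and transition lattice

`transition_network()` builds the directed acyclic lattice whose nodes are
the motifs and whose edges add exactly one acetyl group. There is no
deacetylase in the assay, so the lattice has no reverse edges and the
tetra-acetylated motif is the unique absorbing sink; the lattice must not be
read as a steady-state model. An $n$-site lattice has $n \cdot 2^{n-1}$
edges (32 for wild type). `restrict_site()` halves the space — the K16R
mutant lives on the 8-motif lattice over K5/K8/K12.

Motifs are ordered canonically by acetyl count, then by site tuple, which is
the reading order of the report heatmaps; labels concatenate acetylated
sites N-terminally first (`"K12acK16ac"`), with `"unmod"` for the empty
pattern and `"tetra-ac"` accepted as an input alias.

## The three model families

All families share the observation model $y_m = S_m + C_m$ (MS measures
every H4 molecule, enzyme-bound or not), time in minutes, substrate as
fraction of total H4 ($\sum_m y_m = 1$), and enzyme in the same fractional
units with default $E_{tot} = 0.25$ from the assay stoichiometry (50 nM
complex on 200 nM nucleosomes). Acetyl-CoA is assumed saturating and is not
modeled.

* **Mass action** — acetylation is first order in the substrate motif with
  the enzyme folded into the rate constant (enzyme effectively in excess):
  $\dot S_m = \sum_{(m',i) \to m} k_{m'i} S_{m'} - \sum_i k_{mi} S_m$.
* **Michaelis–Menten** — all motifs compete for one limiting enzyme pool at
  binding quasi-equilibrium: edge flux
  $v_{mi} = k^{cat}_{mi} E_{tot} S_m / (K_m + \sum_j S_j)$.
* **Processive** — enzyme, substrate and complex are explicit:
  $E + S_m \rightleftharpoons C_m$ (rates $k_{on}, k_{off}$), on-complex
  catalysis $C_m \to C_{m+e_i}$ at $k^{cat}_{mi}$ — the enzyme stays bound
  between catalytic events, which is what "processive" means — plus an
  optional within-array hand-off $C_m + S_n \to S_m + C_n$ at $k_{transfer}$
  (the spatial variant; off by default).

Catalytic constants come in a per-site mode (4 parameters, shared across
motifs; cheap, used for fitting at desk scale) and a per-edge mode (32
parameters; needed for per-motif site-preference profiles). Whether the
original analysis shared rate constants across motifs is not derivable from
the published text, so both parameterizations are first-class and the mode
is an explicit argument.

The spatial hand-off is realized as a direct complex–substrate exchange that
bypasses the free-enzyme pool. The underlying observation is only that
moving to another array takes longer than moving within one; this concrete
bimolecular scheme is this package's own design choice, stated here because
other realizations (explicit array compartments, for instance) are possible.

### Numerical choices

`simulate_model()` integrates with lsoda (stiff-capable) at `rtol = 1e-8`,
`atol = 1e-10`; the mass-action and processive families supply analytic
Jacobians. Round-off negatives are clipped to zero only in the observation
layer, never in the solver state. Inside likelihoods the tolerances relax to
`1e-6`/`1e-9` (configurable in `likelihood_spec()`): with measurement noise
at $\sigma = 0.01$ on abundances, tighter integration changes the objective
by far less than one noise unit while costing most of the runtime.

Conservation ($\sum_m (S_m + C_m) = 1$, $E + \sum_m C_m = E_{tot}$) holds to
1e-8 over 180 simulated minutes; mass-action trajectories agree with the
matrix-exponential solution of the edge-rate generator to 1e-6; the
Michaelis–Menten family converges to mass action as $K_m \to \infty$ at
fixed $k^{cat} E_{tot} / K_m$, and the processive family converges to
Michaelis–Menten in the quasi-steady-state regime. That last limit is only
exact when binding equilibrates much faster than catalysis
($k^{cat} \ll k_{off}$) *and* the enzyme is well below $K_m + S$; the test
suite therefore takes the limit at $k_{on} = k_{off} = 10^9$,
$E_{tot} = 2 \times 10^{-5}$, where the residual deviation is
$\sim 10^{-5}$. At shallower scalings (e.g. $k_{off} = 10^4$ with
assay-scale rates) the QSS reduction error is first order in
$k^{cat}/k_{off}$ and dominates.

## Quantification model

`relative_abundance()` implements the fraction-of-summed-MS1-areas
definition per replicate and time point. `species_for_motif()` does the
light/heavy bookkeeping: enzymatic acetyls on the motif's sites, chemical
D3-acetyls on every remaining lysine, so light + heavy always equals the
peptide's lysine count (4 on the wild-type G4–R17 peptide, 3 on the K16R
G4–R16 peptide, where trypsin cleaves after the substituted arginine).

The detection limit (0.003% by default) is a strict-below *flag*, not a
zeroing: values exactly at the limit are detected, and masked observations
keep their values so downstream fitting can omit (the default) or censor
them. `theoretical_mz()` computes monoisotopic m/z from a single editable
constants table (light acetyl +42.010565, D3-acetyl +45.029395, proton
1.007276), treating the peptide N-terminal amine as unmodified because the
chemical derivatization precedes digestion. The computed 2+ m/z for the
mono-enzymatic wild-type species is 724.4381; the instrument reference value
724.9428 differs by about 1 Da at neutral mass for the stated composition,
an offset whose origin the source data do not resolve — the reference values
are therefore carried as metadata and never asserted against.

## Calibration and model ranking

The likelihood is additive Gaussian on relative abundances — the standard
choice in this estimation framework; the original noise model is not
published — with either a fixed $\sigma$ or a single shared $\sigma$
profiled analytically at its conditional MLE (counted as a parameter in the
AIC). Parameters are optimized on the log10 scale inside finite positive
bounds, default $10^{-5}$–$10^3$, spanning the plausible per-minute range
for a 0–180 min experiment. Multi-start L-BFGS-B takes a deterministic
first start — the supplied `theta0` if any, otherwise the midpoint of the
log10 bounds, which sits in a well-behaved basin for rate-like parameters —
and draws the remaining starts uniformly in the log-bounds from a seeded
stream, one RNG block per start, so results are deterministic given
`(data, spec, n_starts, seed)` and best-of-starts is monotone in the number
of starts. Integration failures inside the objective
return a large finite penalty (1e10) with a warning instead of raising, so
optimizers survive pathological corners of parameter space.

Families are ranked by $AIC = 2k - 2\log L$; a family is rejected when its
$\Delta AIC \ge 10$. Ties in the minimum resolve toward the model with
fewer parameters.

## Posterior uncertainty and prediction

`sample_posterior()` targets likelihood × bounded-uniform prior on the
log10 scale with an affine-invariant stretch-move ensemble sampler. The
original analysis used adaptive parallel tempering; the sampler here is a
deliberate backend substitution with the same contract — bounded uniform
priors, seeded determinism, and convergence diagnostics (acceptance rate
and split-chain $\hat R$, flagged above 1.05) rather than sampler identity.
The first half of each chain is burn-in. Credibility intervals are central
quantile intervals at 99% using linear interpolation of order statistics
(quantile type 7) — stated explicitly because 99% bands on small ensembles
are convention-sensitive.

`ensemble_predict()` simulates every retained draw (thinned to a cap) under
a scenario and reports per-(motif, time) quantile bands. The K16R
counterfactual applies `disable_site("K16")` to each draw of the
wild-type-calibrated ensemble: the model surgery removes every reaction
acetylating K16 and keeps all remaining parameter values, exactly the
"all reactions involving K16 are disabled" scenario. The headline
prediction — K12 mono-acetylation becomes the dominant product — is
reproduced; note the counterfactual is a genuine extrapolation and the
analogous published prediction also over-estimated K5/K8 acetylation
relative to mutant measurements.

`site_preference_profile()` requires the per-edge parameterization and
normalizes posterior-median rate constants within each source motif by the
motif's maximum (ties flagged, broken toward the N-terminal-most site);
the profile is invariant under global rescaling of the samples.

## The synthetic-data generator

`preset_library()` fixes four scenarios emulating the measurement structure
of the experiments: 3 replicates, time grid {0, 5, 15, 30, 60} min (5, 30
and 60 are anchored by the reported time courses; 15 is an interpolated
design point and 0 is the enzyme-free control), relative abundances on the
simplex, detection limit 0.003%, additive Gaussian noise $\sigma = 0.01$
clipped to [0, 1] and renormalized per (time, replicate).

Preset kinetic parameters are tuned by the package — not fitted values — so
the simulated envelopes land where the measured ones do: the wild-type
preset ($k^{cat}$ = 0.015/0.03/0.22/8 per min for K5/K8/K12/K16,
$k_{on} = 10$, $k_{off} = 1$, $E_{tot} = 0.25$) gives K16ac ≈ 54% at 5 min
with every motif lacking K16ac below 1%; the K16R preset reaches ≈ 13% K12ac
at 60 min with di-/tri-acetylation ≤ 2%; the zip-suppressed preset raises
$k_{off}$ 40-fold, emulating the reduction of oligo-acetylation seen when
RNA destabilizes the enzyme–substrate interaction; and the K12-preferring
preset swaps the site hierarchy the way a piccolo-type KAT5 complex does.

Two deliberate limitations of the generator: the simplex projection
(clip + renormalize) correlates the per-motif noise, so the realized
residual spread on interior cells exceeds the injected $\sigma$ by roughly a
third — the bundle therefore records the pre-projection draws, which is
where noise calibration is defined; and the generator does not emulate
spectra, retention times, positional isomer ambiguity of di-acetyl forms, or
between-preparation batch effects. Passing recovery tests on these data show
the estimation machinery is correct and well-seeded, not that real MS noise
is Gaussian.

## Problem sizes used in the shipped analyses

Fits in the analysis scripts and tests use the site-level parameterization
(4 kcat + globals) with 3–12 optimizer starts, posterior runs use 10–14
walkers for 250–800 steps (half burn-in), and ensemble predictions thin to
at most 100–200 draws. These sizes give stable model ranking (ΔAIC margins
in the hundreds), parameter recovery within 20%, and interval coverage near
nominal on the synthetic scenarios; per-edge posterior runs (34 parameters)
are exploratory and use short chains in `analysis/04_posterior.R`.

## Known limitations

* The mechanism comparison is between three stated families; mixed or
  intermediate mechanisms (partial processivity) are not in scope.
* Deacetylation, nucleosome positional structure, RNA-binding kinetics and
  acetyl-CoA depletion are excluded by design.
* Masked (below-detection-limit) points are omitted, not treated as left
  censored.
* AIC is the only ranking criterion, matching the source analysis; no
  AICc/BIC or Bayes factors.
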