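---
title: "Differential k-cone analysis: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential k-cone analysis: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcone)
```

## The model

The package works on irreversible mass-action networks. A reaction file
defines stoichiometries; reversible reactions are split into forward and
backward parts (`split_reversible()`), after which fluxes and kinetic
constants are non-negative. At steady state `S v = 0`, and with
`v_i = k_i m_i(x)`, `m_i(x) = prod_j x_j^{|s_ji|}` over substrates only,
the feasible kinetic constants form the polyhedral cone
`{k >= 0 : S M k = 0}` — the k-cone. Its extreme rays are a complete,
finite description: every steady-state-consistent kinetics is a
non-negative combination of them.

Two conditions on the same network give `T = M_n M_d^{-1}` with
`K_d = T K_n`. Working in log space, `log2 diag(T)` is the per-enzyme
expected differential activity (EDA), and because the mass-action terms
are monomials it decomposes exactly into the stoichiometry-weighted sum of
metabolite log-fold changes. This identity is asserted to machine
precision in the tests; it is the reason metabolome data alone determine
the transformation of the whole kinetic space.

Assumptions worth keeping in mind:

* **Mass action is an approximation.** Saturation (Michaelis-Menten) and
  allosteric effects are deliberately out of scope; the EDA measures the
  change in the effective first-order activity of each reaction.
* **EDA equals the true kinetic fold change only when steady-state fluxes
  match across conditions** (`k_d = T W k_n` with `W = I`). The synthetic
  scenarios document whether they hold flux constant: with a zero-order
  import, planting a fold change on a uniquely-substrated internal enzyme
  leaves fluxes unchanged, which is why those scenarios recover the planted
  value exactly in the noise-free limit.
* **Shared substrates are not separable.** Two reactions consuming the
  same metabolite pool receive related EDAs; only the metabolome, not the
  assignment to isoenzymes or parallel consumers, is observed.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cell_volume` | 1.54e-15 | L/cell | literature single-cell volume used to convert per-batch abundances to molar concentrations |
| `noise_cv` | 0.2 | — | replicate coefficient of variation of the log-normal noise; typical metabolomics replicate spread |
| `replicates` | 3 | — | three biological replicates per condition, the design the statistics target |
| planted fold | 8 | — | the magnitude of the strongest regulation the method is expected to flag |
| `alpha` | 0.05 | — | BH-adjusted significance level, also the significance leg of necessity |
| `ratio_threshold` | 3 | — | heterogeneity flag on `sigma_d / sigma_c` |
| `draws` | 10000 | — | Bayes-bootstrap Dirichlet draws; quantile noise is negligible above a few thousand |
| `lb`, `ub` | 1e-16, 1000 | flux | FBA bounds: the tiny lower bound keeps every reaction active; the upper bound is arbitrary because only flux ratios are consumed |
| `eps` (stability) | `.Machine$double.eps` | — | eigenvalue sign threshold: only roundoff separates the classes |
| `max_rays` | 2e5 | — | double-description guard; genome-scale cones blow up combinatorially and should be reduced with equilibrium constraints first |

## Statistics

**Moderated Welch test.** Per condition and reaction, sample variances of
the log2 mass-action terms are shrunk toward a scaled inverse-chi-square
prior whose hyperparameters `d0`, `s0^2` are estimated by the method of
moments on the log variances pooled across reactions and conditions (the
fit is cross-checked against an independent implementation in the tests).
The Welch statistic uses the moderated variances; its degrees of freedom
are Satterthwaite at the residual group dfs plus `d0`. This coupling is a
design decision — the combination of Welch testing with variance
moderation has no canonical formula — chosen so that `d0 = 0` recovers the
ordinary Welch test, `d0 -> Inf` a z-like test at the prior variance, and
the balanced pooled limit the usual moderated total df `d0 + d_total`. An
alternative coupling that inflated each group's df inside the
Satterthwaite formula proved anticonservative under a heteroscedastic null
and was rejected.

**Combinatorial log-fold changes.** Control lfcs are all ordered pairs of
distinct normal replicates (6 for 3 replicates; their mean is exactly zero
by antisymmetry — ordered pairs are used precisely so the stated count and
the zero mean hold). Differential lfcs are all (disease, normal) pairs
(9 for 3+3).

**Bayes bootstrap.** Uniform-Dirichlet weights over the lfc samples; the
2.5/97.5 percentiles of the weighted means form the 95% credible interval.
The 9 combinatorial samples are *interdependent* (each pair shares
replicates with others), and the Dirichlet posterior does not correct for
that: on such samples the interval understates the uncertainty of the mean
and under-covers. This is a documented caveat of the combinatorial
construction, not a defect of the interval code: the calibration test
therefore checks coverage on independent lfc samples (500 reactions,
200 samples each), the regime in which a percentile-type posterior
interval is expected to be calibrated, and the result tables carry the
dependence caveat in their metadata header.

**Heterogeneity and co-regulation.** Per reaction, `sigma_c` (control)
and `sigma_d` (differential) are standard deviations of the two lfc sample
sets; `sigma_d / sigma_c > 3` flags differential heterogeneity, and
flagged reactions are correlated (Pearson) across their differential lfc
vectors.

## Flux-variability necessity filter

Biomass-maximizing FBA (`maximize v_bm s.t. S v = 0, lb <= v <= ub`)
followed by per-reaction min/max LPs at the fixed optimum gives
`lfc_max = |log2(v_max / v_min)|`, the largest activity change a flux
rearrangement at optimal growth could mimic. A reaction is *necessary for
proliferation* when `q < alpha` **and** the smallest-magnitude lfc sample
still exceeds `lfc_max` — a worst-case rule over all combinatorial
samples (a credible-interval bound would be the natural variant; the
worst-case-over-samples rule is the stricter of the two and is what the
filter implements). `v_min` is clamped at `lb` before the ratio, so
reactions that FVA can silence get an effectively infinite `lfc_max` and
are never called necessary: the filter errs conservative.

## Stability

For each k-cone ray, interpreted as a kinetic-constant vector, the
Jacobian of `dx/dt = S v(x)` is built analytically and its eigenvalues
classify the ray: stable (all real parts `< -eps`), unstable (any
`> +eps`), else marginal. Real parts are used for complex pairs (the sign
convention for complex spectra is not canonical; real parts are the local
linear-stability criterion). Extreme rays are sparse, so metabolites
untouched by a ray's active reactions contribute structurally zero
eigenvalues; these spectator directions are excluded by default
(`active_only = TRUE`) because they are neutral by construction, not
instabilities. Genuine neutral directions inside the active subnetwork
(conserved cycles) still classify as marginal. Concentrations default to
the per-condition geometric-mean panel, matching the k-cone construction.

## Numerical choices

* **Double description**: incremental intersection starting from the
  non-negative orthant; combinatorial adjacency test on zero patterns
  (valid because the cone is pointed); degeneracy tolerance 1e-10
  relative; redundant H-representation rows removed by QR beforehand;
  rays unit-normalized and ordered lexicographically on coordinates
  rounded to 10 digits, so outputs are reproducible run to run.
* **Linear programs** (FBA/FVA, cone membership) are solved by a dense
  two-phase simplex with Bland's anti-cycling rule and tolerance 1e-9,
  written for this package after the available general-purpose simplex
  routines failed on the degenerate all-zero right-hand sides typical of
  `S v = 0` systems. Cone membership (`in_cone()`) is an elastic phase-1
  feasibility LP with tolerance 1e-7 on unit-normalized rays.
* **Steady states** are found by integrating the mass-action ODEs
  (`deSolve::lsoda`) over doubling time windows until
  `max |dx/dt| < 1e-10`; divergence and non-convergence raise errors with
  the residual.
* **Degenerate inputs**: empty cones return empty bases with a warning;
  zero mass-action terms name the offending reaction; reactions with
  missing substrate concentrations propagate as explicit `NA`s and are
  excluded from the statistics with a report, never silently zeroed;
  metabolites imputed across conditions yield lfc exactly 0 by
  construction, the conservative "missing means non-differential" reading.
* **Projection**: joint PCA over all supplied bases so conditions share
  axes; `relative_error` is defined as the unexplained-variance fraction
  of the first two components (the quantity has no canonical formula; the
  definition is stated in the output rather than assumed comparable to
  other tools); k-means uses a fixed seed and 10 restarts; when the
  requested cluster count reaches the number of distinct projected rays,
  the distinct rays themselves are the centers.

## What the synthetic generator does and does not emulate

`make_scenario()` produces exactly the study conditions the statistics
assume: a known mass-action network, simulated steady states for both
conditions, multiplicative log-normal replicate noise (`sigma` chosen so
the linear-scale CV equals `noise_cv`), a planted activity change, and a
truth table. It does **not** emulate: correlated noise across metabolites,
limits of detection / missingness mechanisms (missingness is exercised
separately in the imputation tests), saturated kinetics, or
batch effects. Passing the recovery tests therefore shows the inference
chain is correct under its own assumptions; it does not certify
performance on real data where those assumptions fail gradually.

Problem sizes used by the test suite and the acceptance script — cones and
oracles on networks of 3-15 reactions (brute-force cross-checks up to 8),
500 reactions for the statistical calibrations, 100 seeded scenarios for
the recovery rate — were chosen as the smallest sizes at which the checked
properties are statistically meaningful.

## Known limitations

* The credible intervals on combinatorial lfc samples under-cover (see
  above); treat them as descriptive spread, not calibrated posteriors.
* A cone with many reversible pairs can exceed the ray guard; constrain
  with equilibrium constants (`constrain_by_keq()`) before enumerating.
* Equilibrium constraints are implemented as `k_f - K_eq k_b = 0`; a
  concentration-adjusted variant can be expressed by rescaling `K_eq`
  with the appropriate mass-action term ratio before input.
* The heterogeneity screen compares standard deviations from ordered
  control pairs with those from differential pairs; the ordered-pair
  choice fixes `sigma_c` up to the stated convention and is recorded in
  the output metadata.
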