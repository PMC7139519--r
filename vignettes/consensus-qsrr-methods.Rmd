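---
title: "Methods: consensus GA-PLS QSRR modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus GA-PLS QSRR modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrrga)
```

## The model

Retention times are modelled on the natural-log scale, where their
distribution across structurally diverse analytes is much closer to
normal; `ln_transform()` / `inv_ln_transform()` convert between the two
scales, and errors are always reported on both (an RMSE in ln units and
an RMSE in minutes computed from back-transformed predictions are
different quantities and are never converted into one another).

The regression engine is SIMPLS partial least squares for a single
response: the cross-product $s = X^\top y$ is deflated directly, each
weight vector is normalized ($w^\top w = 1$), and scores are kept
orthonormal. On autoscaled data (columns centred and scaled to unit
$n-1$ standard deviation — which is why the model has no intercept on the
scaled scale) a PLS model with as many latent variables as the rank of
$X$ reproduces ordinary least squares; with fewer it regularizes by
projecting onto the directions of maximal X–y covariance. This is the
correct tool here because the 13 mechanistic descriptors are strongly
collinear — several of them are *exact* linear or nonlinear functions of
the frontier-orbital energies, and the minimum bond-dissociation
enthalpy correlates with the hydroxyl count at $R < -0.7$.

Model complexity is controlled by leave-one-out cross-validation:
`loo_cv_curve()` refits the model $m$ times, re-estimating the
autoscaling *inside* every fold so the held-out analyte never leaks into
the scaling parameters (a property the test suite checks directly by
perturbing a held-out response).

## Descriptor definitions and conventions

The 13 descriptors (fixed order from `descriptor_names()`) combine three
mechanistic families:

* **Hydrophobicity / solvent effects**: solvation energy
  $SE = E_\mathrm{solvent} - E_\mathrm{vacuo}$ (kcal/mol, negative =
  favourable solvation).
* **Antioxidant (HAT/SPLET) parameters** (kcal/mol): per hydroxyl site
  $s$, $BDE(s) = H_\mathrm{radical}(s) + H(\mathrm{H}^\bullet) -
  H_\mathrm{parent}$, $PA(s) = H_\mathrm{anion}(s) + H(\mathrm{H}^+) -
  H_\mathrm{parent}$, $ETE(s) = H_\mathrm{radical}(s) + H(e^-) -
  H_\mathrm{anion}(s)$. The reported scalar descriptors are taken at the
  minimum-BDE site (the first-oxidation-step site); `site_policy = "min"`
  switches to the per-quantity minimum. These three obey the exact cycle
  $BDE - (PA + ETE) = H(\mathrm{H}^\bullet) - H(\mathrm{H}^+) - H(e^-)$,
  a constant of the reference enthalpies, asserted to $10^{-9}$ in the
  tests. Proton and electron reference enthalpies default to the
  standard implicit-water values (−250.574 and −17.816 kcal/mol; 1.481
  and 0.752 in vacuo); the hydrogen-radical enthalpy depends on the
  level of theory and must be supplied by the user.
* **Electrostatics / conceptual DFT** (eV): dipole moment, NBO minimum
  charge, and the Koopmans block $IP = -E_\mathrm{HOMO}$,
  $EA = -E_\mathrm{LUMO}$, $\Delta E = IP - EA$,
  $\eta = (IP - EA)/2$, $\mu = -(IP + EA)/2$, $\omega = \mu^2 / 2\eta$.
  Two sign/factor conventions required a decision: the chemical
  potential is implemented as $\mu = -(IP+EA)/2$ so that $-\mu$ is the
  absolute electronegativity (also exposed directly as
  `electronegativity`), and the electrophilicity uses the denominator
  $2\eta$ (not $2\,\Delta E$, which differs by a factor of two). A
  non-positive frontier gap triggers a warning rather than an error —
  DFT gaps are systematically underestimated, and QSRR modelling uses
  relative rather than absolute values.

Analytes without hydroxyl groups have no HAT/SPLET descriptors; they are
carried as missing values and dropped (with a message) by the dataset
container rather than imputed. Enthalpies supplied in Hartree are
converted at 627.5095 kcal/mol.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `train_fraction` | 0.7 | 21 of 30 analytes train; round(f·m) keeps the split well-defined for any m |
| GA population | 20 | grid-search optimum for this problem class; `[10, 20]` axis exposed |
| crossover fraction | 0.8 | fraction of non-elite offspring from single-point crossover; rest cloned + mutated |
| mutation rate | 0.2 | per-bit flip probability of mutation offspring |
| elites | 2 | monotone best fitness per generation |
| max generations / stall | 100 / 10 | stop after 10 generations without best-RMSECV change (strict, 1e-12) |
| tournament size | 2 | selection pressure; not otherwise specified, configurable |
| `lv_min` | 2 | LV search range 2..rank(X) per subset; implies ≥ 2 descriptors per mask |
| `n_runs` | 1000 | full consensus analysis; tests use 25–200 to stay fast |
| knee tolerance | 2 % | see below |
| residual limit | 3 SD | Williams-plot warning limit |

The **knee rule** for choosing the LV count picks the smallest candidate
beyond which the RMSECV curve has flattened: the first $n$ whose
improvement to the next candidate, *relative to the first candidate's
RMSECV*, is below the tolerance. Normalizing by the initial RMSECV (not
the current one) makes the rule insensitive to how far the curve has
already fallen; `policy = "min"` (the grid-search criterion) is also
exposed. Ties always resolve to the smaller model.

**Masks with fewer than two descriptors** receive an infinite sentinel
fitness instead of raising an error, because the LV lower bound of 2
requires at least two columns; penalizing (rather than repairing) keeps
the evolution simple and unbiased.

**Randomness**: one master seed drives everything. `run_ga_repeats()`
draws the per-run child seeds in a single `sample.int()` call from the
master seed, so any run can be reproduced in isolation and results are
identical however the runs are scheduled. Mask fitness is deterministic,
so the memoization cache is shared across runs.

**CV-ANOVA degrees of freedom**: published tables of this kind are not
consistent with any single df convention, so the Fit df is a policy:
`"lv2"` (2 per latent variable, the default), `"n_descriptors"`, or an
explicit integer; the policy is recorded in the result. Every emitted
table is checked against the identities SS additivity, MS = SS/df and
F = MS ratio before it is returned.

**Leverages** use the training cross-product on autoscaled consensus
descriptors; a singular cross-product (possible, since several
descriptors are exactly collinear) falls back to the Moore–Penrose
pseudo-inverse with a warning. Standardized residuals for both the
training and validation sets use fitted (not cross-validated)
predictions and the training residual SD — the conventional Williams
plot.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws eight *base* quantities (SE, a latent
hydroxyl count, BDE$_{min}$, PA, $\delta_{min}$, M$_{tot}$,
$E_\mathrm{HOMO}$ and the frontier gap) from a multivariate Gaussian
with a requested correlation structure (repaired to the nearest positive
definite matrix if needed), discretizes the hydroxyl count to integers
in [0, 7], and *derives* the remaining five descriptors plus ETE through
the exact Koopmans and thermodynamic-cycle identities. Deriving rather
than sampling them is deliberate: in real data these identities hold
exactly, and the package's own invariants (gap = IP − EA, η = gap/2,
BDE − PA − ETE constant) must hold on generated data too. The default
correlation targets include the hydroxyl/BDE inverse correlation at
−0.8; discretization attenuates it slightly (the empirical value stays
within ±0.1 of the target, checked at m = 500). Retention is
$y = 2.3 + X_s\beta + \varepsilon$ in ln minutes (about 10 min at the
centre), with a default noise SD of 0.15 — the middle of the
0.1–0.3 ln-unit residual range typical of validated QSRR models — and
effect templates (`"kc18"`, `"kf5"`, `"iam"`) following the qualitative
coefficient signs of the three column chemistries (e.g. kc18: SE +0.6,
n(OH) −0.5, M$_{tot}$ −0.35 on the autoscaled scale; the weak fourth
effect of the C18-like template is omitted so the preset has three
strong and ten null descriptors).

`generate_qm_records()` inverts the descriptors module: species
enthalpies are constructed so that reassembling descriptors from the
records reproduces the intended matrix to $10^{-9}$, with extra hydroxyl
sites given strictly higher BDE/PA so the intended minimum site is
unambiguous. Its hydrogen-radical reference enthalpy (−313.0 kcal/mol)
is a synthetic, documented choice.

The generator does *not* emulate chromatographic peak shapes, gradients,
co-elution, measurement-replicate structure, or non-Gaussian descriptor
marginals. Passing tests on generated data therefore demonstrate the
correctness and statistical behaviour of the algorithms under the
assumed linear-plus-noise model — not that any particular real column
obeys that model.

## Problem sizes in the test suite

The suite exercises the study-scale configuration (m = 30 analytes, 13
descriptors, 70 % training) but reduces repetition counts where the full
analysis would be redundant for correctness: 200 GA repeats per
consensus (20 master seeds), 100 seeds for the GA-versus-exhaustive
comparison on p = 6 problems, 200 random matrices for the SIMPLS/OLS
equivalence, and 25 or fewer repeats in pipeline smoke tests. These
sizes are the package's own choice of a convincing-but-economical
evidence base; the defaults users see (`n_runs = 1000`) remain the
full-analysis values.

## Known limitations

* **Consensus selection keeps occasional chance-correlated descriptors.**
  At m = 30, a null descriptor whose sample correlation with the
  realized noise is large (likely when ten null descriptors are
  available) genuinely lowers the LOO-RMSECV objective — the effect is
  scale-free in the noise SD — so the GA's run-level optimum includes it
  in a majority of runs and the mean-occurrence threshold cannot remove
  it. Consequently the consensus reliably *contains* the generating
  descriptors with correct signs (observed in 20/20 synthetic master
  seeds), but is not guaranteed to equal the generating support exactly
  (observed in only ~20 % of seeds). This mirrors the method's behaviour
  on real data, where mechanistically implausible descriptors can ride
  into a consensus on chance correlation; interpret trailing consensus
  members (low occurrence, small coefficients) with caution.
* Koopmans IP/EA inherit the DFT band-gap underestimation; only relative
  values across a congeneric series are meaningful.
* The LOO-CV F test treats the cross-validated predictions as fixed;
  its p values are approximate, and the df policy is a convention.
* Kennard–Stone splitting is deterministic and covers descriptor space,
  but places the most extreme analytes in the training set by design, so
  external-validation errors can be optimistic for extrapolation.
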