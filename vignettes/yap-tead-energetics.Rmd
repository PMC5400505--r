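---
title: "Energetic dissection of a protein-protein interface by double mutant cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetic dissection of a protein-protein interface by double mutant cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcycle)
```

## The problem and the model

The transcription factor TEAD is activated by the coactivator YAP, whose
TEAD-binding domain is intrinsically disordered in solution and folds on
binding into two recognizable elements, an α-helix and an Ω-loop, that
dock into two separate pockets on the TEAD surface. `dmcycle` implements
the quantitative machinery for dissecting such an interface residue by
residue: alanine-scanning binding energetics measured by surface plasmon
resonance (SPR), and double mutant cycle analysis (DMCA) of the coupling
between residues across the interface.

All energetics derive from the equilibrium dissociation constant through

$$\Delta G = RT \ln K_d^{eq}, \qquad
  SE_{\Delta G} = RT \, \frac{SE_{K_d}}{K_d^{eq}},$$

with $R = 1.986\times10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 298$ K fixed
everywhere ($RT = 0.591828$ kcal/mol), and $K_d$ always in molar units
(the reference unit matters because of the logarithm). A single
mutation's effect is $\Delta\Delta G = \Delta G_{mut} - \Delta G_{wt}$.
For a pair of mutations, one on each protein, the double mutant cycle
over the four pairs (wt:wt, mY:wT, wY:mT, mY:mT) yields the coupling
energy

$$\Delta\Delta G_{int} =
  \Delta G_{mY:mT} + \Delta G_{wY:wT} - \Delta G_{mY:wT} - \Delta G_{wY:mT},$$

zero when the two residues act independently (mutational effects add,
equivalently the four $K_d$ values are multiplicative), negative for a
favorable (synergistic) coupling, positive for an unfavorable one.
Standard errors propagate as root sums of squares throughout. The
four-leg decomposition ($\Delta\Delta G_{1\ldots4}$, the effect of each
mutation on each background) is returned with every cycle; algebraically
$\Delta\Delta G_2 - \Delta\Delta G_1 = \Delta\Delta G_4 - \Delta\Delta G_3
= \Delta\Delta G_{int}$, which the tests verify to machine precision.

One published table legend prints the $\Delta\Delta G$ SE rule without
the squares. We treat that as a typographical slip and use
root-sum-of-squares propagation everywhere; it is the standard rule and
matches the printed SE values.

## From sensorgrams to $K_d^{eq}$: the six-step workflow

`determine_kd()` converts a set of SPR sensorgrams into a
quality-controlled equilibrium $K_d$:

1. **Global kinetic fit.** All curves are fitted jointly with the
   closed-form 1:1 interaction model,
   $R(t) = R_{eq}(C)\,(1 - e^{-(k_a C + k_d)t})$ during injection and
   exponential decay afterwards, with one $(k_a, k_d, R_{max})$ triple
   for the whole set. $K_d^{eq} = k_d / k_a$, with its SE from the
   parameter covariance by the delta method.
2. **Automated inspection.** The published protocol inspects sensorgrams
   visually; we use three quantitative proxies with tunable thresholds
   (`spr_config()`): equilibrium-plateau flatness (median plateau slope,
   scaled by the largest plateau so noise-dominated low-concentration
   curves don't dominate), injection-start consistency with the fitted
   model (bulk-jump proxy), and a concentration-range check against the
   fitted $K_d$.
3. **Fit-quality gates.** Relative SE of $K_d$ at most 20%, and fitted
   $R_{max}$ at least 70% of the theoretical capacity
   $R_{max}^{theo} = (MW_{analyte}/MW_{ligand}) \times R_{immobilized}
   \times n$. The 70% gate uses $R_{max}^{theo}$, not the
   saturation-scaled value, following the protocol text literally.
4. **Saturation check.** If the top analyte concentration exceeds
   $10\,K_d$, the equilibrium responses (mean of the final 10% of each
   association phase, configurable) are fitted directly with a one-site
   isotherm (`method = "saturation_direct"`).
5. **Surface activity.** Otherwise the saturation capacity is scaled by
   the active fraction of the surface estimated from a saturating
   wild-type run on the same surface:
   $R_{max}^{sat} = R_{max}^{theo} \times
   (R_{max}^{meas*}/R_{max}^{theo*})$. Experiments whose top-
   concentration response does not reach 75% of $R_{max}^{sat}$ are too
   far from saturation to quantify.
6. **Anchored isotherm.** The remaining experiments are fitted with the
   one-site-with-background isotherm plus one unweighted pseudo-point at
   $C = 50\,K_d^{init}$ carrying the saturation information; the result
   is rejected if its relative SE exceeds 10%.

Fitted $K_d$ above the 200 µM assay ceiling is **censored**: the result
reports the bound, never a number. Weak binders that fail step 5 (or the
step-3 SE gate) are also reported censored whenever the top-concentration
response itself implies a ceiling-exceeding $K_d$ through
$K_d \ge C_{top}(R_{max}^{sat}/R_{eq} - 1)$ — that is how ">200 µM"
pairs arise in practice.

### Numerical choices

* The kinetic fit runs on log-parameters (rates and $R_{max}$ stay
  positive) via Levenberg–Marquardt, trying a small grid of
  dissociation-rate starts; the covariance uses the Moore–Penrose
  inverse of $J^TJ$, so drift-dominated data that push the fit onto a
  degenerate ridge still return a (QC-rejected) result instead of
  erroring.
* The step-6 anchor is placed at the value the saturation capacity
  implies at a finite concentration, $R_{max}^{sat} \cdot f/(f+1)$ with
  $f = 50$, and is compared to the background-free model term. Anchoring
  at the asymptote itself would sit $1/51$ above the true curve and
  bias the fitted $K_d$ upward by several percent; with the correction,
  an anchor consistent with the data leaves the fit unchanged (the
  tests check this to 0.5%).
* Curves are assumed blank-referenced on input; solvent-correction
  series are out of scope.

## The cycle analysis

`dmca()` is the package's main fitting function. From a pairwise
$K_d$ table it selects the variants whose single mutation destabilizes
the complex by more than 1 kcal/mol (unmeasured variants are excluded
regardless), enumerates the Cartesian product of cycles, computes
couplings with propagated SEs, classifies them, and back-predicts
$K_d^{calc}$ for cycles whose double mutant fell beyond the ceiling.

Three thresholds matter, all configurable with defaults mirroring the
published protocol:

| parameter | default | meaning |
|---|---|---|
| `threshold` | 1.0 kcal/mol | single-mutant $\Delta\Delta G$ selection rule |
| `significance` | 0.5 kcal/mol | couplings within ±0.5 are "additive" |
| `ceiling_molar` | 2e-4 M | assay ceiling; beyond it, cycles are "n. m." |

With every $K_d$ measured at ≤15% relative SE, each $\Delta G$ carries
at most $RT \times 0.15 = 0.09$ kcal/mol and each coupling at most
$0.18$ kcal/mol (`max_propagated_se()`). The 2SE significance bound is
therefore 0.36 kcal/mol; the analysis computes and reports it but
classifies against the more conservative 0.5 kcal/mol band, following
the published choice. A censored double-mutant $K_d$ makes its cycle
`not_measurable` — the 200 µM bound is never used as a value.
Back-prediction assumes the minimum significant coupling
($\Delta\Delta G_{int} = -0.5$ kcal/mol by default):
$\Delta G_{mm}^{calc} = \Delta\Delta G_{int} + \Delta G_{mY:wT} +
\Delta G_{wY:mT} - \Delta G_{wY:wT}$; pairs with
$K_d^{calc} \le 200$ µM would have been measurable had they been
coupled at least that strongly, so their "n. m." status is informative.

Wild-type rows are keyed by the label `"wt"`; replicate rows are
averaged with SE pooling.

## Thermal-shift screening

Because TEAD is folded in isolation, a mutation can weaken binding
indirectly by destabilizing the fold. `fit_tm()` fits a two-state
Boltzmann sigmoid with linearly sloping baselines to each fluorescence
melt curve; the post-transition aggregation/quench region is trimmed at
the global intensity maximum, and the fit is invariant to affine
intensity rescaling. A derivative-based estimate (`tm_derivative()`)
serves as a model-free cross-check; the two agree for symmetric
transitions, and the sigmoid was chosen because it yields an SE
naturally (the instrument software's algorithm is undocumented, so a
small systematic offset against it cannot be excluded).

Two sign conventions appear in the source material for
$\Delta T_m$; we adopt $T_m^{mut} - T_m^{wt}$, the convention under
which all the printed values are negative except one. The exclusion
rule is applied to $|\Delta T_m| > 4$ °C — the conservative reading,
equivalent in practice since all excluded shifts are negative.

## The structure-contact utility

`shell_residues()` reproduces the selection logic that nominated the
TEAD interface residues: partner-chain residues whose minimum
heavy-atom distance to any query residue is within 5 Å. Distances are
heavy-atom by default (the atom-selection convention is unstated in the
source protocol; a side-chain-only mode is available), the first model
of multi-model files is used, and for alternate locations the
highest-occupancy conformer is kept. Because the exact atom-selection
convention is unknowable, regenerating the published 15-residue list
from a real structure is supported but deliberately not asserted
anywhere; the packaged structure fixture is synthetic.

## What the synthetic data emulate — and what they don't

The generator module produces every input the pipeline consumes, with
known ground truth:

* `simulate_sensorgram()` — exact 1:1 kinetics (verified against
  numerical ODE integration) plus additive Gaussian response noise and
  linear baseline drift. Defaults equilibrate within the published
  25–230 s injection windows. Instrument noise magnitudes are not
  stated in the source protocol; the defaults are fixture choices, not
  claims about the original data.
* `simulate_panel()` — pair energies built additively from a wild-type
  $\Delta G$, per-variant $\Delta\Delta G$, and injected couplings;
  $K_d$ perturbed by a median-preserving multiplicative log-normal
  whose relative SD equals `rel_se` (capped at the assay's stated 15%),
  with a matching SE column; censoring applied at the true-$K_d$
  ceiling.
* `simulate_melt_curve()` — two-state sigmoid with sloping baselines
  and additive noise over a 25–85 °C scan in 0.5 °C steps.

Not modeled: mass-transport limitation, bivalent analytes,
surface regeneration, DMSO bulk effects beyond a constant offset,
multi-transition melts, dye-binding artifacts. Passing recovery tests
on these synthetics therefore demonstrates the statistical correctness
of the estimators under the assay's stated noise structure, not
robustness to every artifact of real biosensor data.

## Validation scale and reproducibility

The test suite and `scripts/acceptance.R` re-derive the published
numbers from the packaged printed-value fixtures and measure
ground-truth recovery at the following problem sizes, chosen to mirror
the study's stated conditions: 100 simulated SPR experiments per
affinity decade from 10 nM to 100 µM at 1% (of $R_{max}$) response
noise; 200 simulated panels at 15% relative $K_d$ error with injected
couplings of −3.5, −1.0, 0 and +1.0 kcal/mol; 50 melt-curve replicates
at 2% amplitude noise. All simulations are seeded and bit-reproducible.

One honest limitation is recorded in every report bundle: the raw
80-entry pairwise $K_d$ table behind the published coupling matrix is
not redistributable. The packaged `reconstructed_panel()` back-derives
the double-mutant $K_d$ values from the printed couplings, so
recomputing the matrix from it validates the cycle arithmetic and the
combinatorics (9 × 7 variants, 63 cycles, 80 $K_d$ values, 7 "n. m."
cells) but is circular as a data check. Independent validation rests on
the one cycle reconstructible from main-text numbers alone
(Arg89:Asp272, via its printed $\Delta\Delta G_4$ leg) and on the
single-mutant tables, which are printed in full. One printed value
disagrees marginally with recomputation: the Val414Ala
$\Delta\Delta G$ recomputed from its whole-nanomolar $K_d$ is −0.15
kcal/mol against −0.17 printed, a rounding artifact of the 14 nM input;
comparisons with print are therefore made at printed precision.

```{r example, eval = FALSE}
rep <- reproduce_tables()
rep                     # reproduction summary with the counts above
fit <- dmca(reconstructed_panel())
summary(fit)            # coupling matrix with "n. m." cells
predict(fit)            # Kd_calc for the unmeasurable pairs
```
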