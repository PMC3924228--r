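---
title: "Crowding-constrained flux balance analysis and the emergence of carbon catabolite repression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding-constrained flux balance analysis and the emergence of carbon catabolite repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdfba)
```

## The model

Flux balance analysis (FBA) treats a metabolic network at steady state:
with stoichiometric matrix $S$ (rows = internal metabolites, columns =
reactions) and flux vector $v$, any feasible metabolic state satisfies
$S v = 0$ within flux bounds, and the cell is assumed to maximize the
flux through a biomass reaction, $\mu$. Plain FBA knows nothing about
how much catalytic protein the chosen fluxes require. The crowding
extension (FBAwMC) adds a single linear budget,

$$\sum_i a_i v_i \le B,$$

where $a_i \ge 0$ (hr·gDW/mmol) is the *crowding coefficient* of
reaction $i$ — the cytoplasmic volume demand of the enzyme needed to
carry one unit of flux — and $B$ (dimensionless, default 1) is the
fraction of cell volume available for metabolic enzymes. The sum runs
over enzymatic reactions; exchange pseudo-reactions carry no enzyme and
are excluded by default (`include_exchanges = TRUE` prices transporters
into the budget instead, which is of interest because selective uptake
also relieves competition for membrane space). Because enzyme demand is
direction-independent, reversible reactions are first split into
forward/backward pairs (`split_reversible()`), each inheriting the
parent coefficient, so the crowding sum is taken over non-negative
fluxes and the problem stays a pure LP.

Setting $B = \infty$ removes the constraint and recovers plain FBA —
the model's own negative control: every carbon-hierarchy and
acetate-overflow phenomenon below disappears in that limit.

### Degenerate optima

LP optima of flux networks are routinely non-unique. `solve_fbawmc()`
therefore runs a lexicographic second stage: among all flux vectors
attaining the optimal $\mu$, it returns the one minimizing total flux
$\sum_i v_i$ (the parsimonious convention). Uptake hierarchies reported
downstream are then deterministic, single-valued functions of the
inputs. Tolerances: primal feasibility $10^{-8}$, optimality $10^{-9}$,
both recorded in the returned `flux_state`.

The solver is a dense two-phase primal simplex with Bland's rule,
written for the small (tens of variables), highly degenerate LPs this
package produces; a brute-force vertex-enumeration oracle
(`brute_force_oracle()`), sharing no code with the simplex path, checks
it on randomly generated networks in the test suite.

## The fixture network

No crowding coefficients for a genome-scale *E. coli* model are
published alongside the experiments this package emulates, so the
package ships a deliberately small synthetic stand-in
(`build_fixture_network()`): five carbon substrates — glucose and
galactose (6 C), maltose (12 C), lactate and glycerol (3 C) — feeding a
shared pyruvate-level pool, and two routes from pyruvate to biomass
carbon:

* **OxPhos**: 1 pyruvate → 3 biomass-carbon, high crowding cost
  ($a = 0.12$) — high yield, enzyme-expensive;
* **fermentation**: 1 pyruvate → 1 biomass-carbon + 1 acetate, low
  crowding cost ($a = 0.0225$) — low yield, enzyme-cheap, with a
  reversible acetate exchange so secreted acetate can later be
  re-assimilated (at a deliberately steep cost, $a = 0.15$, so that
  ferment-then-reassimilate never undercuts direct OxPhos).

The biomass reaction drains 40 mmol biomass-carbon per gDW (the
realistic carbon content of *E. coli* dry mass), so biomass flux is the
specific growth rate in 1/hr. Per-substrate catabolism costs rise from
glucose (0.0075 per pyruvate) to glycerol (0.06), and base uptake
capacities follow transporter physiology (glucose PTS fastest at
10 mmol/gDW/hr; the maltose ABC transporter slowest at 4; the
three-carbon substrates faster in molar terms at 15). All values are
package constants fixed by two calibration checks that
`build_fixture_network()` re-runs on every construction, failing with a
report if either breaks:

1. with $B = \infty$ the optimum routes all carbon through OxPhos and
   secretes no acetate;
2. ranked by attainable growth under the budget, the substrate
   hierarchy is glucose > maltose > galactose > lactate > glycerol.

Two properties of the fixture are modeling conveniences, not claims
about *E. coli*: it is **carbon-closed** (no CO$_2$ sink; respired
carbon ends up in the biomass pool), which makes the dynamic
simulation's carbon balance exactly checkable at the cost of
unrealistically high mass yields and of equal final biomass across
substrates; and its outputs are **qualitative** — the patterns
(hierarchies, onsets, switches), not the numerical values, are the
reproducible content.

## Batch cultures (dynamic FBA)

`simulate_batch()` couples the LP to extracellular mass balances by
explicit time stepping: at each step the LP is solved with uptake
capacities from the configured kinetics (`hard_cap`, the fixed-capacity
convention, or Michaelis–Menten with per-substrate `Km`); biomass then
grows exponentially within the step at the optimal $\mu$ and
concentrations change by flux × integrated biomass × molar mass. When a
substrate would be overdrawn inside a step, the step is re-solved once
with that substrate's capacity set to the availability-limited rate;
residuals below the exhaustion threshold ($10^{-4}$ g/L) are snapped to
zero so exhaustion is a clean crossing. Acetate exchange stays
reversible throughout — reuptake after glucose exhaustion is never
scripted, it emerges when the LP finds it optimal.

Defaults mirror the emulated study design: initial OD600 0.035
(0.4 gDW/L per OD unit, display only), 2 g/L single-substrate media,
0.4 g/L each in mixed medium, `dt` = 0.01 hr. The analysis scripts use
`dt` = 0.02 hr and 10–12 hr horizons; the carbon-balance convergence
study uses `dt` ∈ {0.1, 0.03, 0.01} over 10 hr. On the fixture the
mixed culture consumes glucose first (exhausted ~3.4 hr) and glycerol
last (~6.9 hr), secretes acetate during the fast phase and
re-assimilates it after the sugars are gone, and its peak growth rate
(0.759/hr) weakly dominates every single-substrate peak (0.700/hr for
glucose) — the co-utilization advantage the crowding budget predicts.

## Chemostat steady states

At steady state a chemostat pins the growth rate to the dilution rate,
$\mu = D$. The experiments this mirrors scanned $D$ = 0.1–0.7/hr. How
substrate availability couples to $D$ is a modeling choice the source
experiments leave open; the package's closure is substrate-limited:
all maximum uptake capacities $U$ are scaled by a common factor
$\lambda(D)$, found by bisection (tolerance $10^{-8}$ on $\mu$), such
that the FBAwMC optimum satisfies $\mu(\lambda U) = D$. Per-substrate
scaling is available as an option (`per_substrate`), joint scaling is
the documented default. The feed contains no acetate, so acetate
reuptake is disabled in the chemostat (it remains enabled in batch).
Residual medium concentrations are deliberately not modeled — the
simulator lives in flux/ratio space, since mapping fluxes back to g/L
would need volumetric biomass data the model does not produce.
$D > \mu_{max}$ is washout: an error for a single point, a flagged row
in a scan.

Each substrate's contribution is summarized by the carbon-weighted
consumption ratio $r_j = v_j c_j / \sum_k v_k c_k$ ($c_j$ = carbon
atoms per molecule). On the fixture the scan shows the phenomenon the
package exists to reproduce:

* below $D^* = 0.6$/hr the crowding constraint is slack, all five
  substrates are co-consumed at fixed ratios, and no acetate is
  secreted — metabolism is substrate-limited and purely oxidative;
* at $D^*$ the constraint saturates (`crowding_lhs` = budget) and both
  transitions happen at once: uptake turns selective (glucose's ratio
  rises monotonically, 0.24 → 0.46, and is the largest of all ratios
  at 0.7/hr; lactate and glycerol drop out entirely) and acetate
  secretion switches on and grows steeply (0 → 28 mmol/gDW/hr);
* with $B = \infty$ the ratios are flat in $D$ and acetate never
  appears.

Carbon catabolite repression, in other words, emerges here without any
regulatory machinery: it is the LP's optimal reallocation of a finite
enzyme-volume budget at high growth demand.

## Descriptive kinetics

The analysis helpers implement the summary statistics used around such
experiments, with their conventions documented:

* `growth_rate()`: $GR_t = \ln(OD_t/OD_{t-1})/\Delta t$. The log-ratio
  form is the default because it is the only dimensionally consistent
  reading (units 1/hr) and is exact for exponential growth; the raw
  ratio form is exposed for comparison.
* `normalize_to_biomass()`: substrate concentration divided by OD600
  pointwise (a flag switches to final-OD normalization, since either
  convention appears in practice), rescaled to start at 1; grids are
  aligned by linear interpolation, never extrapolation.
* `fit_one_phase_decay()`: $y(t) = plateau + (y_0 - plateau)e^{-Kt}$
  by Levenberg–Marquardt with $K$ bounded positive and start values
  from a log-linear regression; the half-life $\ln 2 / K$ is the time
  to the midpoint between $y_0$ and the plateau. The fit is
  scale-equivariant, and on noiseless data recovers $K$ to $10^{-8}$.
* `cell_density_distribution()`: $CDD_{\rho_i} = OD_{\rho_i} / \sum_i
  OD_{\rho_i}$ over the eight Ficoll step-gradient layers (1.19, 1.18,
  1.16, 1.14, 1.12, 1.10, 1.08, 1.06 g/ml), after per-layer blank
  subtraction (negatives clipped to zero with a warning), summarized by
  the modal layer and the OD-weighted mean density.
* `promoter_activity()` / `promoter_fold_ratio()`: GFP/OD600 and its
  induced/uninduced ratio.

## Synthetic data and what passing tests show

Every input the analysis functions consume can be generated with known
ground truth: noisy batch observations sampled from a simulated
trajectory at 30-minute intervals, one-phase-decay series, Ficoll
gradient profiles (Gaussian mass over the discrete layers plus blank
and read noise), and paired induction time courses. Noise defaults (2%
multiplicative lognormal CV on OD-like quantities, 0.002 OD additive on
gradient reads) resemble plate-reader variability; they are documented
choices, not data-derived. Each generator draws from its own RNG stream
keyed by (seed, generator name), so identical seeds are byte-identical
and adding generators never perturbs existing output.

The recovery studies the tests run — median relative error of $K$ over
200 noisy replicates ≤ 5% (observed ≈ 2%), gradient mean-density bias
≤ 0.005 g/ml over 100 profiles, induction fold recovered within a few
percent — establish that the pipeline is *self-consistent*: it recovers
the truth of data shaped like its own assumptions. They do not validate
the generators against real measurements, which show lag phases,
heteroscedastic assay noise, and instrument drift that these generators
deliberately omit.

## Known limitations

* The fixture's crowding coefficients are synthetic; model outputs are
  patterns, not predictions of measured rates or concentrations.
* Carbon closure inflates yields and equalizes final biomass across
  substrates, so the observed differences in maximal culture density
  between substrates are outside the fixture's reach.
* The batch simulator has no lag phase, pH, oxygen transfer, or
  single-cell heterogeneity; the chemostat simulator has no volumetric
  state (cell volume and buoyant density are experimental observables
  with no equation in this model).
* Strain deletions are representable only as network edits (e.g.
  zeroing the glucose exchange bound to mimic a PTS-deficient mutant);
  no gene–protein–reaction layer exists.
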