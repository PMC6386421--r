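---
title: "Methods: a thermodynamic consumer-resource model of microbial community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a thermodynamic consumer-resource model of microbial community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermocrm)
```

## The model

`thermocrm` simulates the assembly of microbial communities in which the only
limiting factor for growth is usable energy. `S` consumer species compete for
`M` substitutable resources in a chemostat. Each cell of species `i` imports
energy from resource `a` at a rate set by its uptake coefficient and the
resource concentration,

    J_in[i, a] = w_a * sigma(c_ia * R_a),

where `w_a` is the energy density of resource `a` and `sigma` is the
functional response (linear Type-I by default, optionally a Monod form
`sigma(x) = sigma_max * x / (sigma_max + x)`, which has unit slope at the
origin and so reduces to Type-I at low uptake). A fraction `l_a` of the
energy imported from resource `a` leaks back into the environment as
metabolic byproducts; the remainder powers growth,

    J_grow[i] = sum_a (1 - l_a) * J_in[i, a],
    dN_i/dt   = g_i * N_i * (J_grow[i] - m_i).

Because `l_a` lies in `[0, 1]`, no cell can generate more usable power than
it imports: the leakage parameterization builds the second law of
thermodynamics into the bookkeeping. The leaked energy is partitioned over
byproduct types by a shared, column-stochastic metabolic matrix `D_ba` (the
fraction of energy leaked from resource `a` that re-enters the environment
as resource `b`), giving the secretion fluxes

    J_out[i, b] = sum_a D_ba * l_a * J_in[i, a]

and the resource dynamics

    dR_a/dt = kappa_a - R_a / tau_R + sum_j N_j * (nu_out[j, a] - nu_in[j, a]),

with mass fluxes `nu = J / w`. The chemostat supplies a single external
resource (index 1 in R, "resource 0" in the labels): `kappa = (kappa_0, 0,
..., 0)`, and every resource is diluted on the timescale `tau_R`.

Summing `w_a * dR_a/dt` over resources at a fixed point yields the global
conservation law used throughout the tests:

    sum(w * kappa) = sum(w * Rbar) / tau_R + sum(Nbar * m).

Equivalently, every surviving species' retained influx equals its
maintenance cost, `sum_a (1 - l_a) J_in[i, a] = m_i`.

## Units and default parameters

The energy-flux scale is fixed by setting the pool-mean maintenance cost to
1, and the time scale by `tau_R = 1`; all defaults are expressed in these
units.

| parameter | default | meaning |
|---|---|---|
| `S`, `M` | 200, 100 | pool species, resource types |
| `mean_preferred` | 10 | high-preference resources per species (mean) |
| `high_value` / `baseline_value` | 1 / 0.01 | uptake coefficients |
| `cost_mean`, `cost_sd` | 1, 0.1 | maintenance cost distribution |
| `g_i` | 1 | growth factor (sets only the transient timescale) |
| `w_a` | 1 | energy densities |
| `l_a` | uniform `l` | leakage fraction, the main control parameter |
| `w0k0` | — | supplied energy flux `w_0 * kappa_0`, the other control |
| `tau_R` | 1 | dilution timescale |
| `sigma_max` | 10 | Monod saturation (only with `response = "monod"`) |

Communities are seeded with random 100-species subsets of the pool
(`draw_community_subsets()`), emulating stochastic colonization, and started
from a fresh chemostat plus a small inoculum: `N_i(0) = 0.01`, the supplied
resource at its species-free level `kappa_0 * tau_R`, all byproducts at 0.
The initial abundance only sets the transient; the steady state is
insensitive to it as long as it is well above the extinction threshold.

## The random pool generator

The generator defines the study conditions; its defaults are not tuning
knobs.

* **Consumer matrix.** Each entry is independently `1` with probability
  `p = mean_preferred / M` and `0.01` otherwise — "10 preferred resources on
  average" implemented as i.i.d. Bernoulli entries rather than exactly 10 per
  row, the simplest scheme consistent with a mean. The Bernoulli mixture has
  `<c> = 0.109` and `<c^2> = 0.10009`, so the expected niche overlap
  (cosine similarity of uptake vectors) is `<c>^2/<c^2> = 0.1187`.
* **Variant schemes.** `gamma` matches both binary moments exactly.
  `gaussian` draws from a normal with the binary-matched mean and sd,
  truncated at 0 by resampling; a zero-truncated normal cannot reach the
  binary mixture's coefficient of variation (2.7), so its realized moments
  sit higher — it is a robustness variant, not an exact match.
* **Metabolic matrix.** Columns are independent Dirichlet draws. The exact
  sparsity scheme is a design choice of this package: per column, secretion
  weights are drawn once from a lognormal (`sdlog = 1`) and scaled to a total
  concentration of `0.2 * M`, which concentrates each column on a handful of
  byproducts; `dense` (flat concentration 1) and `uniform` (deterministic
  `1/M`) options reproduce progressively less structured community
  metabolisms.
* **Costs.** `m_i = 1 + Normal(0, 0.1)`, resampled (not clipped) when a draw
  is non-positive, so the mean is preserved. The cost jitter breaks ties
  between species with similar consumption profiles.
* **Overlap tuning.** `spec_for_target_overlap()` retunes the binary family
  to any target mean overlap while holding the total uptake capacity
  `10 * 1 + 90 * 0.01 = 10.9` fixed: the baseline value is freed first
  (raising it increases overlap up to 1 as all entries equalize); targets
  below the baseline-free floor `p` are reached by lowering the preference
  probability with baseline 0. With baseline 0 a species can draw an
  all-zero row; such species simply cannot feed, and realized overlap is
  measured over the feeding species.

## Numerical choices

* **Integration.** `deSolve::lsoda` (stiff-capable, adaptive) in blocks of
  500 time units, `rtol = 1e-8`, `atol = 1e-10`. Between blocks, abundances
  below `1e-6` are set to exactly 0 — extinction by thresholding rather than
  event detection, which is robust for the 300-dimensional stiff systems
  here, and the extinct rows are dropped from the active system for speed.
  The integrator clips transiently negative values when evaluating rates;
  the rhs itself is pure.
* **Convergence.** A run is converged when every survivor's per-capita
  growth residual `|J_grow - m_i| / m_i` and the relative resource drift
  fall below `1e-6`. Runs that exhaust `max_time = 1e5` are returned with
  `converged = FALSE` — typically communities containing a near-neutral
  species decaying on a timescale longer than the budget (residuals around
  `1e-5`). They are flagged, never silently accepted.
* **Susceptibilities.** `dRbar_a/dkappa_a` is estimated by a forward finite
  difference (`delta_kappa = 0.1` in units of the mean maintenance cost),
  re-equilibrating from the baseline steady state. Re-invasion from the
  regional pool is disallowed: extinct species stay extinct (their rates are
  identically zero), though further extinctions can occur. Entries whose
  perturbed system fails to converge are reported as `NA`, never fabricated.
* **Flux networks.** The community flux matrix `J_ba = D_ba l_a sum_i N_i
  w_a sigma(c_ia Rbar_a)` is pruned at 1% of its largest entry (relative to
  the global maximum, not per node). Cycle analysis (Kahn's topological
  sort) excludes self-loops `a -> a`: the question of interest is whether
  distinct resources admit a definite order of energy succession, and a
  Dirichlet-sampled `D` has no zero-diagonal constraint, so a resource can
  trivially "secrete itself". Reachability from the supplied resource uses
  the pruned directed edges.
* **Presence/absence and NODF.** Species are "present" above a configurable
  relative-abundance threshold (0 by default; 0.5% is the convention for
  sequencing data). The NODF implementation scores every unordered row pair
  and column pair from the larger fill to the smaller (equal fills score 0),
  which makes it independent of matrix ordering and identical to the
  canonical sorted-matrix NODF. Null models: `equiprobable` shuffles all
  entries (preserving total fill); `proportional` draws each entry Bernoulli
  with the mean of its row and column fill fractions. Small matrices have
  broad null distributions — a 3x3 perfectly nested triangle is *not*
  significantly nested (null sd of NODF is about 38 there); separation
  requires tens of rows/columns.
* **PCA.** Performed on relative abundances (compositions), mean-centered,
  via `stats::prcomp`; component signs follow the largest-magnitude-loading
  convention so projections are deterministic. The k-means/silhouette output
  of `run_beta_diversity()` is a descriptive diagnostic of clustering, not
  part of the model's mathematics.

## Experiment design

* **Phase diagram.** One regional pool (and one metabolic matrix) is shared
  across the whole `(w0k0, l)` grid — the same 200 species experience every
  environment — so all communities inhabit one species universe and can be
  pooled into a single presence/absence matrix for nestedness and
  beta-diversity analysis. The default grid is 10 log-spaced energy fluxes
  (10–1000) by 10 leakage values (0.05–0.95), 10 communities per point
  (1,000 communities), and always contains the three reference examples:
  syntrophy-limited (1000, 0.1), energy-limited (28, 0.6) — both
  resource-limited — and the diverse, similarity-limited regime (1000, 0.9).
* **Overlap sweep.** Pools (and their metabolic matrices) are regenerated
  per overlap value and replicate from the tuned sampling spec; richness is
  regressed on the target overlap by OLS per parameter set.
* **Size scaling.** Proportional scaling holds `S/M = 2`, subsets of `M`
  species, and `mean_preferred = 0.1 * M` fixed while `M` grows.

## Problem sizes used by the shipped tests and report

The test suite and the acceptance report run at "desk scale", chosen as the
smallest ensembles at which each phenomenon is unambiguous: full-scale
(S = 200, M = 100) 10-community ensembles for the three reference examples;
a 5x5 grid with 10 communities per point at M = 40 (S = 80, subsets of 40)
for nestedness; 3 pools x 5 communities per overlap value at M = 40 for the
overlap sweep; susceptibilities from a 20-resource sample (tests) or all 99
byproduct resources (report). At these sizes the suite reproduces the
regime ordering of richness, the modal Simpson flux diversities (2 vs 10),
resource pinning two orders of magnitude below `tau_R`, nestedness z-scores
far above both null models, and the negative richness-overlap slope specific
to the diverse regime.

## What the generator does and does not emulate

The synthetic pools capture the statistical structure the analysis needs —
sparse binary-like uptake preferences, random shared core metabolism,
near-degenerate maintenance costs, stochastic colonization — and none of the
biology it abstracts away: no phylogenetic or modular structure in `c`, no
family-level metabolic specialization, no demographic noise, no invasion
during dynamics, no spatial structure, no temporal supply fluctuations, no
non-substitutable resources, and no explicit terminal waste products. Light
as an energy source would require a different import term. Passing tests
therefore certify the model's internal laws and its macroecological
signatures under these idealized conditions, not quantitative predictions
for any particular real community.

## Known limitations

* Communities with near-neutral species pairs can exceed the integration
  budget and return `converged = FALSE`; downstream observables warn.
* The Dirichlet sparsity scheme is a package choice (the construction used
  for the original figures is not published in the main text); topology
  statistics of the flux networks — in particular how often moderate-leakage
  resource-limited communities contain small reciprocal byproduct loops —
  depend on it.
* NODF z-scores depend on ensemble size; the proportional null is far more
  conservative than the equiprobable shuffle.
* At very high `w0k0` and very low leakage the supplied resource
  concentration is large and stiff transients make integration slowest.
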