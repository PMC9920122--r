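---
title: "Energy landscape analysis with pairwise maximum entropy models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscape analysis with pairwise maximum entropy models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(energyscape)
```

## The model

`energyscape` describes the joint activity of a small network of N brain
regions by the pairwise maximum entropy (Ising) model over binary activity
patterns σ ∈ {−1, +1}ᴺ:

$$P(\sigma \mid h, J) = \frac{e^{-E(\sigma \mid h, J)}}{\sum_{\sigma'} e^{-E(\sigma' \mid h, J)}},
\qquad
E(\sigma \mid h, J) = -\sum_i h_i \sigma_i - \tfrac12 \sum_i \sum_{j \ne i} J_{ij} \sigma_i \sigma_j .$$

`h[i]` is the baseline tendency of region *i* to be active; `J[i, j]`
(symmetric, zero diagonal) is the pairwise interaction between regions *i*
and *j*. With the ½ prefactor on the double sum, each unordered pair
contributes `J_ij σ_i σ_j` once. Energies are dimensionless (natural-log
units, implicit temperature 1), and probability is strictly monotone in
−energy: low-energy patterns are the frequently visited ones.

This is the maximum-entropy distribution constrained to match the first and
second empirical moments, so it is the least-committal pairwise description
of the data. It deliberately ignores temporal order: the likelihood is a
product over time points, and everything downstream treats the series as
i.i.d. draws.

### State indexing

All 2ᴺ patterns are numbered 1-based with region 1 as the most significant
bit and active = bit 1, so the all-inactive pattern is state 1 and the
all-active pattern is state 2ᴺ (1024 for a 10-region attention-type
network). The convention is fixed by `encode_state()`/`decode_state()` and
used everywhere (figure axes, minima tables, signature reports). Because
every operation enumerates all 2ᴺ states, the package refuses N > 20
outright, and network configurations are capped at 12 effective regions —
past that the exact fit is impractical anyway.

## From raw tables to binary patterns

* **Binarization** (`binarize()`): each region's continuous signal is
  thresholded at that region's own time mean — above the mean is +1, at or
  below is −1. The at-the-mean tie maps to −1 for determinism; with
  continuous recordings ties have measure zero, the rule only matters for
  integer-valued test fixtures. A zero-variance region has no meaningful
  threshold and raises an error naming the region. Thresholds are
  per subject and per region: each subject is binarized against its own
  means before any group pooling.
* **Bilateral reduction** (`reduce_bilateral()`): networks wider than the
  12-region ceiling (an 18-region default-mode or 14-region visual set) are
  reduced by averaging homologous left/right pairs *on the continuous
  signals, before binarization*, giving 9 and 7 merged regions
  respectively.
* **Group concatenation** (`concatenate_group()`): group-level models are
  fitted to the per-subject binarized series concatenated along time.
  Binarization is not re-applied after concatenation, so group statistics
  are duration-weighted averages of subject statistics. Group landscapes
  come from these concatenated fits, not from averaging per-subject
  landscapes.

## Fitting

`pmem()` maximizes the log-likelihood by gradient ascent. The gradient per
observation is exactly (empirical − model) moments, so the update is

$$h_i \mathrel{+}= \epsilon\,(\langle\sigma_i\rangle_{\text{emp}} - \langle\sigma_i\rangle_{\text{mod}}),
\qquad
J_{ij} \mathrel{+}= \epsilon\,(\langle\sigma_i\sigma_j\rangle_{\text{emp}} - \langle\sigma_i\sigma_j\rangle_{\text{mod}}),$$

with model moments computed exactly by summation over all 2ᴺ states at each
step. Convergence is declared when the largest absolute moment mismatch
drops below `tolerance` — the maximum-likelihood stationarity condition
itself, which doubles as the primary correctness oracle in the tests.

Numerical choices, all tunable through `pmem()` arguments:

* initialization at `h = 0, J = 0` (the uniform model). The log-likelihood
  is concave in (h, J), so the optimum is unique and initialization affects
  only speed;
* default step ε = 0.1, tolerance 1e−5, at most 50,000 updates;
* by default a step that would lower the likelihood is rejected and ε
  halved, then allowed to recover slowly (×1.05 per accepted step, capped
  at the initial ε). The decrease test tolerates ~1e−12 relative noise so
  floating-point jitter near the optimum cannot deflate the step size.
  `adapt = FALSE` gives plain fixed-step ascent, whose monotone likelihood
  is itself property-tested;
* the partition function is evaluated with a max-shift (log-sum-exp), so
  well-defined parameters cannot overflow; non-finite parameters abort with
  advice to lower the learning rate. Non-convergence within the iteration
  budget is reported honestly in the fitted object, not raised as an error;
* patterns absent from the data enter only through the partition function —
  no pseudocounts.

Fitted objects carry the standard methods (`print`, `summary`, `coef`,
`logLik`, `residuals` — the moment mismatches —, `predict` for state
energies/probabilities, `simulate` for exact draws, `plot` for the
empirical-vs-model moment diagnostic).

## The landscape

`energy_landscape()` enumerates all 2ᴺ energies and extracts:

* **local minima** — states strictly below all N Hamming-1 neighbours.
  Strict inequality means plateaus are not minima; with continuous-valued
  energies exact ties are measure-zero, and on synthetic integer fixtures
  the behaviour is deterministic. All strict minima are kept (no depth
  pruning);
* **basins** — steepest-descent attribution: from each state, repeatedly
  step to the lowest-energy neighbour while one is strictly lower; ties
  resolve to the lowest state index, as do all tie-breaks in the package;
* **minimax barriers** (`minimax_barrier()`) — over all hypercube paths
  between two states, the minimal achievable value of the path's maximum
  energy, computed by a Dijkstra variant whose path cost is the running
  maximum;
* the **disconnectivity tree** (`disconnectivity_tree()`) — built by a
  threshold sweep: activate states in ascending energy order and union
  Hamming-adjacent active components, recording an internal node whenever
  two minima-bearing components join. By the minimax/ultrametric
  correspondence this is equivalent to the Dijkstra formulation; the test
  suite asserts the equivalence (union-find LCA barrier = Dijkstra barrier
  = exhaustive path enumeration) on dozens of random landscapes rather than
  assuming it. Trees export as indented text, Newick strings with barrier
  annotations (`to_newick()`), `hclust` objects, and the classic
  leaves-at-their-energy plot.

## The group screen

For every network, candidate states are the union of both groups' local
minima. Each candidate is tested by a two-sample t-test (pooled-variance
Student by default — the study design this emulates has unequal group sizes
but similar within-group protocols; Welch is a flag away) on per-subject
energies: each subject gets its own `pmem()` fit and the candidate state's
energy is evaluated under that subject's parameters. The family-wise level
α = 0.05 is Bonferroni-divided by M, the total minima count pooled over all
networks *and both groups* — a state that is a minimum in both groups is
tested once but counted twice in M, which is conservative and mirrors how
published minima tallies are constructed (a seven-network tally of
11 + 21 + 7 + 52 + 24 + 4 + 6 gives M = 125 and a corrected level of
0.0004). Reports carry per-group mean energies so the direction of an
effect (which group sits lower) is readable, and two-sided p-values
throughout.

How per-subject energy samples are obtained is genuinely underdetermined in
this literature; per-subject maximum-likelihood fits are the package's
choice, being the only option that needs no extra windowing parameters.

## The synthetic generator

`sample_patterns()` draws i.i.d. states exactly from the enumerated
Boltzmann distribution (inverse-CDF over 2ᴺ probabilities). Exact sampling
rather than MCMC removes mixing-time concerns entirely at these scales.
`make_two_group_dataset()` builds a full two-group study: per-subject,
per-group independent draws with subject seeds derived deterministically
from (study seed, group index, subject index), so datasets are reproducible
byte-for-byte and subjects are independent. `make_continuous_surrogate()`
adds Gaussian noise on top of ±1 so the binarization stage can be exercised
end-to-end; it verifies that re-binarization recovers the source series and
warns when the noise or imbalance makes that fail.

Generator defaults, chosen once as a realistic emulation of the two-group
resting-state design this package targets: N = 10 regions (an
attention-network-sized system), uniform ferromagnetic coupling 0.1 with
N(0, 0.05) bias jitter, 23 + 47 subjects, 500 time points per subject.
Group effects are modelled by scaling one group's couplings
(`scale_couplings()`), which raises that group's energy at the cooperative
all-active/all-inactive states.

What the generator does *not* emulate: temporal autocorrelation (matching
the product-form likelihood), hemodynamic forward models, scanner noise,
motion artefacts, or any preprocessing upstream of extracted ROI tables.
Passing tests therefore certify the statistical machinery on data that
satisfies the model's assumptions; they cannot certify those assumptions
for real fMRI.

## Problem sizes used in the test suite

The suite validates each claim at the smallest scale that exercises it:
landscape oracles on 50 random N ≤ 4 landscapes; parameter recovery at
N = 6 with 100,000 exact samples (correlation ≥ 0.95 between true and
fitted h and J); the null calibration of the screen with 200 replicate
two-group studies at N = 4, 8 subjects per group, 200 time points each,
thresholded at the M = 125 corrected level (family-wise error must stay
within binomial tolerance of 0.05); and the power scenario at the
generator's N = 10 defaults with 20 subjects per group, 2,000 time points
and couplings halved in one group, which must flag the all-active and
all-inactive states with the stronger-coupling group at lower energy.

## Known limitations

* Exhaustive enumeration bounds N; wider networks must be reduced
  (bilaterally or by coarser parcellation) before fitting.
* The i.i.d. likelihood ignores the strong temporal autocorrelation of real
  BOLD signals; fitted models describe the marginal pattern distribution,
  not dynamics, and effective sample sizes for the t-tests are nominal.
* Bonferroni with M counted over groups and networks is conservative;
  no FDR or permutation alternative is provided.
* Inter-network interactions are out of scope: each network is modelled in
  isolation.
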