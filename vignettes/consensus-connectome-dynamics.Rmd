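---
title: "Consensus connectome dynamics: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus connectome dynamics: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdyn)
```

## The phenomenon

A braingraph (connectome) is an undirected graph whose nodes are
anatomically identified gray-matter regions and whose edges mark
discovered axonal fiber connections. Given an ensemble of n subject
braingraphs over one shared atlas, call an edge *k-frequent* if it is
present in at least k of the n graphs, and call the graph of all
k-frequent edges the *k-consensus connectome*. As k decreases from n to
1, the inclusion condition relaxes, so the consensus connectomes are
nested and grow. The striking empirical observation — consensus
connectome dynamics (CCD) — is that the new edges do not appear at random
places: they overwhelmingly attach to edges already present, so the
growing graph looks like a developing, tree-like structure. A convenient
scalar signature is the number of *isolated* edges: an edge newly
appearing at threshold k that touches no other edge of the k-consensus
graph. In real 418-subject ensembles over 1015 nodes the cumulative
isolated-edge total stays remarkably small (tens, against tens of
thousands of edges).

This package implements the three computational pillars around that
observation:

1. **Consensus machinery** (`edge_frequencies`, `k_consensus`,
   `ccd_trajectory`, `appearance_orders`): per-edge subject frequencies,
   the per-step trajectory (edge counts, new edges, new isolated edges)
   with step i corresponding to the (n+1-i)-consensus connectome, and the
   appearance step n+1-f of an edge of frequency f (vertices appear at
   the earliest step of their incident edges).

2. **A robustness statistic** (`quarter_partition`, `discordance`,
   `quarter_set_robustness`): is the appearance order a property of the
   brain or of the particular sample? Subjects are split into 4 balanced
   "quarter sets"; for two random distinct quarters X and Y and two
   random edges e, f common to all quarters, we estimate the probability
   that e appears strictly before f under X while f appears strictly
   before e under Y (or vice versa). For random orders this is 1/2; the
   smaller the estimate, the more robust the order.

3. **A generative model** (`dpa`, `simulate`, `calibrate_C`): a
   doubly-preferential attachment (DPA) random graph on a fixed node set
   that reproduces both the exponential edge-count growth and the small
   isolated-edge totals of the real dynamics.

## The DPA model

The model lives on N nodes (default 1015). Each step adds every
currently absent pair uv independently with probability

$$p_{uv} = \frac{B}{2(N-1)}\left(\deg u + \deg v\right) + C,$$

degrees frozen from the previous step. It is "doubly" preferential
because both endpoints contribute their degree, unlike vertex-arrival
preferential attachment where one endpoint is always the newborn vertex;
here all nodes exist from the start and only edges arrive, mirroring how
consensus edges materialize among fixed ROIs.

Summing the B term over **all** pairs gives the expectation identity

$$\sum_{u<v}\frac{B}{2(N-1)}(\deg u+\deg v)=B\,|E|,$$

so the edge count grows by the factor 1+B per step and follows
approximately $\lfloor A\rfloor e^{Bk}$ from a $\lfloor A\rfloor$-edge
start. The defaults A = 46.37 and B = 0.014 are the amplitude and rate
obtained by log-linear regression of the real 1015-node edge-count curve
(`fit_exponential` performs exactly this regression). With C = 0 the
model can never create an edge between two zero-degree nodes; the small
constant C (default 7.6e-7 per absent pair per step) licenses such
"isolated" edges at a realistic rate.

Parameters, units and defaults:

| parameter | meaning | default |
|---|---|---|
| N | nodes (atlas size) | 1015 |
| A | exponential amplitude (edges) | 46.37 |
| B | growth rate per step | 0.014 |
| C | per-pair isolated-edge probability per step | 7.6e-7 |
| D | nodes eligible for the initial graph | 60 |
| steps | growth steps (one per consensus threshold) | 418 |

Two bookkeeping corrections matter:

* **Initial edge count.** The C term contributes an expected
  $\binom{N}{2}C$ edges per step; accumulated across the geometric
  growth this inflates the curve by $\binom{N}{2}C/B$ edges, so the
  initial graph is shrunk to
  $\lfloor A-\binom{N}{2}C/B+0.5\rfloor$ edges
  (`adjusted_initial_edges`; 46 edges when C = 0, 18 at the default C).
  We read the correction as the binomial coefficient over pairs — an
  N/2 reading would make it numerically negligible and contradict its
  derivation from the per-step expectation $\binom{N}{2}C$.

* **D is a free parameter.** The edge-count curve identifies A and B but
  says nothing about how concentrated the initial 18–46 edges are. The
  default D = 60 makes the initial graph non-trivially connected; it is
  configurable and documented as unidentified.

### Numerical and algorithmic choices

* Candidate edges each step are only the currently absent pairs, so
  growth is monotone; degrees are updated synchronously after the step.
  The identity above deliberately sums over all pairs (the analytic
  approximation "not accounting for multiple edges") and is enforced to
  machine precision in `expected_new_edges` and the tests.
* A simulated new edge is counted isolated when neither endpoint had
  positive degree before the step *and* it shares no endpoint with
  another same-step arrival — i.e. isolation is judged in the full
  post-step graph, the same rule the consensus trajectory applies.
* $p_{uv}$ is clipped to [0, 1] defensively; with the default parameters
  the maximum is B + C < 1 and the clip never fires.
* One run draws a single Bernoulli vector over the ~5.1e5 absent pairs
  per step (vectorized; a full 418-step run at N = 1015 takes seconds).
  Run r of a batch uses seed `seed + r - 1`, making batches reproducible
  run by run.
* The "plateau" is simply the cumulative isolated count at the final
  step; no curve-shape detection is attempted.

### Calibrating C

Because two isolated edges almost never arrive at the same node in one
step, the cumulative isolated total responds almost linearly to C.
`calibrate_C` exploits this: simulate at a provisional C, divide C by
the ratio of the simulated total to the target, and iterate (default
tolerance 5%, at most 5 iterations). Targeting a total of ~52 — the
midpoint of the real curve's 50–55 plateau — recovers C within a few
percent of 7.6e-7 at the full scale.

## The discordance statistic

`discordance` estimates, by Monte-Carlo sampling with replacement
(default 1e6 samples; an exhaustive mode enumerates all pairs for small
item sets), the probability that a random item pair appears in strictly
opposite order in two random distinct groups. Two design points are
forced by the statistic's null value:

* Reversal is counted in **either** direction. One-directional counting
  would give a 1/4 null, not the stated 1/2.
* Ties — equal appearance steps — are concordant, since a reversal
  requires "strictly before" in both groups. With few subjects per
  group, frequencies collide often; tie mass therefore pulls even a
  perfectly exchangeable null somewhat below 1/2 (the tests budget for
  this: the synthetic null check uses a ±0.1 band around 1/2 rather
  than Monte-Carlo error alone, while the tie-free order null is checked
  against 1/2 at three standard errors).

The reported standard error is the binomial
$\sqrt{p(1-p)/\text{samples}}$, which describes sampling noise for the
given ensembles; variation across re-partitions is visible by changing
the seed. The cross-ensemble mode draws X from one ensemble's quarters
and Y from another's, which is the generic form of the deterministic-
versus-probabilistic tractography comparison; nothing
tractography-specific is implemented.

Whether the original quartering was random or ordered by subject id, and
how many samples were drawn, is not recorded in the source material;
this implementation makes both explicit (`quarter_partition(seed = )`,
`n_samples`).

## The synthetic generator

`planted_model` + `sample_ensemble` produce ensembles with a **planted
developmental order**: edge ranks are recorded from a run of the DPA
simulator itself (so generator and simulator test each other), and each
edge receives a per-subject inclusion probability interpolating linearly
from `q_max` at rank 1 to `q_min` at the last rank. The `coupling`
parameter scales that gradient; at 0 every edge gets the constant
probability `(q_max + q_min)/2`, an exchangeable null with no order
information. Subjects are independent Bernoulli draws per edge.

Default test scale — N = 100 nodes, ~600 edges, 100–400 subjects,
q from 0.95 to 0.05 — runs the full pipeline in seconds and yields the
expected contrast: Spearman correlation above 0.8 between planted rank
and CCD appearance step, quarter-set discordance below 0.25 under full
coupling versus ~0.5 under the null.

What the generator does *not* emulate: anatomical parcellation and
geometry, realistic degree distributions, inter-subject correlation of
edge noise, and tractography artifacts. Passing tests therefore show the
statistics behave correctly on ensembles with (and without) a planted
order signal — not that real brains satisfy the developmental
hypothesis.

## Problem sizes in the test-suite and acceptance script

The full-scale simulation (N = 1015, 418 steps, 10 runs) is exercised
directly: it is the package's headline computation and completes in
about a minute and a half. The C-recovery check uses 6 runs per
calibration iteration from a deliberately misestimated starting value
(4e-7). All other checks run at toy or synthetic scale (N ≤ 200) chosen
so each oracle comparison is exhaustive or statistically well-powered.

## Known limitations

* Consensus construction is binary (edge presence only); any weight
  thresholding upstream of presence is out of scope.
* The discordance null is exactly 1/2 only for tie-free orders; see
  above.
* At late steps the realized edge count falls a few percent below
  $\lfloor A\rfloor e^{Bk}$ because only absent pairs can be added while
  the analytic expectation counts all pairs; at the default scale the
  gap stays under 10% through step 418 (under 16% for the C-adjusted
  18-edge start).
* `calibrate_C` assumes the isolated total responds monotonically and
  near-linearly to C; with very small targets (a handful of isolated
  edges) ratio noise dominates and more runs per iteration are needed.
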