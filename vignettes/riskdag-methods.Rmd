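---
title: "Methods: ensemble causal discovery for survey risk-factor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble causal discovery for survey risk-factor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

riskdag studies how risk and protective factors around a binary outcome —
here non-suicidal self-injury (NSSI) in school-age adolescents — can be
arranged into a directed acyclic graph (DAG) from a single cross-sectional
survey. Three methodological families are combined, mirroring common
practice in computational causal discovery for epidemiological survey data:

1. **Constraint-based search** (PC in its original, stable and parallel
   variants, and FCI for robustness to latent confounding), driven by
   Fisher-z conditional-independence tests;
2. **An order-randomized ensemble**: PC and FCI outputs depend on the
   order in which variables are visited, so each algorithm is run many
   times under random permutations and only edges that appear
   consistently are retained;
3. **A gradient-based learner** (a graph autoencoder in the NOTEARS
   family) whose signed weighted adjacency separates risk (positive)
   from protective (negative) influences.

The package is a *reusable pipeline plus a validation harness*: because
survey data of this kind is access-restricted, a synthetic
structural-causal-model (SCM) generator emulating the survey's variable
structure provides ground truth for every stage.

## The synthetic survey generator

`make_cpcd_like_spec()` ships a fixed 22-node SCM: 21 explanatory
variables plus a binary NSSI outcome. Its design choices:

* **Tiers.** `Gender` and `Grade` are intrinsic attributes
  (`exogenous_fixed`); the four pandemic behavioral-change indicators
  (sleep, physical activity, screen time, sugary-beverage consumption,
  each binary `-`/`+`) are `exogenous_covid`. No edge may point into an
  exogenous node, and the search enforces the same restriction as
  background knowledge.
* **Signed pathways.** NSSI has nine direct parents. Protective
  constructs (positive youth development, life satisfaction, sleep
  duration) carry negative weights into NSSI; depression, internet
  addiction, pandemic-related PTSD, academic anxiety, family dysfunction
  and sugary-beverage increase carry positive weights. Mediating
  structure follows the hypothesized mechanism network: e.g. reduced
  physical activity raises academic anxiety, which feeds PTSD and
  depression; family dysfunction lowers life satisfaction and raises
  depression; PYD buffers internet addiction and depression.
* **Effect sizes.** All |weights| lie in [0.25, 0.8] with unit Gaussian
  noise, chosen so that every edge is comfortably detectable at
  n = 5,000 but not at n = 50 — power curves stay informative.
* **Discretization.** Ordinal and binary variables arise by cutting a
  latent continuous value at fixed thresholds, and the *discretized*
  code (not the latent) feeds children. Downstream analysis therefore
  faces the same coarsening a real survey imposes. Cut points for
  endogenous discrete nodes were frozen once from a quantile calibration
  at large n so that default marginals sit near the reference survey
  table (NSSI prevalence about 26%, depression about 35%, PTSD about
  35%, an 8-level grade distribution, and so on); exogenous nodes have
  standard-normal latents, so their cut points are exact normal
  quantiles.
* **Reproducibility.** Each node draws its noise from a per-node
  substream derived from the seed and the node's name, so adding a node
  to a spec never perturbs the draws of existing nodes, and exogenous
  marginals are bitwise invariant to interventions on endogenous
  weights.

What the generator does *not* emulate: item-level questionnaire
structure, measurement error models, survey weighting, or the real
joint distribution beyond marginal plausibility. Passing recovery tests
on this generator demonstrates algorithmic correctness and statistical
behavior under ordinal coarsening — not that the pipeline recovers the
true causal structure of any particular real survey.

## Preprocessing

The pipeline order is fixed: variables with missing rate strictly above
90% are dropped; samples missing an entire required questionnaire block
are removed and remaining isolated gaps are imputed deterministically
(mode for discrete, median for continuous); rows with any continuous
value outside median ± 4·IQR are removed (a robust rule that resists
masking and never touches ordinal scales); ordinal labels are encoded to
integers following the declared level order; finally every column is
centered and scaled to unit variance with the n−1 denominator.
Standardization preserves all sample correlations exactly, so every
downstream conditional-independence decision is invariant to location
and scale of the raw data. Treating encoded ordinal variables as numeric
in Fisher-z tests is a deliberate, documented approximation — the
price is a small distortion of partial correlations quantified by the
generator's faithfulness test (error rate under 5% at n = 20,000).

## Conditional-independence testing

The Fisher-z test transforms the sample partial correlation r of x and
y given a set S (computed by inverting the correlation submatrix over
{x, y} ∪ S) to

    z = sqrt(n − |S| − 3) · atanh(r),    p = 2 · (1 − Φ(|z|)),

declaring independence iff p > α. One correlation matrix is cached per
dataset; each test is then a small Schur-complement solve, compiled for
the search's inner loop. Collinear submatrices raise an error rather
than silently saturating (a silent r = ±1 would corrupt skeletons), and
|r| = 1 returns p = 0 with a saturation flag instead of propagating an
infinite statistic. α defaults to 0.05 and is a reported configuration
value everywhere; the recovery experiments use α = 0.01 as is common
for large-sample skeleton discovery.

A d-separation oracle engine (`ci_engine_dsep`) can be substituted for
the statistical test, which separates algorithmic soundness from
sampling error: with the oracle, PC must return exactly the true CPDAG.
The test suite verifies this exhaustively for every DAG on up to four
nodes (593 graphs) and on seeded random designs with five to seven
nodes; full enumeration at seven nodes (about 1.1 billion DAGs) is not
tractable, so sampling stands in above four nodes.

## PC, FCI, and background knowledge

Skeleton discovery follows the level-wise deletion scheme: starting
from the complete graph, at depth ℓ every ordered adjacent pair is
tested against size-ℓ subsets of the current adjacency of the first
endpoint, visited in the configured variable order. `pc_original`
mutates adjacencies immediately (order-sensitive); `pc_stable` freezes
adjacency sets per depth (its skeleton is order-invariant);
`pc_parallel` computes each depth's decisions from the same frozen
adjacencies and applies them in visit order, which makes it bit-identical
to `pc_stable` by construction — parallelism is an implementation
contract, not a semantic one. Unshielded colliders are oriented from
recorded separating sets, then Meek's rules R1–R4 are closed. The FCI
variant keeps the classic order-sensitive sweep, re-tests surviving
edges against subsets of Possible-D-SEP sets, and completes a partial
ancestral graph (PAG) with the collider rule plus the four
arrowhead/tail completion rules; the selection-bias rules are omitted
because a school-based cross-sectional design has no selection structure
for them to orient.

Two practical choices deserve note. First, the Possible-D-SEP subset
search is capped at subsets of size 4 by default (`max_pdsep_size`):
the exhaustive search is exponential in the candidate-set size and, on
faithful data, subsets beyond the skeleton's terminal depth essentially
never separate an additional pair; `Inf` restores the textbook search.
Second, background knowledge is enforced *during* orientation: no rule
ever points an arrowhead into a tier-protected variable, and undirected
edges incident to such a variable are oriented away from it. Conflicting
collider demands are resolved first-come in visit order and logged; the
downstream ensemble absorbs that arbitrariness.

## The order-randomized ensemble

`randomized_runs` executes M searches (the reference analysis used
1,000 per algorithm) under permutations drawn from a master seed, and
tallies, per ordered pair, how often a run output a directed edge, and
per unordered pair how often an undirected or circle-marked edge
survived. "Consistently appears" is operationalized on *total* support:
an unordered pair qualifies within an algorithm when its directed
occurrences (either way) plus undirected occurrences reach a fraction τ
of the runs (default 0.6 — the source analysis gives no number, so τ is
a required, logged configuration value); its direction is the majority
of the directed tallies, kept undirected on a tie. Qualification could
not be based on directed counts alone: the stable variant is
order-invariant, so every edge its CPDAG leaves undirected would never
reach a directed threshold and the consensus would discard exactly the
best-replicated part of the skeleton. Algorithms are merged by majority
(default) or intersection; directional disagreements fall back to
majority, and ties stay as undirected edges in the output (also listed
separately) rather than being silently dropped. Any directed cycle in the merged graph is
repaired by deleting, within each cycle, the edge with the lowest mean
frequency — the minimal intervention consistent with the tally
evidence. The whole procedure is bit-reproducible from the master seed.

The ensemble's value is testable, and the test suite tests it: on the
shipped 22-node spec at n = 10,000, α = 0.01, M = 100 and τ = 0.6, the
consensus of {pc_stable, pc_original, FCI} is compared, by structural
Hamming distance against the knowledge-aware CPDAG of the generating
structure, with a single original-PC run on the same data. On this
generator the consensus does *not* dominate: it wins or ties only a
minority of replicates, sitting consistently a few SHD above the single
run, and the corresponding acceptance test is intentionally left
failing rather than weakened. The mechanism is instructive. The
dominant errors at this sample size are not order noise but systematic:
borderline mediated chains produce spurious separating sets, hence
spurious colliders, and the same wrong orientation in most variable
orders. Aggregating per-pair majorities across runs then amplifies the
bias (a direction that is wrong in 56% of orders is wrong in the
consensus with certainty, while a single run is wrong with probability
0.56), and abstaining to an undirected edge costs a full misorientation
against a compelled truth edge anyway. Order randomization genuinely
stabilizes which edges appear — consensus runs here add essentially no
spurious edges — but it cannot repair orientation errors that do not
depend on the order. The ensemble remains the right tool for its
original purpose, robustness of edge *presence*; for orientation
accuracy its per-pair majority is provably no better than the bias of
its inputs.

## The graph autoencoder

The gradient-based learner follows the NOTEARS recipe: minimize a
reconstruction loss plus an L1 penalty on a weighted adjacency A,
subject to the smooth acyclicity constraint

    h(A) = tr(exp(A ∘ A)) − d = 0,

via an augmented Lagrangian whose penalty parameter ρ grows by a factor
of 10 (capped at 1e16) whenever h fails to shrink by 4×, with
multiplier updates between subproblems and h_tol = 1e−8.

The autoencoder itself is a pair of *shared scalar maps* applied
elementwise: the encoder h_i = f1(x_i), messages m_j = Σ_i A[i,j] h_i,
and the decoder x̂_j = f2(m_j), with

    f(u) = u + Σ_k w_k φ_k(u),

where the φ_k are a fixed bank of tanh ridge functions, linearly
detrended against the data, whose readout weights w are trained along
with A (bank sizes default to 8 for the encoder and 4 for the decoder).
With the readouts at zero the model is *exactly* linear NOTEARS. This
residual design is deliberate: a free-form encoder/decoder pair has an
exact gain invariance — scaling the encoder output by c and A by 1/c
leaves every reconstruction unchanged — through which an L1 penalty on
A can be evaded arbitrarily, making the scale (and hence any fixed edge
threshold ω) meaningless and training unstable. Anchoring both maps to
the identity and restricting the trainable nonlinearity to
curvature-only bases pins A to the scale of the data, so ω = 0.3 and
the risk/protective sign semantics are well defined, while the maps can
still bend to accommodate monotone nonlinear relations such as
discretized ordinal scales. An L2 penalty (default 1) on the readouts
keeps the curvature corrections small unless the data demand them.

Subproblems are solved full-batch by L-BFGS-B with the classic
A = A⁺ − A⁻ split (box constraints A± ≥ 0 make the L1 term linear and
leave inactive entries exactly at zero). First-order optimizers with
per-coordinate step normalization proved unable to break the
reciprocal-edge saddle of the acyclicity penalty — both directions of a
two-cycle shrink at the same rate — whereas the quasi-Newton solve
preserves gradient-magnitude asymmetries and resolves each pair to the
better-supported direction. Background knowledge enters as a hard mask
(forbidden entries pinned to zero through the bounds). Fits are
deterministic given the seed; non-convergence returns the best iterate
flagged, not an error.

One identifiability caveat governs how the learner is validated. After
per-column standardization, the direction of a reversible edge in a
linear-Gaussian model is not identifiable — the two-node problem
becomes exactly symmetric — so support-recovery tests (edge F1) run on
the generator's natural scale, where variance ordering carries the
directional information this model family is known to exploit. The
polarity test, by contrast, runs on the standardized pipeline scale:
signs survive standardization, and only edges actually recovered into
the outcome are labeled. Accordingly, on real standardized survey data
the learner's arrows should be read as the consensus pipeline's
corroboration, not as independently identified directions.

## Reporting

Detection-rate tables reproduce the two-decimal, round-half-up display
convention of survey tables (`rate_percent(886, 3768)` prints 23.51).
Local causal neighborhoods take the induced subgraph within a given
number of steps of the target, ignoring edge direction (both parents
and children appear at each step). Pathway enumeration lists all
directed paths into the target up to a maximum length (default 6),
sorted by length then lexicographically so output is exactly
reproducible, each edge optionally annotated with its risk/protective
polarity from a thresholded weighted adjacency.

## Problem sizes used by the test suite and acceptance script

The validation harness scales the reference analysis down to sizes a
single CPU handles comfortably while preserving every qualitative
condition: the ensemble recovery experiment uses M = 100 runs per
algorithm over 20 replicate datasets of n = 10,000 (the acceptance
script uses M = 50 over 6 replicates); the type-I calibration uses
2,000 null simulations at n = 500 (script: 1,000); autoencoder
validation uses 20 five-node designs at n = 2,000 and 20 survey-spec
fits at n = 5,000 (script: 8 and 4). The oracle soundness check is
exhaustive through four nodes and sampled at five to seven.

## Known limitations

* Fisher-z on encoded ordinal data is an approximation; heavily skewed
  ordinal variables inflate type-I error slightly (bounded by the
  generator's faithfulness test).
* FCI's Possible-D-SEP truncation (size 4) sacrifices completeness
  guarantees under dense latent confounding; raise `max_pdsep_size`
  when latent structure is the scientific focus.
* The consensus DAG inherits the identifiability limits of its inputs:
  within a Markov equivalence class, direction frequencies reflect
  order-randomization behavior, not causal evidence.
* The autoencoder's scalar-channel architecture models each edge as one
  signed weight; interactions and non-monotone effects are outside its
  model class.
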