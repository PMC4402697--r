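---
title: "Conditioning pairwise IBD probabilities on the IBD graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditioning pairwise IBD probabilities on the IBD graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigsr)
```

## The problem and the model

Identity-by-descent (IBD) at a genomic locus is an equivalence-like
relation over haplotypes: sharing descends from common ancestors, so if
haplotypes a–b share and b–c share at the locus, a–c must share as
well. The true IBD graph at any locus is therefore a disjoint union of
cliques — equivalently, a set partition of the haplotypes. Pairwise
callers score each pair in isolation and routinely miss edges that the
clique structure makes near-certain, especially for short segments
where per-pair evidence is thin.

`pigsr` treats the calibrated pairwise scores as a *probabilistic IBD
graph* `G_P = (N, P)`: every unordered pair carries a probability
`p_ij`. A proposed configuration `g` (binary edge assignment) has
probability

$$P(g \mid G_P) = \prod_{i<j} p_{ij}^{e_{ij}} (1-p_{ij})^{1-e_{ij}},$$

a product over all pairs, accumulated in log space because components
can involve hundreds of factors. Conditioning every edge on the whole
graph, restricted to the biologically possible (transitive)
configurations $V$, gives the updated edge probability

$$\dot p_{ij} = \frac{\sum_{g \in V,\, e_{ij} \in g} P(g \mid G_P)}
                     {\sum_{g \in V} P(g \mid G_P)}.$$

With two strong edges and one weak one the effect is exactly what
intuition demands:

```{r worked}
G <- ibd_graph_from_probs(c("1", "2", "3"), c(0.9, 0.9, 0.1))
round(exact_conditionals(G), 4)
```

## Exact computation

Transitive configurations on `n` labelled nodes are in bijection with
set partitions, so `exact_conditionals()` enumerates restricted-growth
strings rather than filtering all $2^{n(n-1)/2}$ graphs: B(8) = 4140
partitions versus $2^{28}$ graphs. The default refusal cap is 12 nodes
(B(12) ≈ 4.2 million, processed in chunks so memory stays flat);
beyond that the sampler takes over. Ratios are formed by log-sum-exp
accumulation; tests compare at $10^{-9}$ absolute tolerance, and the
enumeration is cross-checked in the test suite against an independent
brute-force filter of all graphs for small n.

Exact conditioning requires all `p_ij` strictly inside (0, 1); the
calibration layer guarantees this by clamping (below). Probabilities of
exactly 0 or 1 are reserved for the sampler's pinning rule.

## The sampling approximation

For components beyond the enumeration cap, `run_sampler()` explores
transitive configurations with single-edge moves:

1. **Initialisation.** Every edge with `p_ij` at or above the
   fixed-edge threshold (default 0.99) is pinned present and treated as
   probability exactly 1; the configuration is clique-closed. Pinned
   edges are never proposed and report probability 1.
2. **Proposal.** One non-pinned edge is selected with probability
   proportional to `edge_weight()` — the normal CDF (μ = 0.5,
   σ = 0.234) of `p_ij` mirrored about 0.5 — so uncertain edges are
   proposed often and near-certain ones rarely. The edge is set present
   with probability `p_ij`, absent otherwise.
3. **Repair.** Adding an edge merges two cliques (clique closure).
   Removing an edge splits its clique in two: pinned edges survive as
   welded blocks, each block or leftover node joins the side (anchored
   at the removed edge's endpoints) to which its mean edge probability
   is higher, visiting leftover nodes in random order; exact ties are
   settled by a fair coin. If the two endpoints are themselves welded
   together by pinned edges the split is impossible and the component
   is restored whole.
4. **Accumulation.** The configuration's probability is added to a
   running total `N_g` and to `N_ij` for every present edge; the
   estimate is `N_ij / N_g`.

By default each *distinct* configuration's mass is accumulated once, on
first visit (`sampler_config(accumulate = "distinct")`). The estimate
is then exactly the conditional ratio restricted to the visited set,
and converges to the enumeration value as coverage grows. The
alternative `accumulate = "all"` re-accumulates on every visit; we keep
it for completeness but do not recommend it: repeated visits weight
each configuration by its visit frequency *times* its probability, and
the estimate converges to a biased limit (on the worked example above
it stabilises near 0.48 instead of 0.324, since the chain prefers
high-probability configurations and the accumulator then counts them
twice over).

Runs stop when every estimate changes by less than `convergence_tol`
(default 1e-11) for `convergence_window` (default 5000) consecutive
iterations, or at `max_seconds` (default 120 s per component, matching
a production setting of about two minutes per region), or at
`max_iterations`. Identical seeds give bit-identical trajectories.

### Convergence behaviour and a known limitation

`convergence_experiment()` implements the validation protocol used by
the acceptance script: a random graph with Uniform(0, 0.99) edge
probabilities, 25 seeded sampler runs, and the run-averaged mean
relative percent difference between estimate and enumeration,

$$\bar\delta = \frac{100}{|E|}\sum_{i<j}
  \frac{|\dot p_{ij} - \hat p_{ij}|}{\dot p_{ij}},$$

evaluated at fixed iteration checkpoints (pinned edges excluded). On
3–5-node graphs the sampler typically covers all of configuration
space within a few thousand iterations and $\bar\delta$ falls to
(near) zero. On 6–8-node graphs it does not: the removal repair's
side-assignment is deterministic given the probability matrix (the
fair-coin branch fires only on exact float ties), so the move set can
reach only a subset of all partitions. The estimator then converges to
the conditional ratio over the *reachable* set, and $\bar\delta$
plateaus — typically at a few percent, dominated by edges whose exact
conditionals are tiny (~0.005), whose mass lives in rarely-visited
configurations. Running far past the checkpoints does not remove this
plateau. Users who need small-conditional edges to high relative
accuracy should stay within the enumeration cap; for the pipeline's
decision problem (is an uncalled edge above 0.99?) the sampler's
accuracy is ample, because such edges are dominated by pinned
sub-cliques that the chain handles exactly.

## LOD calibration

Refined IBD-style callers emit a LOD score: the base-10 log likelihood
ratio of one shared haplotype versus none. With prior probability
ε = 0.0046 (genome-wide average IBD sharing of a random pair; also the
probability assigned to uncalled pairs so every configuration stays
sampleable), Bayes' rule in odds form gives posterior odds
`o = ε/(1-ε) · 10^lod`. The default `fitted_curve` mode uses the
empirical conversion `p = (2o + af)/(o + f)` with
`f = ε·10³/0.997 − ε·10³` and a cubic shape term
`a = (1−lod)³/7` for lod ≤ 1, −0.15 above — a curve fitted to observed
true-positive rates against an expanding (European-like) population
simulation. Its raw value exceeds 1 from moderate LOD on, so outputs
are clamped to `[p_min, p_max]` (defaults ε and 0.999); the upper clamp
keeps configuration probabilities finite in log space while staying
above the sampler's 0.99 pinning threshold, so well-supported calls are
pinned exactly as intended. Two alternatives exist because the fitted
constants need not transfer across demographies: `plain_odds`
(`o/(1+o)`; equals ε at lod 0) and `empirical`
(`fit_empirical_calibration()`: quantile-binned true-positive
fractions made monotone by isotonic regression). The grouping of the
printed `f` expression is taken literally; monotonicity of the fitted
curve is verified on a LOD grid in the tests rather than proven.

## From segments to regions and back

Input is the tab-delimited Beagle/Refined IBD `.ibd` dialect (1-based
inclusive coordinates; converted internally to half-open intervals and
back on output). Default input filters are LOD ≥ 0.1 and length ≥ 0.1
cM; without a genetic map, lengths assume a uniform 1 cM/Mb (the
conventional equivalent of a 1e-8 per-bp recombination rate). The
graph only changes where segments start or end, so those breakpoints
delimit the analysis regions; within a region, haplotypes incident to a
covering segment form the graph, called pairs get calibrated
probabilities (several covering calls keep the strongest), uncalled
pairs inside a connected component get ε, and disjoint components are
conditioned independently (they cannot influence each other's ratios).
Two-node components skip sampling: both configurations are transitive
and the ratio reduces to the input probability.

After conditioning, each original call takes the maximum estimate
across the regions it spans; uncalled pairs passing the threshold
(default 0.99) are emitted as *inferred* segments over the intersection
of their component's member-segment intervals — without inspecting
sequence, sharing can only be asserted where every supporting segment
exists. Same-pair pieces above the threshold that overlap or abut are
merged (union interval, maximum probability), and the report is
filtered at 0.5 cM by default. Components larger than 200 nodes are
processed but flagged; the per-component time limit is the real guard.

## Synthetic data and what passing tests show

`simulate_ibd_truth()` emulates the *downstream statistical structure*
a sequence-level simulation plus pairwise calling would hand to the
graph conditioning: clique events placed by a Poisson process along a
30 Mb chromosome, sizes 2–8 with halving frequency, exponential lengths
(mean 0.8 cM, floor 0.1 cM), members drawn only from haplotypes free
over the interval so the truth is exactly transitive at every locus.
`emit_noisy_calls()` degrades truth into calls: logistic detection in
length (~0.2 at 0.1 cM, ~0.9 at 0.5 cM), jittered endpoints, LOD
increasing with length for true calls, sparse short low-LOD false
calls. Defaults were chosen once as plausible desk-scale settings and
are config-exposed.

This generator deliberately does *not* model linkage disequilibrium,
demography, phasing switch errors or genotyping error, and its truth is
perfectly transitive where real truth need not be. Passing the
end-to-end tests therefore shows that the machinery recovers
clique-implied edges and controls false inference under the stated
noise model — not that comparable gains follow on any particular real
cohort.

The flagship end-to-end property: fully detected cliques of size ≥ 4
with one call masked. The masked edge's mates are pinned after
calibration, initialisation clique-closes over them, and the pipeline
re-emits the masked pair as an inferred segment at probability ~1 in
the majority of cliques, while unrelated pairs bridged into a component
by a weak call stay near ε and are never emitted.

## Numerical and design choices

* Edge keys are canonical ordered pairs under C-collation sorting;
  probabilities are stored once per unordered pair in symmetric
  matrices. Node label sorting is locale-independent (radix).
* All mass accumulation is in log space (`logaddexp`); exact ratios use
  log-sum-exp.
* Problem sizes in the validation protocol: 25 runs, checkpoints at
  5000 and 7500 iterations, graphs of 3–8 nodes (enumeration-feasible),
  matching the experiment the acceptance script reproduces.
* Ties in the removal repair use exact float equality and a seeded fair
  coin; leftover-node visitation is a seeded shuffle. These choices
  keep runs reproducible while matching the randomised description.
* The 2-node identity, the ε fill, and the 0.99 pin/merge thresholds
  are all configurable; defaults follow the production settings quoted
  above.

## Limitations

* The sampler's reachability plateau (above) bounds relative accuracy
  on edges with tiny conditionals; exact enumeration is the remedy up
  to 12 nodes.
* Inferred segments inherit their boundaries from existing calls, so
  their endpoints are approximate; length-distribution analyses should
  prefer the original boundaries.
* The default calibration is demography-specific; recalibrate
  empirically when the study population differs.
* Truth transitivity is enforced by construction in the generator;
  real call sets routinely violate it, which is precisely why the
  conditioning step exists.
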