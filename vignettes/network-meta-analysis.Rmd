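---
title: "Methods: a signed network meta-analysis of resting-state connectivity in JME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a signed network meta-analysis of resting-state connectivity in JME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmenet)
```

## The problem

Resting-state imaging studies of juvenile myoclonic epilepsy (JME) report
scattered, pairwise findings: connectivity between two brain regions is
increased or decreased in patients relative to healthy controls, measured
with heterogeneous indicators (FC, SC, gFCD, lFCD, EC, ReHo) on
heterogeneous equipment (MRI, MEG, EEG and combinations). No single study
sees the whole brain's altered network. `jmenet` treats the literature
itself as the measurement: each study conclusion becomes one signed edge
observation over a controlled 21-region vocabulary, and the corpus becomes
an undirected, signed whole-brain graph whose structure can be analysed
with standard graph theory.

The pipeline answers three questions in sequence:

1. **Which regions matter?** Degree centrality
   $C_D(N_i) = \sum_{j \ne i} x_{ij}$ counts a region's direct functional
   connections; betweenness centrality
   $C_B(N_i) = \sum_{j \ne k \ne i} \sigma_{jk}(i)/\sigma_{jk}$ measures
   how often a region sits on shortest paths between other regions, i.e.
   how strongly an abnormal discharge originating there could propagate
   through the network.
2. **Which sub-networks are dynamically plausible?** A stochastic
   node-reduction procedure prunes regions that cannot affect the rest of
   the network and enumerates the distinct surviving configurations over
   many seeded runs.
3. **Are the reported signs mutually coherent?** Restricting the
   high-degree core to anatomically plausible white-matter tracts, signs
   are propagated transitively (a positive A–B change combined with a
   negative B–C change implies a negative A–C change) and each observed
   change is scored as satisfied or violated.

## From records to a signed graph

A record carries a study id, modality, indicator, an unordered region
pair, and either a qualitative direction (±1) or a raw correlation
coefficient. Raw correlations are mapped through the Fisher
transformation $z = \tfrac12 \log\!\big(\tfrac{1+r}{1-r}\big)$ and
classified by the sign of $z$. The transform is undefined at $|r| = 1$
and $z = 0$ is deliberately unclassifiable: the two-category conversion
has no tie rule, so an exact zero is an error rather than a silent
choice. An optional threshold `tau` treats $0 < |z| < \tau$ as
sub-threshold for sensitivity analyses; the default `tau = 0` reproduces
the plain sign rule.

Region labels pass through merge conventions (parietal lobule variants
into the parietal lobe; pre/postcentral gyri, posterior cingulate gyrus
and the SMA anterior cluster into the primary motor sensory cortex;
thalamic subregions into the thalamus; globus pallidus, putamen and
caudate into the basal ganglia). Records whose endpoints merge into the
same region are dropped with a logged count. Hemisphere is not modelled:
left/right reports of one region collapse to a single label before
ingest.

Pairs reported with both signs across studies are *conflicts*. The
default policy excludes every record of a conflicted pair — the
conservative choice — with a `"majority"` option that keeps the dominant
sign. Indicators that are not connectivity strengths (`network_metric`,
`unknown`) are bookkept but excluded from edge construction unless
explicitly included.

```{r example-build}
sim <- generate_records(synthetic_spec(seed = 1))
net <- build_network(sign_records(sim$records))
net
head(centrality_profile(net))
```

## Node reduction and configuration enumeration

A *termination node* is a node with betweenness exactly zero: it lies on
no shortest path between any other pair and therefore cannot influence
the rest of the network's topology. `reduce_method1()` iterates:

1. partition the current surviving subgraph into communities with seeded
   asynchronous label propagation (the only stochastic component);
2. compute betweenness within each community's induced subgraph, and
   globally on the surviving subgraph;
3. remove the termination nodes and repeat.

Iteration stops when a pass removes nothing (`"stable"` convergence:
every survivor then has positive betweenness in the reduced network), or
when the termination set covers the entire surviving set (`"terminal"`
convergence: a fully terminal attractor such as a complete graph, which
is kept as the final configuration rather than wiped). A pass that would
leave a single node raises a degenerate-configuration error, and
`enumerate_configurations()` counts such runs as excluded.

Two numerical choices deserve emphasis:

* **Seed derivation.** The label-propagation seed of each iteration is a
  31-bit hash of the base seed together with the canonical signature of
  the current surviving subgraph. Reduction is therefore deterministic
  and bit-reproducible given its seed, and idempotent: re-reducing a
  returned configuration with the same base seed re-derives the exact
  partition that declared it stable.
* **Where randomness acts.** Label propagation is the pipeline's only
  named stochastic component (layout cannot change topology), so
  configuration diversity across seeds comes entirely from community
  splits. On dense, diameter-2 networks label propagation almost always
  returns one community, and the reduction is then close to
  deterministic; sparse networks, where communities fragment, show the
  full stochastic behaviour. The number of distinct configurations is
  consequently a property of the corpus density, not a fixed constant.

Each reduced configuration is classified by its normalized betweenness
profile: category 1 when exactly one region exceeds `cb_high = 0.8`,
category 2 when at least two regions fall in `(0.5, 0.8]` and none
exceeds 0.8, category 3 when all regions are below 0.5. Profiles
matching none of these (a single mid-band region, several regions above
0.8, or a value of exactly 0.5) are assigned category 3 with a warning,
with precedence 1 > 2 > 3 — the conservative completion of a
classification that leaves such profiles undefined.

The empirical distribution over observed signatures is tested for
uniformity with a chi-square test at significance level 0.01, using the
observed signatures as categories; a single observed signature is
trivially uniform (p = 1). On vertex-transitive test fixtures the
procedure's symmetric outcomes are recovered uniformly within each
automorphism orbit.

## Core extraction and tract-constrained consistency

The second reduction keeps regions whose degree strictly exceeds
`degree_threshold = 10`. Degree is the count of distinct neighbours by
default; a `"multiplicity"` mode counts supporting records instead,
because a degree filter may equally well have operated on record-level
connections — both readings are exposed rather than guessed.

The tract map is a declarative input (YAML), not tractography: which
fiber connections are admissible is an anatomical claim the package does
not make for you. A 6-region convenience map
(`inst/extdata/tracts-default.yaml`) encodes canonical thalamocortical
and cortico-basal connections and is labelled a fixture, not ground
truth.

Sign propagation along a tract path multiplies edge signs. For a
non-adjacent pair the implied sign is evaluated over *every* shortest
tract path; disagreement between shortest paths — possible only in
structurally unbalanced networks — yields an indeterminate sign, which
counts as a violation. This is the minimal generalization of the
two-edge chain rule to longer paths, and on structurally balanced
networks (every cycle with positive sign product) it never produces an
indeterminate result.

`search_max_consistent()` automates what is otherwise a manual analysis:
it enumerates connected spanning edge-subsets of the tract map, assigns
every sign combination consistent with directly observed edges, scores
each candidate by the fraction of observed changes satisfied, and
returns the maximum (ties break toward fewer edges, then lexicographic
signature). Exhaustive enumeration is limited to cores of at most 8
regions; beyond that a seeded greedy hill-climber with restarts takes
over, and on every test fixture the greedy optimum never exceeds the
exhaustive one.

The consistency report prints two denominators: the satisfied fraction
over evaluated changes, and the fraction over all pre-exclusion changes
(conflicting study conclusions removed before evaluation re-enter the
denominator). Published corpus-level percentages can follow either
convention, so both are always reported.

```{r example-consistency}
spec <- synthetic_spec(seed = 1)
tracts <- generate_tract_map(spec)
signed <- sign_records(sim$records)
core_obs <- signed[signed$region_a %in% sim$truth$core &
                     signed$region_b %in% sim$truth$core, ]
found <- search_max_consistent(tracts, core_obs)
found$report
```

## What the synthetic generator emulates

`generate_records()` produces a corpus shaped like the JME literature:
15 studies over 21 regions, mixed indicators and modalities, per-study
cohorts of 10–60 patients and controls, and a planted 6-region
high-degree core. Its defaults are the package's study conditions:

* Core-involving pairs receive a record with probability
  `p_core_edge = 0.7`; periphery–periphery pairs with
  `p_periphery_edge = 0.05`. The expected core degree,
  $0.7 \times 20 = 14$, comfortably exceeds the degree-10 filter, and
  periphery degrees exceed 10 with probability about $10^{-4}$ per node
  (binomial calculation), so the planted core is identifiable from the
  simple-graph degree alone.
* The planted-core property is a *guarantee*, not just an expectation: in
  the rare draw (probability ≈ 0.05 per core node) where a core node's
  degree lands at or below the threshold, missing core-involving edges
  are added until it exceeds it. Frequency properties are therefore
  stated, and tested, on the pre-top-up Bernoulli draws, which the
  ground-truth bundle records alongside the final edge list.
* Edge signs derive from a structurally balanced assignment — each region
  carries a hidden spin and an edge's sign is the product of its endpoint
  spins — then flip independently at `frustration_rate` (default 0).
  Balance makes frustration-free corpora fully consistent by
  construction, which pins the end-to-end expectation: the maximally
  consistent tract network must satisfy every observed change.
* `conflict_rate` plants opposite-sign duplicate records from a second
  study on a controlled fraction of pairs, exercising conflict detection
  with exact bookkeeping.

What the generator does *not* emulate: publication bias, correlated
reporting between studies, region-size effects, lateralization, and any
time-series level structure. Passing tests on synthetic corpora
therefore demonstrate that the pipeline recovers what it is told is
there, under the density and noise regime above — not that the
literature itself satisfies these assumptions.

## Problem sizes and reproducibility

All stochastic stages take explicit integer seeds, and every derived
seed is a deterministic 31-bit hash, so whole-pipeline runs are
bit-reproducible (`run_pipeline()` twice with one config yields
byte-identical reports up to the timestamp). The shipped test suite
checks betweenness against an independent brute-force enumerator on
every labelled connected graph with up to 6 nodes plus 200 random
10-node graphs; uniformity fixtures use 1000 reduction runs; parameter
recovery uses 100 generator seeds. The acceptance script runs the full
pipeline at 200 whole-brain and 100 core reduction runs — sizes chosen
so the whole analysis replays in about a minute on a laptop while
keeping the binomial recovery guarantees sharp.

## Known limitations

* The mechanism by which repeated runs generate distinct configurations
  is an interpretation (label-propagation randomness feeding a
  termination-node pruning); other readings of the same procedure exist,
  and the package documents rather than hides this choice.
* Betweenness is computed on unweighted graphs; record multiplicity
  affects degree (optionally) but never path lengths.
* The region vocabulary ships 20 codes; published legends for comparable
  networks are ambiguous about a 21st label, so the registry is
  config-extensible instead of guessing.
* Tract maps are inputs. The default 6-region map is a plausibility
  fixture; any serious use should supply an atlas-derived map.
* No meta-analytic weighting: a 15-patient study and a 60-patient study
  contribute one edge observation each. Cohort sizes are bookkept for
  summary, not used as weights.
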