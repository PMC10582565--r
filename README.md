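# jmenet

Network meta-analysis of resting-state functional connectivity changes in
juvenile myoclonic epilepsy (JME).

Resting-state studies of JME each report a handful of pairwise findings —
connectivity between two brain regions increased or decreased in patients
versus healthy controls, measured as FC, SC, gFCD, lFCD, EC or ReHo on
MRI, MEG or EEG. `jmenet` pools such literature-extracted region-pair
records into a signed, undirected whole-brain graph over a controlled
21-region vocabulary and analyses it end to end:

* **Ingest & conversion** — records from CSV/JSON; raw correlations pass
  through the Fisher transform *z* = ½·log((1+r)/(1−r)) and reduce to a
  qualitative sign; anatomical merge conventions (e.g. globus pallidus,
  putamen and caudate into the basal ganglia) collapse raw labels;
  conflicting study conclusions are detected and excluded (or
  majority-resolved).
* **Centrality profiling** — degree C_D(N_i) = Σ_j x_ij (direct
  connections) and normalized betweenness
  C_B(N_i) = Σ_{j<k} σ_jk(i)/σ_jk / [(g−1)(g−2)/2] (fraction of shortest
  paths through a region), plus seeded label-propagation communities and
  spring layouts.
* **Stochastic node reduction** — iteratively removes *termination nodes*
  (betweenness 0: regions that cannot affect the rest of the network),
  with seeded label propagation injecting the randomness; distinct
  surviving configurations are enumerated over many runs, classified by
  their betweenness profile (single region > 0.8; a pair in (0.5, 0.8];
  all below 0.5), and chi-square-tested for uniformity.
* **Core extraction & tract-constrained consistency** — the degree > 10
  core is re-analysed under a declarative white-matter tract map: signs
  propagate transitively along tracts (+ then − implies −), every
  observed change is scored satisfied/violated, and an exhaustive (or
  greedy) search returns the maximally consistent simplified core
  network.
* **Synthetic corpora** — a generator plants a 6-region high-degree core
  and structurally balanced signs with controlled frustration and
  conflict rates, so every stage is testable against known ground truth.

## Worked example

```r
library(jmenet)

sim <- generate_records(synthetic_spec(seed = 1))   # 15 studies, 21 regions
net <- build_network(sign_records(sim$records))
net
#> <brain_network> 21 regions, 80 edges (signed)

prof <- centrality_profile(net)
head(prof[order(-prof$degree), ], 4)
#>  node degree    cb_raw    cb_norm
#>   R15     16 34.311905 0.18058897
#>   R05     14 18.401190 0.09684837
#>   R04     13 17.650000 0.09289474
#>   R08     13 20.676190 0.10882206

core <- core_filter(net, 10)           # degree > 10 core regions
sort(igraph::V(core)$name)
#> [1] "R04" "R05" "R07" "R08" "R09" "R15"
identical(sort(igraph::V(core)$name), sim$truth$core)
#> [1] TRUE

tracts <- generate_tract_map(synthetic_spec(seed = 1))
signed <- sign_records(sim$records)
obs <- signed[signed$region_a %in% sim$truth$core &
              signed$region_b %in% sim$truth$core, ]
search_max_consistent(tracts, obs)$report
#> <consistency_report> 11/11 observed changes satisfied (100.0%)
```

The degree ranking singles out the planted high-degree regions; the
degree-10 filter recovers exactly the planted 6-region core; and because
the generator's default frustration rate is 0, the tract-constrained
search finds a core network satisfying all 11 observed core changes
(fraction 1.0). With `frustration_rate > 0` the report lists each
violated change with its implied versus observed sign, and prints the
satisfied fraction under both denominators (evaluated changes only, and
including pre-excluded conflicts).

One call runs everything and writes a JSON report, centrality CSV and
GraphML networks:

```r
cfg <- pipeline_config(out_dir = "out", seed = 42)
report <- run_pipeline(cfg, records = sim$records, tracts = tracts,
                       registry = sim$registry)
```

A thin command-line wrapper with `simulate`, `ingest`, `build`, `reduce`,
`core`, `consistency` and `run` subcommands lives at
`inst/cli/jmenet.R`.

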