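# disturbnet

Systems-level analysis of a microbial community observed through a
**press disturbance**: abundance-pattern classification of taxa,
ensemble generalized Lotka-Volterra (gLV) interaction-network inference
from the time series, and topological comparison of the pre- and
post-disturbance networks. The motivating setting is an anaerobic
digester whose 16S community was sampled before, during and after a
sustained temperature drop, but the pipeline applies to any
taxon-by-sample relative-abundance time series with a
before/during/after phase design.

## Who it is for

Microbial ecologists and bioprocess researchers who have a
relative-abundance table (family level or any single taxonomic level),
a phase design, and optionally per-taxon annotations (GC%, genome size,
domain, metabolic pathway category), and who want reproducible,
threshold-documented answers to: which members changed, which members
interact, and which members gained or lost topological importance after
the disturbance.

## The methods in brief

**Classification.** Each taxon gets one label per axis:

* abundance: HA (mean share > 1%), LA (0.1–1%), RA (rest);
* presence: Core (present in every sample) vs Ncore;
* stability: a two-sided F test of before- vs after-window variances at
  α = 0.05, direction resolved by the coefficient of variation
  cv = sd/x̄ about the *present-mean* x̄ = Σx / #(x > 0) — BS when the
  before window is the more variable, BV when the after window is, NC
  when the F test finds no difference;
* response: induced if the during-window present-mean strictly exceeds
  both the before and after present-means (convex pattern), repressed in
  the strict concave case, neither otherwise.

**Network inference.** The engine regresses the per-step log-ratio
`log(x[k+1]/x[k])/dt` of each taxon on an intercept and all member
abundances (the discrete gLV model, in which this relation is exactly
linear), with ridge penalty λ = 1e-3. Around the engine sits the
consensus procedure: 1,000 fits on random 90% member subsets, a sign
kept only when more than 90% of the replicates containing the pair agree
(or an exact binomial test against 0.9, by option), then the strongest
10% of reliable pairs by |mean coefficient| become the network.

**Topology.** In-degree and directed unnormalized betweenness per node
(signs ignored), and a per-taxon niche label comparing the two phase
networks by in-degree dominance: `A` (larger before), `B` (larger
after), `star` (equal, positive), `none`.

A fully seeded synthetic generator (gLV dynamics with a disturbance
window, environmental stochasticity, lognormal or multinomial
observation noise, compositional closure) provides ground truth for
every stage; see the methods vignette
(`vignettes/disturbnet-methods.Rmd`) for model details and design
rationale.

## Worked example

```r
library(disturbnet)

# a 15-member synthetic community, 30/3/30 samples around the disturbance
sc  <- glv_scenario(n_before = 30, n_during = 3, n_after = 30, seed = 7)
sim <- simulate_glv(sc)
sim$table
#> abundance_table: 15 taxa x 63 samples (days 1-63)
#> column sums in [1, 1]

cls <- classify_all(sim$table, sim$design)
table(cls$stability_class, cls$response)
#>      induced repressed neither
#>   BS       2         8       0
#>   BV       0         0       0
#>   NC       4         1       0

net_b <- infer_network(sim$table, sim$design, phase = "before", R = 200, seed = 8)
net_a <- infer_network(sim$table, sim$design, phase = "after",  R = 200, seed = 9)
net_b
#> signed_network: 12 nodes, 11 edges (7 positive, 4 negative)

head(compare_networks(net_b, net_a), 8)
#>     taxon in_degree_A in_degree_B niche
#> 1 taxon01           0           1     B
#> 2 taxon02           1           2     B
#> 3 taxon03           0           0  none
#> 4 taxon04           2           2  star
#> 5 taxon06           2           2  star
#> 6 taxon07           1           2     B
#> 7 taxon08           1           1  star
#> 8 taxon10          NA           0     B
```

Reading the output: ten of the fifteen members changed their variance
regime significantly (BS — more variable before the disturbance — with
mostly repressed responses inside the window); the before-phase network
keeps 11 high-consensus strong edges, 10 of which match the sign of the
true generating coefficient; and the niche table shows which members
receive more interactions after recovery (`B`) or held equal in-degree
in both networks (`star`; `NA` = absent from that network).

The one-call pipeline runs the whole chain and writes the
classification TSV, edge CSVs, GraphML exports, summary tables and a
reproducibility manifest:

```r
run_pipeline(default_config(seed = 7, out = "results_run"))
```

A thin command-line wrapper with the same options ships in
`inst/scripts/disturbnet.R` (`Rscript disturbnet.R run --seed 7 --out results`).

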