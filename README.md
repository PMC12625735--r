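# tknet

Transkingdom multi-omics correlation networks and two-compartment
topology comparison, in R.

## The problem

Ileal and colonic microbial communities differ in composition and
density, and it is unclear which gut segment's microbiota better
reflects host metabolic state under diet-induced obesity. `tknet`
addresses the question topologically: it builds an association network
spanning microbial genera and host omic layers (liver transcriptome,
serum/liver metabolome, metabolic phenotypes) across two diet groups,
then measures which compartment's genera sit closer to the host layers
in that network.

## The method

For screened (differential) features, Spearman correlations are
computed separately within the normal-chow (NC) and high-fat-diet (HFD)
groups. An edge between features *a* and *b* is retained when

1. sign(r_NC) = sign(r_HFD) ≠ 0 (sign consistency across conditions),
2. the Fisher-combined p-value, X = −2(ln p_NC + ln p_HFD) ~ χ²₄,
   passes joint Benjamini–Hochberg control at the edge FDR, and
3. sign(r) = sign(lfc_a) · sign(lfc_b) (fold-change coherence;
   violations are summarized as PUC, the proportion of unexpected
   correlations).

The two compartments are then compared by: retention proportion (2×2
χ² test), bipartite edge counts to each host layer, degree power-law
diagnostics, bipartite betweenness centrality
BIBC(v) = Σ_{s∈S₁, t∈S₂} σ_st(v)/σ_st (a Brandes-style accumulation
restricted to compartment→host pairs), and set-to-set average shortest
path with Wilcoxon comparison. Dense gene subnetworks are detected by
seeded Louvain and ranked by internal density 2e/(n(n−1)); their
members can be tested for over-representation against user-supplied
GMT gene sets. A latent-factor synthetic generator with planted
cross-kingdom coupling (`generateDataset`) makes the whole chain
testable without external data.

## Worked example

```r
library(tknet)

sim <- generateDataset(simulationConfig(seed = 1))   # planted asymmetry 0.8 vs 0.3
dr  <- screenLayers(sim$dataset)                     # per-layer HFD-vs-NC screen
net <- buildNetwork(sim$dataset, dr)                 # meta-analytic network
net
#> TranskingdomNetwork: 129 nodes, 1704 edges
#>   nodes by layer: genes=55 metab_liver=14 metab_serum=17 microbes_A=21 microbes_B=19 phenotypes=3
#>   candidates=9705 retained=1704 PUC=0.019

compartmentReport(net)
#> TopologyReport
#>   retention microbes_A 21/21 = 1.00
#>   retention microbes_B 19/35 = 0.54
#>   retention chi-square = 13.440, p = 0.000246
#>   edges microbes_A -> genes        261
#>   edges microbes_B -> genes        75
#>   ...
#>   avg shortest path -> genes: 1.582 vs 2.092 (Wilcoxon p = 3.81e-42)
```

Reading it: of the ileal (`microbes_A`) genera that passed the
differential screen, 100% kept at least one significant, sign-
consistent, coherent edge versus 54% of colonic genera (χ² p ≈ 2×10⁻⁴);
the ileum has ~3.5× as many direct edges to the gene layer; and its
average shortest path to the transcriptome is about half a step shorter
— exactly the planted asymmetry (ileal factor loadings 0.8 vs colonic
0.3). PUC = 0.019 says under 2% of significant edges contradicted the
planted fold-change directions.

The same flow runs from files: `writeDataset()` emits per-layer TSVs,
and `runPipeline(list(data_dir = ..., out_dir = ...))` executes
screen → network → topology → subnetworks → enrichment and writes
GraphML, result TSVs, a topology-report JSON and a run log.

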