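---
title: "Transkingdom networks: models, assumptions, and design choices"
author: "tknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transkingdom networks: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tknet)
```

# The scientific problem

Gut microbial communities differ sharply between intestinal segments:
the ileum is the main site of nutrient absorption and enterohepatic
circulation, while the colon carries a denser, more diverse community.
Which segment's microbiota is more tightly tied to host metabolism is a
live question with practical consequences (most studies sample feces,
a proxy for the colon). One way to address it without interventions is
topological: build an association network that spans microbial and host
"kingdoms" — genera on one side, liver transcripts, serum/liver
metabolites and metabolic phenotypes on the other — and ask which
compartment's genera sit closer to the host layers in that network.

`tknet` implements this comparison end to end: differential feature
screening, meta-analytic correlation network construction over two diet
groups (normal chow, NC, versus high-fat diet, HFD), and a topology
suite that quantifies each compartment's proximity to the host. Because
the deposited data of any particular study are not required, the
package ships a synthetic multi-omics generator with *planted* coupling
so that every downstream claim can be tested against a known truth.

# The statistical pipeline

## Compositional normalization and screening

Microbial counts are compositional; before any Euclidean statistic they
are centered log-ratio transformed per sample:

$$\mathrm{clr}(x_i) = \ln(x_i + c) - \frac{1}{p}\sum_j \ln(x_j + c),$$

with pseudocount $c = 0.5$ by default (a conventional half-count;
configurable). Every CLR column sums to zero by construction, which the
test suite fuzzes.

Two screens are exposed:

* **Diet response per feature** (`twoGroupDifferential`): Mann–Whitney
  U by default (omics scales are heavy-tailed; Welch's t is available),
  BH-adjusted within each layer. This screen decides which features
  enter the network. Fold-change *signs* (HFD vs NC) feed the coherence
  filter below.
* **Differential response between segments** (`twoWayAnova`): per
  feature, `value ~ diet * segment` with type-II sums of squares
  (tolerant of mild unbalance; identical to type I/III on the balanced
  design), the interaction term BH-adjusted across features. This is
  the screen for taxa whose diet response differs between ileum and
  colon; it requires the two compartments to share a genus namespace.

Presence-based compartment-specific genera use a declared rule: present
in at least 50% of one compartment's samples and absent from the
other's. Shannon diversity $H = -\sum p_i \ln p_i$ is computed per
sample via `vegan`.

## Meta-analytic network construction

For every unordered pair of screened features, Spearman correlation and
its t-approximation p-value are computed *separately within each diet
group*. A candidate edge survives only if

1. **sign consistency**: $\mathrm{sign}(r_{NC}) = \mathrm{sign}(r_{HFD}) \neq 0$;
2. **significance**: the Fisher-combined p-value
   $X = -2(\ln p_{NC} + \ln p_{HFD}) \sim \chi^2_4$ is BH-adjusted
   jointly across all candidate edges and must fall below the edge FDR
   (default 0.05);
3. **coherence** (optional, default on): the correlation sign equals
   the product of the two endpoints' fold-change signs.

The fraction of significant, sign-consistent edges that *violate*
coherence is reported as PUC (proportion of unexpected correlations), a
diagnostic for causal interpretability, whether or not coherence is
enforced. Whether incoherent edges should be removed or merely counted
is genuinely open; both behaviors are exposed via `requireCoherence`,
with removal as the default because the planted-truth generator makes
coherent signs the ground truth.

By default one network is built containing both compartments' microbes
and all host layers, but **ileum-microbe × colon-microbe pairs are
excluded** from the candidate set: the comparison of interest is each
compartment against the host, and cross-compartment microbial edges
would let one compartment "borrow" the other's host proximity. Host ×
host edges (gene–gene, metabolite–gene, …) are retained — shortest
paths and gene modules need them. A flag restores the fully integrated
behavior.

Numerical notes: Spearman uses average ranks on ties (consequential
under microbial zero-inflation); correlation p-values of exactly zero
(|r| = 1) are clamped to the smallest positive double before the log;
groups with fewer than 4 samples are rejected; features constant within
a group have their pairs skipped and counted.

## Topology comparison suite

* **Retention** — the fraction of a compartment's screened features
  that survive with ≥ 1 edge; compared by a 2×2 chi-square without
  Yates correction (counts are not small; a flag enables it).
* **Bipartite edge counts** — edges with one endpoint in the
  compartment and one in a host layer.
* **Degree / power law** — descriptive only: the continuous-
  approximation discrete MLE
  $\hat\alpha = 1 + n \big/ \sum_i \ln\!\frac{k_i}{k_{\min}-1/2}$ plus
  a log–log OLS $R^2$ of the degree histogram. This estimator is known
  to be accurate only for $k_{\min} \gtrsim 6$; at $k_{\min}=1$ it is
  biased toward $\approx 2$ regardless of the true exponent (on exact
  zeta-distributed degrees with $\alpha = 2.5$ it converges to
  $\approx 2.02$). The package's parameter-recovery test therefore
  simulates and estimates at $k_{\min} = 10$, where recovery is
  accurate; the default $k_{\min}=1$ remains for descriptive use on
  real degree sequences. No bootstrap goodness of fit is attempted —
  the scale-free claim this diagnostic supports is qualitative.
* **BIBC** (bipartite betweenness centrality) — for node $v$ and node
  sets $S_1, S_2$:
  $$\mathrm{BIBC}(v) = \sum_{s \in S_1}\sum_{t \in S_2}
    \frac{\sigma_{st}(v)}{\sigma_{st}},$$
  with $\sigma_{st}$ the number of shortest $s$–$t$ paths and
  $\sigma_{st}(v)$ those through $v$ as an *interior* node (endpoints
  never score for their own pair; unreachable pairs contribute 0).
  Implemented as a Brandes-style dependency accumulation with sources
  restricted to $S_1$ and endpoint credit restricted to $S_2$; the test
  suite verifies it against exhaustive shortest-path enumeration on
  random graphs and asserts the exact identity
  $\sum_v \mathrm{BIBC}(v) = \sum_{\text{reachable }(s,t)} (d(s,t)-1)$.
  Hubs are the top 20% of scored microbial nodes, with ties broken by
  stable feature-id order and set size $\lceil 0.2\,n \rceil$ — the
  ceiling and the tie rule are declared choices.
* **Set-to-set closeness** — BFS shortest-path lengths over all
  $(s, t)$ pairs between two sets; unreachable pairs are *excluded and
  counted* rather than given infinite length (which would poison the
  mean). Distributions from the two compartments are compared by a
  two-sided Wilcoxon rank-sum test: exact enumeration when both sides
  have ≤ 8 values and no ties, tie-corrected normal approximation
  otherwise. Paths run over the *full* network — a microbe may reach
  the transcriptome through a metabolite, matching the information-flow
  reading of the network; a per-layer subgraph analysis can be had by
  building the network on fewer layers.
* **Dense subnetworks** — Louvain modularity optimization on the
  layer-induced subgraph (fixed seed: Louvain is order-sensitive),
  communities under 10 members discarded, the rest ranked by internal
  density $2e/(n(n-1))$ and the top $k$ returned. Louvain-by-density is
  a declared substitute for whatever module detector a given study may
  have used; the algorithm sits behind one interface and is swappable.
* **Over-representation** — hypergeometric upper tail against
  caller-supplied gene sets (GMT format). The universe defaults to the
  genes that entered network construction — the statistically
  defensible background — not the genome. No ontology access is
  attempted.

# The synthetic generator and its planted truth

`generateDataset()` draws, per sample, latent factors
$z \sim N(0, 1)$ and sets every feature's latent value to

$$\text{baseline} + \delta \cdot 1[\text{HFD}] + \lambda z_{f} + \varepsilon,$$

with each feature tied to exactly one factor $f$ (round-robin within
layer) and $\varepsilon \sim N(0, \sigma_{\text{noise}})$. Microbial
latents are softmax-normalized per sample and counts drawn multinomially
at a fixed sequencing depth; genes and metabolites are exponentiated
(log-normal); phenotypes stay linear. A single RNG stream is seeded
once and consumed in a fixed order, so a configuration is
bit-reproducible.

The asymmetry between compartments is planted through the loading
magnitudes: ileal microbes load at $|\lambda| = 0.8$, colonic microbes
at $0.3$, host features at $0.8$. *Coupled pairs* are same-factor
(microbe, host) pairs; their expected correlation sign is the product
of their loading signs. Diet-effect signs are
$\mathrm{sign}(\lambda_i) \times d_f$ for a per-factor diet direction
$d_f$, which makes every coupled pair's fold-change sign product equal
its correlation sign — the planted network is coherent by construction
and PUC on generator output is near zero. Setting the two loadings
equal makes the compartments statistically exchangeable, which the
acceptance checks exploit as a negative control.

Default conditions mirror the targeted study design: 2 diet groups × 12
samples, both compartments measured on every animal over a shared
40-genus namespace, 80 genes, 20 + 20 metabolites, 5 phenotypes, depth
20,000. No empirical effect sizes exist for this design to copy, so
the loadings (0.8 vs 0.3), diet-effect scale (half-normal
with SD 2 latent units, so roughly half of all features pass the
screen at $n = 12$), and noise SD 0.5 are calibration choices fixed
once; with two factors the gene layer carries exactly two planted
modules, matching the two dense subnetworks the comparison reports.

What the generator deliberately does **not** emulate: phylogenetic
correlation among taxa, overdispersion beyond the latent noise
(softmax–multinomial rather than Dirichlet-multinomial), zero-inflation
structure, batch effects, and longitudinal sampling. Passing tests
therefore demonstrate that the pipeline recovers planted covariance
asymmetry under clean compositional noise — not that it is robust to
every pathology of real sequencing data.

# Problem sizes and numerical tolerances

The test suite runs the full pipeline at the default conditions
(roughly 185 features, 24 samples, ~10,000 candidate edges per run) for
20-seed win-rate checks, 100 random graphs of ≤ 30 nodes for the BIBC
oracle equivalence (tolerance 1e-9, plus the exact total-BIBC
identity), 10 permutations × 19,900 candidate pairs for null
calibration, and 5,000 simulated degrees for exponent recovery. CLR
centering is asserted to 1e-9 × features; closed-form statistics
(Fisher df = 4 tail, exact Wilcoxon enumeration) to 1e-6 or better.
BH adjustment is `stats::p.adjust`, cross-checked against a
step-up reference implementation.

# Known limitations

* Edge significance rests on the Spearman t-approximation; at
  $n = 12$ per group the exact permutation null differs slightly in the
  far tail. The BH family is all candidate edges jointly — a declared
  choice where the family definition is ambiguous.
* The meta-analytic AND-filter (both groups must agree in sign)
  discards condition-specific associations by design; associations
  present only under HFD or only under NC are invisible.
* Louvain maximizes modularity, not density; ranking *by* density after
  the fact approximates a density detector and can split one planted
  module when inter-module edges are very sparse.
* The win-rate acceptance properties are statements about the
  generator's conditions (n = 12/group, loadings 0.8/0.3), not about
  any particular real dataset.
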