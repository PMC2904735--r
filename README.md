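# graphletsig

Graphlet signature clustering for functional-genomics screens.

Genome-wide RNAi screens produce hit lists with no pathway structure.
`graphletsig` integrates such a hit list with a protein–protein interaction
(PPI) network and finds groups of hits whose *network neighbourhoods look
alike* — candidate members of the same regulatory pathway — then grows each
group into a connected candidate-pathway subnetwork.  It is aimed at
systems-biology analysts who have (i) an undirected PPI edge list, (ii) a
per-gene screen Z-score table, and optionally (iii) pathway gene sets, and
who want a reproducible, statistically scored shortlist of pathway
candidates.

## The method

Each node's topology is summarized by its **graphlet degree vector** (GDV):
for the 30 connected graphlets on 2–5 nodes and their 73 automorphism
orbits (orbit 0 = the edge, 3 = the triangle, 8 = the square, …, 72 = the
5-clique), coordinate *i* counts how many induced subgraphs touch the node
at orbit *i*.  Signatures are compared with the weighted log-scale
similarity

    D_i = w_i |log(u_i+1) − log(v_i+1)| / log(max(u_i,v_i)+2)
    S(u,v) = 1 − Σ D_i / Σ w_i,     w_i = 1 − log(o_i)/log(73)

where `o_i` counts the orbits that affect orbit *i* under anchored subgraph
containment.  For every screen hit with degree > 3, a cluster is formed by
scanning similarity thresholds 96%, 95%, …, 90% and keeping, at the first
non-empty threshold, the hit plus all eligible nodes at or above it.
Clusters of size ≥ 3 are scored for screen-hit enrichment with the
seed-excluded hypergeometric tail (no multiple-testing correction), the
number of significant clusters is judged against 1,000 same-size random
clusters (empirical p, Z-score, normal tail p), and each significant
cluster is expanded by its direct neighbours into a connected subnetwork
whose diameter can be compared with the diameters of curated pathway gene
sets.

A synthetic-data generator plants topologically coherent pathway modules in
a heavy-tailed background with screen effects, so the entire analysis is
testable end to end with no downloads.

## Worked example

A 26-node toy network ships with the package: two 5-cliques, a 6-ring with
chords (the "pathway"), a hub with six spokes, and a short path, with
Z-scores making the ring members and the hub screen hits.

```r
library(graphletsig)
net <- system.file("extdata", "toy_network.tsv", package = "graphletsig")
ann <- system.file("extdata", "toy_annotations.tsv", package = "graphletsig")
gmt <- system.file("extdata", "toy_genesets.gmt", package = "graphletsig")
cfg <- pipelineConfig(network = net, annotations = ann, geneSets = gmt,
                      outDir = tempfile(), nullRuns = 200, seed = 5)
report <- runPipeline(cfg)
#> [graphletsig] labelling screen hits (|Z| > 1)
#> [graphletsig] eligibility filter (degree > 3)
#> [graphletsig] counting graphlet degree vectors on the full network (26 nodes, 40 edges)
#> [graphletsig] similarity matrix over 17 eligible nodes
#> [graphletsig] forming clusters around 7 eligible screen-positive seeds
#> formAllClusters: 6 formed, 0 singleton, 1 unformed of 7 seeds
#> [graphletsig] scoring cluster enrichment (alpha = 0.05)
#> [graphletsig] random-cluster null model (200 runs)
#> [graphletsig] expanding significant clusters
#> [graphletsig] pathway diameter survey over 3 gene sets

head(report$enrichment, 3)
#>   seed size k hit_rate     p_value significant
#> 1   C1    5 5      100 0.001373626        TRUE
#> 2   C2    5 5      100 0.001373626        TRUE
#> 3   C3    5 5      100 0.001373626        TRUE

report$null
#> NullModelSummary: observed = 6 significant clusters over 200 randomization runs
#>   null mean = 0.22, sd = 0.46, empirical p = 0, Z = 12.53, normal-tail p = 2.44e-36
```

Reading the numbers: each of the six ring members seeds a cluster
containing the other five (similarity 1 at the 96% threshold — the ring is
vertex-transitive), giving hit-rate 100% and enrichment p =
C(6,5)/C(16,5) ≈ 0.00137 against the 17-node eligible universe; the hub,
topologically unlike everything else, forms no cluster.  Random same-size
clusters almost never reach six significant clusters, hence the empirical
p of 0.  The stage tables (labels, GDVs, similarities, clusters,
enrichment, null counts, expansion, survey) are written under `outDir`.

For real data, replace the three paths; `vignettes/` documents every
parameter, and `inst/scripts/graphletsig.R` exposes the stages as shell
subcommands (`simulate`, `gdv`, `cluster`, `enrich`, `nulltest`, `expand`,
`survey`, `run`).

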