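# cnsnet

Community detection for **attributed networks** — undirected graphs whose
nodes carry categorical annotations (functional classes in a molecular
interaction network, topics and affiliations in a collaboration network,
roles and locations in an organisational network). Communities in such
networks are shaped jointly by the wiring and by the attributes; `cnsnet`
implements **coupled node similarity (CNS)**, a similarity that learns how
attribute values are used in the network instead of treating all mismatches
alike, and uses it to drive weighted community detection.

## The method

For each attribute *m* and value pair *(x, y)*, three terms are coupled:

- **intra-attribute** similarity
  δ<sup>Ia</sup><sub>m</sub>(x,y) = |g(x)||g(y)| / (|g(x)| + |g(y)| + |g(x)||g(y)|),
  a value-frequency term (g(x) = nodes carrying x);
- **inter-attribute** similarity δ<sup>Ie</sup><sub>m</sub>(x,y), built from
  information conditional probabilities
  P<sub>n|m</sub>(B | x) = |g\*<sub>n</sub>(B) ∩ g<sub>m</sub>(x)| / |g<sub>m</sub>(x)|
  via the subset minimisation
  min<sub>B⊆F<sub>n</sub></sub> {2 − P(B|x) − P(B̄|y)}, solved in closed form;
- **attribute-to-structure** similarity
  δ<sup>AS</sup><sub>m</sub>(x,y) = (edges between g(x) and g(y)) / (|g(x)||g(y)|),
  the homophily term.

The node similarity is CNS(i,j) = Σ<sub>m</sub> δ<sup>Ia</sup> · δ<sup>Ie</sup> ·
δ<sup>AS</sup> at the two nodes' value pair (variants `cns2`–`cns4` use other
combinations). It weights the graph's edges — W(i,j) = S(i,j) where an edge
exists, 0 otherwise — and communities are found on the weighted graph with
**SLPA** (speaker–listener label propagation), **BGLL** (weighted-modularity
Louvain) or similarity-based **K-medoids**. Results are scored against ground
truth with NMI, F-measure and optimal-matching accuracy, and a
planted-partition generator produces attributed benchmark networks with three
attribute assignment rules. Baseline similarities (adjacency, cosine,
Jaccard, SMC, CAS) are included for comparison.

## Worked example

The package ships a seven-author collaboration network with `topic` and
`country` attributes in which one author, George, is structurally ambiguous —
he sits symmetrically between two triangles:

```r
library(cnsnet)
toy <- toy_fixture()
g <- toy$graph
g
#> <attributed_graph> 7 nodes, 8 edges, 2 attribute(s): topic, country

intra_attribute_similarity(g, "country", "AU", "CN")
#> [1] 0.5454545        # = 6/11: AU and CN are frequent together
round(cns(g, "George", "Ying"), 2)
#> [1] 0.41
round(cns(g, "George", "Jones"), 2)
#> [1] 0.29             # attribute coupling breaks the structural tie

fit <- detect_communities(g, measure = "cns1", algorithm = "bgll", seed = 1)
fit
#> <cns_communities> bgll + cns1: 7 nodes in 2 communities, WQ = 0.3869
evaluate_partition(toy$truth, fit)
#> # A tibble: 1 × 3
#>     nmi f_measure accuracy
#>   <dbl>     <dbl>    <dbl>
#> 1     1         1        1
```

CNS rates George more similar to Ying (0.41) than to Jones (0.29) because
Australian and Chinese authors collaborate often, so BGLL on the CNS-weighted
graph assigns him to the Ying–Hua–Pitt community — exactly the ground truth,
which structure-only or match/mismatch similarities cannot resolve.

Synthetic benchmarks and sweeps:

```r
bm <- generate_benchmark(benchmark_spec(mu = 0.1), seed = 42)
fit <- detect_communities(bm$graph, "cns1", "bgll", seed = 42)
evaluate_partition(bm$truth, fit)

sw <- sweep_benchmark(mu = seq(0.1, 0.9, 0.2),
                      measures = c("adjacency", "smc", "cns1"),
                      algorithms = "bgll", n_seeds = 5, seed = 1)
autoplot(sw)   # accuracy vs mixing, one line per measure
```

A command-line front end wrapping these functions is installed at
`system.file("cli", "cns.R", package = "cnsnet")` with subcommands
`similarity`, `detect`, `benchmark`, `evaluate` and `sweep`.

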