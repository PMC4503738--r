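# tiesim — weighted social network formation with tie aging and deletion

`tiesim` is an R package for simulating and analysing the formation of
weighted social networks from two empirically grounded tie-creation
mechanisms — *cyclic closure* (befriending a friend of a friend, biased
toward strong ties) and *focal closure* (linking to a random stranger) —
combined with one of three ways a relationship can end:

* **node deletion (ND):** a person drops out and loses all ties at once;
* **link deletion (LD):** a single tie breaks abruptly, regardless of its
  strength;
* **aging:** every tie weight decays by a factor `f` per step and ties
  falling below a threshold `w_th` disappear.

All three produce *Granovetterian* networks — strongly tied communities
connected by weak bridges — but they differ sharply in modularity,
within-community weight homogeneity, and the shapes of the degree, strength
and weight distributions. The package ships the complete analysis suite
needed to see this: distributions with maximum-likelihood power-law
exponents, neighbourhood overlap versus weight, clustering and
nearest-neighbour-degree profiles, an in-repo seeded Louvain, weighted link
communities with partition-density cuts, link-percolation curves with
threshold gaps (Δf_c), and the closed-form clique theory of the aging model
(equilibrium weight `6δ/((1−f)(n−1))`, flat strength `6δ/(1−f)`).

It is directly reusable wherever a realistic weighted contact network is
needed as a substrate, e.g. epidemic models on social networks.

## A worked example

```r
library(tiesim)

p <- model_params(2000, "AGING", aging_factor = 0.9, w_th = 0.01,
                  p_r = 0.005, p_delta = 0.05, steps = 10000, seed = 3)
net <- run_simulation(p)$network
net
#> weighted_network: 2000 nodes, 11087 edges, <k> = 11.087

average_clustering(net)
#> [1] 0.8801486

part <- louvain_partition(net, seed = 1)    # binary, final level
part
#> partition (final, binary): 82 communities, Q = 0.9424

intra_community_weight_fluctuation(net, part)$aggregate
#> [1] 0.5340105

d <- delta_fc(net, n_shuffles = 10, seed = 1)
d$delta_fc
#> [1] 0.8266438
```

Read: the aging mechanism builds an exceptionally modular network
(Q ≈ 0.94 against ≈ 0.66 for LD at the same scale) whose within-community
tie weights are homogeneous (σ_c/⟨w⟩_c ≈ 0.53 < 1, against ≈ 2 for ND/LD),
and removing the weakest ties first fragments it after only ~8% of the
edges are gone, while removing the strongest first takes ~91% — the
weak-tie bridging gap Δf_c ≈ 0.83.

The strength of every node hovers near the theoretical
`6δ/(1−f) = 60` independently of its degree:

```r
clique_equilibrium_weight(11, 0.9) * 10
#> [1] 60
subset(strength_vs_degree(net), count >= 30)$mean
#> [1] 53.9 53.6 53.2 55.2 52.9 53.9 53.7 53.8 54.3 53.8 53.3 54.7 54.2 51.8
```

Presets for the reference parameter sets and the four-statistic summary
table (⟨k⟩, C, binary Louvain Q, σ_c/⟨w⟩_c for each mechanism):

```r
ps <- preset_params("desk")          # N = 2000, T = 10000, 10 realizations
tab <- table1_pipeline(ps$params, n_realizations = ps$n_realizations)
```

A command-line front end with `simulate`, `analyze`, `communities`,
`percolate`, `theory` and `table1` subcommands is installed under
`inst/cli/tiesim` (TSV in, TSV out, `--config` files supported).

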