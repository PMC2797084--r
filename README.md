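# crossnet

Proteomics-first discovery of dysregulated sub-networks in
protein–protein interaction (PPI) networks.

Proteomic screens of tumor versus control tissue yield short lists of
proteins with significant fold change, but they see only a biased slice
of the proteome. `crossnet` uses those hits as **seeds** for a network
search: every protein is scored for **network crosstalk** with the seed
set by a random walk with restart, the raw scores are calibrated against
a **degree-matched Monte Carlo null**, and each seed's neighborhood
yields two candidate sub-networks (all interacting partners, and the
partners with significant crosstalk — the *crosstalkers*). Candidates
are then scored for **synergistic dysregulation** — the mutual
information between their aggregate mRNA expression profile and the
phenotype — against a size-matched random-star null, and top-ranked
sub-networks become features for cross-cohort disease classification.
The package targets computational biologists working with a proteomic
hit list, a PPI edge list, and one or more labeled expression cohorts.

## The model in brief

Crosstalk scores are the stationary distribution of

α*ₜ*₊₁ = (1 − r) P α*ₜ* + r ρ

where P is the column-stochastic walk matrix of the PPI graph
(P(u,v) = 1/|N(v)|, or reliability-weighted), ρ the restart distribution
over the seed set (uniform, or fold-change-weighted), and r = 0.5 the
restart probability. Raw scores are standardized per protein against
n = 1000 degree-matched random seed sets,

z_S(v) = (α(v) − μ_S(v)) / σ_S(v),

and proteins with z_S(v) > z* = 3.45 (p ≈ 0.001 under a normal null)
are crosstalkers. A candidate sub-network Q is scored by

φ(Q) = MI( quantize₆( Σ_{v∈Q} e(v) / √|Q| ), c )

in bits, and is significant when φ exceeds the mean + 1 sd of random
star sub-networks of the same size. Classification uses the aggregate
profiles of the top-k sub-networks with a linear-kernel SVM, evaluated
by F-measure (harmonic mean of precision and recall, disease class
positive).

## Worked example

Everything below runs on a synthetic benchmark with known ground truth —
a 500-node scale-free network with a planted 20-node dense module whose
genes carry a mean shift of 1.5 between classes (20 + 20 samples):

```r
library(crossnet)

bench <- generate_benchmark(synthetic_config(rng_seed = 7))
bench
#> Synthetic benchmark: 500-node network, 20-gene planted module, 30 seeds, 40 samples

res <- discover_subnetworks(bench$network, bench$seeds, bench$data, rng_seed = 42)
res$scores
#> Adjusted crosstalk scores over 500 proteins (z* = 3.45): 10 above cutoff
table(res$labels)
#> crosstalker  interactor       other
#>          10         111         379

tab <- synergy_table(res$assessments)
head(tab[order(-tab$phi), ], 5)
#>   seed       kind size phi null_mean null_sd significant skipped
#>  g0285 interactor   15   1     0.292   0.319        TRUE   FALSE
#>  g0431 interactor   12   1     0.308   0.323        TRUE   FALSE
#>  g0482 interactor   12   1     0.308   0.323        TRUE   FALSE
#>  g0024 interactor   19   1     0.269   0.313        TRUE   FALSE
#>  g0211 interactor   13   1     0.303   0.322        TRUE   FALSE
```

The top candidates reach φ = 1 bit — the ceiling H(c) for balanced
classes, i.e. their aggregate profile separates tumor from control
perfectly — far above the size-interpolated star-null mean + sd
(≈ 0.29 + 0.32). Using the best sub-network as a single feature to
classify an independently generated cohort sharing the same planted
module:

```r
ranked <- select_features(res$assessments)   # 38 significant sub-networks
cfg <- synthetic_config(rng_seed = 7)
set.seed(cfg$rng_seed + 500)
test <- generate_expression(cfg, bench$truth, bench$network)
cross_classify(res$data, normalize_expression(test), ranked, k = 1)
#> Cross-classification with 1 feature(s): precision 0.952, recall 1.000, F 0.976
```

Real data enter through `load_network()` (TSV edge list plus optional
protein-complex table, merged as cliques), `read_seed_list()` and
`read_expression()`; `map_seed_set()` restricts a hit list to proteins
present in the network. A thin command-line wrapper with
`simulate` / `crosstalk` / `calibrate` / `synergy` / `classify`
subcommands lives at `inst/cli/crossnet.R`.

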