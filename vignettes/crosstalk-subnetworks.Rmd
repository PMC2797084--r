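---
title: "Crosstalk-based discovery of dysregulated sub-networks"
author: "crossnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosstalk-based discovery of dysregulated sub-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnet)
```

## The problem

Proteomic screens of diseased versus control tissue produce short lists of
proteins with significant fold change — but such screens see only a small,
biased slice of the proteome, over-sampling abundant and well-studied
proteins.  `crossnet` treats those hits as *seeds* for a network search:
if disease processes concentrate in densely interacting "hotspot" regions
of the protein–protein interaction (PPI) network, then proteins with
strong *network crosstalk* to the seed set are good candidates for a role
in the phenotype even when the screen itself never detected them.
Candidate sub-networks built around each seed are then tested for
*synergistic dysregulation* — coordinate mRNA-level differential
expression — on independent expression cohorts, and the best sub-networks
become features for cross-cohort disease classification.

## The model, stage by stage

### Network model

The interactome is an undirected graph $G = (V, E)$ over protein IDs with
optional reliability weights $w(u,v) \in (0,1]$.  Binary interactions and
protein complexes are merged with the *matrix model*: each complex
contributes a clique among its members.  Duplicate edges keep the maximum
weight — when a weighted binary edge and a weight-1 complex edge disagree
we preserve the stronger evidence; the rule is configurable only in the
sense that callers can pre-filter their tables, and is stated here because
interaction databases leave it open.  Self-loops are dropped; node
membership is defined by the kept edges, so readers never produce isolated
nodes.

### Crosstalk by random walk with restart

A random walk starts at a seed; at each step it moves to a uniformly
chosen interaction partner with probability $1-r$ or restarts at a seed
with probability $r$.  Its stationary distribution $\alpha(v)$ — the
long-run fraction of time at $v$ — is the crosstalk score, computed by
iterating

$$\alpha_{t+1} = (1-r)\,P\,\alpha_t + r\,\rho,$$

with $P(u,v) = 1/|N(v)|$ (or weight-normalized when edge weights are
used) and restart vector $\rho$ uniform over the seeds (or proportional
to fold-change z-scores).  $r=0$ reduces to PageRank of the network,
$r=1$ to the restart vector; the default $r = 0.5$ keeps the measure
local to the seeds while still rewarding multiple alternate paths.

Numerical choices the iteration contract leaves open:

* convergence is declared when the L1 change of successive iterates
  drops below `tol = 1e-10` (with `max_iter = 10000` as a guard); the
  contraction factor is $1-r$, so the default converges in a few dozen
  iterations;
* probability mass on degree-0 nodes is redirected to $\rho$ each step,
  preserving $\lVert\alpha_t\rVert_1 = 1$ exactly;
* components containing no seed legitimately end with $\alpha = 0$; they
  are reported, not treated as errors.

`solve_crosstalk_exact()` solves the same fixed point as a dense linear
system, $\alpha = r(I-(1-r)P')^{-1}\rho$; it exists purely as an
independent oracle for testing and is guarded to 2000 nodes.

### Degree-matched calibration

Proteomic seeds are far better connected than average proteins, and raw
random-walk scores inflate around hubs.  Calibration draws $n = 1000$
*degree-matched* null seed sets: every node joins the bucket of the seed
minimizing the absolute degree difference (ties broken uniformly at
random), and a null set takes one uniform draw per bucket.  Re-running
the walk for each null set (restarts uniform over the null set, whatever
weighting the real run uses) gives per-protein null statistics
$\mu_S(v), \sigma_S(v)$ (n−1 denominator), and the adjusted score is the
z-score $z_S(v) = (\alpha(v) - \mu_S(v))/\sigma_S(v)$.  A protein with
$z_S(v) > z^\ast$ is a *crosstalker*; the default $z^\ast = 3.45$
corresponds to $p = 0.001$ under a normal approximation of the null.
Non-significant direct neighbors of seeds are *interactors*.

Two implementation notes:

* **Seed anchoring.**  When several seeds share a degree that few other
  nodes have, purely random tie-breaking can leave a seed's bucket empty,
  making the null undefined.  Each seed therefore stays in its own bucket
  (it always attains the minimal degree difference, zero); random
  tie-breaking applies to every other node.
  `partition_buckets(anchor_seeds = FALSE)` gives the fully exchangeable
  rule, under which (marginally over partitions) the bucket model on a
  regular graph reduces exactly to uniform seed-set sampling — the
  package's test suite verifies that reduction against an independent
  uniform-sampling oracle.  Conditional on one fixed partition, as any
  single calibration run is, inclusion probabilities are $1/|B(u)|$ and
  small deviations from the marginal model remain.
* **Degenerate variance.**  Where $\sigma_S(v) = 0$ the z-score is
  $\pm\infty$ by the sign of $\alpha(v)-\mu_S(v)$ (0 on equality) and the
  count of such nodes is reported.

### Candidate sub-networks and synergy

Each seed $u$ yields two candidates: the *interactor sub-network*
$N(u)$ and the *crosstalker sub-network*
$N^\ast(u) = \{v \in N(u) : z_S(v) > z^\ast\}$.  The seed itself is
excluded from its own candidate — candidates are defined over
interacting partners; an `include_seed` switch exists for sensitivity
analyses.  Empty or singleton candidates are kept for bookkeeping but
marked unscorable, because the synergy null starts at size 2.

Synergy of a candidate $Q$ on an expression dataset is

$$\phi(Q) = \mathrm{MI}\big(\mathrm{quantize}_k(e(Q)),\, c\big), \qquad
  e(Q) = \frac{1}{\sqrt{|Q|}}\sum_{v \in Q} e(v),$$

with every gene row standardized to mean 0, sd 1 (sample convention,
classes pooled) beforehand, $k = 6$ equal-width bins spanning the
observed range (right-open except the last; a constant profile maps to
bin 1), and plug-in mutual information in bits.  The $1/\sqrt{|Q|}$
aggregation keeps independent noise at unit variance so coordinate
shifts, not set size, drive the score.  Genes absent from the matrix are
dropped and the *effective* size is used everywhere downstream.  The MI
base is a convention (the score is used only relative to its null);
equal-frequency binning was considered and rejected as the default
because equal-width bins preserve the bimodal signature of a
class-shifted aggregate profile.

### Star-topology significance

A candidate is a star — all members interact with one protein — so its
null must be too: for each size $s \in \{2,4,8,16,32,64\}$, draw a random
hub uniformly from $D=\{v : |N(v)| \ge s\}$, then $s$ of its neighbors
uniformly, score $\phi$, and repeat $n = 1000$ times.  Sizes exceeding
the maximum degree are dropped with a warning.  Null mean and sd are
interpolated piecewise-linearly at the candidate's effective size
(extrapolated with the last segment's slope above the largest sampled
size, and flagged); a candidate is *significant* when
$\phi \ge \text{mean} + 1\,\text{sd}$.  The 1-sigma rule is lenient by
construction (roughly an 84th-percentile cut under normality); it is the
reporting threshold, not a family-wise error control.

### Classification

Significant sub-networks from the training cohort are ranked by $\phi$
(ties: smaller size, then seed ID), their aggregate profiles become
features, and a linear-kernel SVM (cost 1) is trained and applied to an
independent test cohort — genes intersected with each cohort's
measurements, features standardized with training statistics only (the
test cohort must not leak into feature scaling).  Performance is the
F-measure with the disease class as positive.  Kernel and cost are
deliberately minimal: the features are one-dimensional summaries
already, and the cross-cohort setting punishes anything tunable.

## The synthetic benchmark

`generate_benchmark()` emulates the shape of the real inputs with known
ground truth:

* **Network**: a preferential-attachment backbone (2 initial nodes, 2
  edges per new node, attachment probability proportional to degree + 1)
  gives a connected, heavy-tailed graph; a planted module of 20 nodes is
  additionally wired at internal edge probability 0.5 — the "hotspot".
  Defaults: 500 nodes, 1092-ish edges.
* **Expression**: one gene per node, 20 + 20 samples; planted-module
  genes gain a mean shift $\delta = 1.5$ (noise sd $\sigma = 1$) in the
  disease class; all other entries are independent Gaussian noise.
  A shift model rather than resampled real data keeps every effect size
  controlled.
* **Seeds**: 30 proteins drawn 70/30 from the module and its direct
  neighbors — under these defaults the module part caps at all 20 module
  nodes — with synthetic fold-change z-scores $|N(3,1)|$ so the
  weighted-restart path is exercisable.

What passing on this benchmark does *not* show: real interactomes have
ascertainment structure (study bias correlated with degree) that a
preferential-attachment model only caricatures; microarray noise is
heteroskedastic and correlated across genes, not i.i.d. Gaussian; and the
one-gene-per-protein identity mapping sidesteps probe-to-gene ambiguity
entirely.  The benchmark validates the machinery, not the biology.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at the
default benchmark scale (500 nodes, 1000-replicate nulls), with 50
generator replicates for the synergy-recovery study, 20 for the
calibration-recovery and effect-free studies, and 20 random graphs of up
to 200 nodes for the solver-oracle comparison — sizes at which every
Monte Carlo quantity is stable to the tolerances asserted while the
whole suite stays fast.  Every stochastic stage takes an explicit
`rng_seed` and reproduces bitwise; the self-calibration sanity statistic
pools z-scores over 20 fresh degree-matched draws because a single
draw's pooled sd carries heavy sampling noise (single-draw z-scores are
strongly correlated across proteins).

## Known limitations

* Weight conflicts between binary and complex-derived edges resolve to
  the maximum; databases that encode evidence differently may want a
  different rule upstream.
* The star null conditions only on candidate *size*, per the reference
  scheme; candidates of hubs inside a dysregulated region face a null
  partly contaminated by that same region, which is conservative there.
* Whether the 1-sigma interpolated rule and any fixed absolute MI
  threshold agree depends on cohort size; both numbers are reported so
  users can apply either.
* z-scores of $\pm\infty$ (zero null variance) are excluded from pooled
  summaries and flagged rather than imputed.
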