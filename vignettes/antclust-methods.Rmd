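---
title: "Ant colony clustering of athlete profiles: model, tunables, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant colony clustering of athlete profiles: model, tunables, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antclust)
```

## The problem

Athlete monitoring produces wide tables — physical indicators (speed,
strength), physiological measurements (VO2, heart-rate response),
technical scores and competition results — with no labels attached.
The analyst's questions are unsupervised: how many behavioural types are
present, which athletes form each type, and how stable is that structure?
`antclust` answers them with an ant-colony-optimization (ACO) clustering
engine plus the validation machinery needed to trust its output.

## The model

### Path construction

The `n` athletes are points in feature space with pairwise distances
$d_{ij}$ (Euclidean on the feature columns by default; Manhattan and
cosine are available). Each of $m$ ants starts at a uniformly drawn
point and repeatedly hops to an unvisited point, choosing $j$ from $i$
with probability

$$P(i \to j) \;\propto\; \tau_{ij}^{\alpha}\,\eta_{ij}^{\beta},
\qquad \eta_{ij} = \frac{1}{d_{ij} + \varepsilon_d},$$

until all points are visited. $\tau_{ij}$ is the pheromone trail on the
edge, $\eta_{ij}$ the heuristic desirability (inverse distance), and
$\alpha, \beta \ge 0$ set their relative influence. The weights are
evaluated in log space and renormalized against their maximum before
sampling, so extreme exponents (e.g. $\beta = 50$, which degenerates to
the greedy nearest-neighbour tour) cannot overflow.

### From a path to a partition

A Hamiltonian path over a clustered point cloud tends to traverse each
cluster contiguously and jump between clusters along long edges. We
therefore cut the $k-1$ largest of the $n-1$ consecutive path edges
(ties broken at the earliest path position) and take the contiguous
segments as clusters. This guarantees exactly $k$ non-empty clusters for
any path and keeps the mapping from paths to partitions deterministic.

### Partition cost

Pheromone reinforcement needs a scalar notion of path quality. We use
the size-weighted within-cluster cohesion

$$\mathrm{cost} \;=\; \frac{1}{n}\sum_{c}\,|c|\cdot
  \overline{d}_{\text{pair}}(c),$$

the average over athletes of their mean distance to own-cluster peers
(members of singleton clusters contribute zero). The weighting matters:
an unweighted sum of per-cluster mean distances is minimized by shaving
one or two outliers into singletons and leaving everything else in one
wide cluster, because the big cluster then counts only once regardless
of its size. On the package's standard fixture that degenerate solution
beats the true three-archetype split under the unweighted objective,
while the size-weighted form ranks the true structure first. The cost is
a package design choice — quality-driven reinforcement requires one, but
no canonical definition exists for path-based clustering.

### Pheromone update

After all $m$ ants finish an iteration, every trail evaporates and the
uncut edges of each ant's path receive a quality-scaled deposit:

$$\tau_{ij} \;\leftarrow\; (1-\rho)\,\tau_{ij} \;+\;
  \sum_{k=1}^{m} \Delta\tau_{ij}^{(k)},
\qquad \Delta\tau_{ij}^{(k)} = \frac{Q}{\mathrm{cost}_k + \varepsilon_d}$$

(deposit only if edge $(i,j)$ is an uncut edge of ant $k$'s path). Edges
inside good clusters are reinforced; cut edges and unused edges only
evaporate. This is the classic ant-cycle scheme: all ants deposit, scaled
by solution quality. Entries are floored at $\tau_{\min}$ so every edge
retains nonzero selection probability (ergodicity).

### Stopping and the reported solution

Iteration stops at the budget $T$ or as soon as the *pheromone change
rate* — the maximum relative entry change in one update — falls below
$\varepsilon_{\mathrm{conv}}$. With steady stochastic deposits the
change rate hovers near $\rho$, so on diverse runs the budget usually
binds; the criterion fires when the colony locks onto a stable path set.
The returned solution is the best by cost over *all* iterations, not the
final one, making the result monotone in $T$.

## Tunables

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `m` | ants per iteration | 20 | grid: 10/20/50 |
| `iterations` ($T$) | iteration budget | 200 | grid: 100/500/1000 |
| `rho` ($\rho$) | evaporation per iteration | 0.1 | grid: 0.1/0.5/0.9 |
| `tau0` ($\tau_0$) | initial trail level | 1.0 | grid: 1.0/0.5/0.1 |
| `alpha` ($\alpha$) | pheromone exponent | 2 | grid: 2/3/4 |
| `beta` ($\beta$) | heuristic exponent | 2 | grid: 2/3/4 |
| `Q` | deposit scale | 1.0 | not part of the grid |
| `k` | cluster count | 3 | scan 2–5 with `cluster_scan()` |
| `epsilon` | convergence threshold | 1e-4 | relative change rate |
| `tau_min` | trail floor | 1e-12 | positivity/ergodicity |
| `eps_d` | division guard | 1e-10 | in $\eta$ and $\Delta\tau$ |

`default_grid()` holds the reference grid (729 combinations);
`aco_grid_search()` evaluates it with repeated seeded runs, ranking by
mean silhouette with mean Davies–Bouldin as tiebreak — both indices are
reported, and on clearly structured data they improve together, so the
primary/tiebreak order is a convention rather than a trade-off. A
`max_evaluations` cap (seeded uniform subsample of the grid) bounds
desk-scale runtime; it is off by default and unused on the small
fixtures in the test suite.

Two points where the mechanism admits more than one reading were fixed
as follows. Initial trails are a *constant* $\tau_0$ (the value the
tuning grid varies); a randomized start is available as an explicit
$\pm 10\%$ jitter flag but is not the default, since a constant start
keeps the first iteration unbiased and the grid value meaningful. Ants
always traverse *all* points: partial tours would leave some athletes
unassigned and the path-cut extraction undefined.

## Randomness and reproducibility

One master seed governs a run. Each (iteration, ant) pair draws from its
own counter-based substream (a splitmix64 state keyed by seed, iteration
and ant index), so changing `m` or `iterations` never reshuffles the
draws of unrelated ants, and identical inputs give bit-identical results
— including across the command-line interface, whose partition and table
outputs are byte-reproducible from config + seed. Generator, subsampler,
k-means restarts and grid search derive named substreams from the same
master seed.

## Internal and supervised validation

**Silhouette.** $S(i) = (b(i) - a(i)) / \max(a(i), b(i))$ with $a(i)$
the mean distance to own-cluster peers and $b(i)$ the smallest mean
distance to another cluster; range $[-1, 1]$, higher better. Members of
singleton clusters score 0 — $a(i)$ has no peers there, and 0 is the
neutral convention. Computed from the same distance matrix the engine
clustered on.

**Davies–Bouldin.** $\mathrm{DB} = \frac{1}{k}\sum_i \max_{j \ne i}
(\sigma_i + \sigma_j) / d(c_i, c_j)$ with per-cluster scatters
$\sigma_i$ around Euclidean centroids; lower better. Centroid distances
are always Euclidean — the centroid formulation presumes a vector-space
mean — even when the clustering metric is not. Coincident centroids are
an error, not infinity.

**Cluster-to-label matching.** Supervised scores for an unsupervised
partition require a cluster-to-class assignment; we solve the optimal
one-to-one matching on the confusion table exactly (Hungarian
algorithm, zero-padded when counts differ) and verify it against
exhaustive bijection search in the tests. Precision, recall and F1 are
macro-averaged over the true classes; an empty denominator contributes 0.
AUC needs class scores, which a hard clustering lacks: we use the softmax
(temperature 1) of the negative Euclidean distance to the mapped
cluster's centroid, an explicit package construction, and omit AUC when
no feature data is supplied.

## The synthetic athlete generator

With no public athlete dataset bundled, the generator is the package's
ground-truth instrument. `default_athlete_spec(k, d)` defines $k$
archetypes over $d$ features organised in four named blocks (physical,
physiological, technical, performance). Each archetype's unit profile is
+1 on its own signature group of $\lfloor d/k \rfloor$ consecutive
features; multiplying by `separation` and adding isotropic Gaussian
noise (`within_sd`, diagonal only — no covariance information is
assumed, correlated noise being an extension hook) yields the samples.
For $k \ge 3$ all pairwise archetype distances are equal
($\mathrm{separation}\cdot\sqrt{2\lfloor d/k\rfloor}$); for $k = 2$ the
two profiles differ in the first named block only. The standard fixture
($k = 3$, $d = 8$, 20 athletes per archetype, separation 6, unit noise)
has a true-label silhouette of about 0.68: clearly clustered, visibly
overlapping — a realistic difficulty for 60 athletes.

Missingness is injected by blanking exactly
$\mathrm{round}(\mathrm{rate} \cdot n \cdot d)$ cells chosen without
replacement (not Bernoulli), so tests assert exact counts; duplicates
append $\mathrm{round}(\mathrm{rate} \cdot n)$ copied rows under fresh
IDs. Each archetype's noise substream is keyed by its own mean profile
and count rather than its position, so permuting the archetypes in a
spec reproduces the identical multiset of rows; cell-position-keyed
missingness breaks that symmetry, which therefore holds exactly only at
zero injection rates.

What the generator does *not* emulate: heterogeneous measurement units
(features share one scale), sport-specific physiology, skewed or heavy-
tailed marginals, longitudinal structure, and cluster-size imbalance
beyond what `n_per_cluster` encodes. Tests passing on this fixture show
the machinery is correct and the method recovers planted isotropic
Gaussian structure; they do not certify performance on real athlete
data.

Because the fixture is generated on one common scale, the package's own
validation runs cluster it as generated: z-scoring first would shrink
exactly the signature axes (between-archetype variance inflates those
columns' standard deviations) and silently weaken the stated 6-sigma
condition. For real data with mixed units, `standardize_features()`
(z-score with population standard deviation, divisor $n$; zero-spread
columns map to zeros) remains the documented default step.

## Preprocessing

`clean_features()` applies, in order: exact-duplicate row removal
(bit-identical feature rows, first kept — near-duplicates are out of
scope), dropping feature columns whose missing fraction exceeds a
threshold (default 0.5), then mean imputation (or row dropping, per
policy), and a final duplicate sweep since imputation can create new
exact duplicates; the operation is idempotent. Missing markers on input
are the empty cell, `NA` and `NaN`, case-insensitive. Repeated seeded
runs — not cross-validation — are the stability instrument throughout:
clustering has no held-out prediction target, so every stochastic
quantity is reported as mean ± sd over derived seeds.

## Baselines

K-means delegates Lloyd refinement to `stats::kmeans()` but seeds it
with our greedy-spreading (k-means++-style) centers, best of `n_init`
restarts by within-cluster sum of squares, fully seeded. DBSCAN is
implemented in the package on the distance matrix (no suitable
implementation among the package's dependencies): index-order expansion,
border points joining the first cluster that reaches them — fixed rules
that make output order-invariant up to relabeling. Its default `eps` is
the 90th percentile of `min_pts`-th-neighbour distances (k-distance
heuristic, `min_pts = 4`). In benchmarks DBSCAN's noise points are
excluded from its metric computation and counted; repeats with fewer
than two surviving clusters score `NA` and are dropped from its
averages.

## Numerical choices, edge cases, problem sizes

Log-space weight evaluation; lowest-index tie-breaks in sampling and
edge cuts; `iterations = 0` is an error (a run must iterate at least
once); `k = 1` (one cluster, no cuts) and `k = n` (all singletons) are
valid limits; internal indices require $k \ge 2$ and $n \ge 3$. The test
suite and the acceptance script validate at deliberate desk scale: the
standard 60-athlete fixture for structure recovery (scan over
$k \in 2..5$, 20 regenerated seeds), exhaustive partition enumeration at
$n \le 10$, $k \in \{2, 3\}$ for global-optimality checks (the colony's
best-of-5-seeds cost lands within 1% of the true optimum on ≥ 90% of
random instances), and 20 paired seeds for the k-means/DBSCAN
comparison. The achieved-cost/optimum check also bounds the method's
main structural limitation: path-cutting can only produce partitions
whose clusters are contiguous on some visited path, and with few ants on
ambiguous data the colony can lock onto a suboptimal path early.

## Known limitations

Runtime grows as $m \cdot T \cdot n^2$; hundreds of athletes are
comfortable, tens of thousands are not. Max–min and rank-based pheromone
schemes, parallel colonies and correlated synthetic noise are documented
extension points, not implemented. The supervised AUC construction is a
package definition, not a community standard — compare AUC values only
within this package.
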