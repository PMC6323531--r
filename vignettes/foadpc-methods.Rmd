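---
title: "Gray-level density-peaks segmentation with fruit-fly parameter selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-level density-peaks segmentation with fruit-fly parameter selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foadpc)
```

## The problem

Unsupervised segmentation of grayscale medical images (brain CT/MRI and
similar) partitions pixels into regions of homogeneous intensity so that
lesions, edema and normal tissue can be delineated without training data.
Clustering pixels directly is expensive at full resolution; `foadpc`
instead clusters the 256-bin gray-level histogram: gray levels are the
points, the number of pixels at each level is the point's weight, and the
absolute gray difference $d_{ij} = |g_i - g_j|$ is the distance. A pixel
then simply inherits the cluster of its gray level.

## Density-peaks clustering of the histogram

For every present gray level $g$ (one with at least one pixel), two
quantities are computed:

* **local density** — the number of pixels within the cut-off distance
  $d_c$:
  $$\rho(g) = \sum_{g' : |g - g'| < d_c} n(g'),$$
  where $n(g')$ is the histogram count. The inequality is strict, the
  level's own pixels are included (that offset is constant across levels
  and never changes rankings), and because distances are integers only
  $\lceil d_c \rceil$ matters.
* **separation** $\delta(g)$ — the distance to the nearest level with
  strictly higher density rank; the top-ranked level takes its *maximum*
  distance to any other level, so the global density peak always carries
  a large score.

Cluster centers should have both large $\rho$ (they sit on a histogram
mode) and large $\delta$ (they are far from any denser mode). Instead of
asking a human to pick them from the $\rho$–$\delta$ decision graph
(exported by `decision_graph()`), the product $\gamma = \rho\,\delta$ is
ranked and the top $k$ levels become centers. Remaining levels are visited
in decreasing density rank and each inherits the label of its nearest
denser neighbor, so labels flow downhill from every mode.

Determinism requires total orders where the definitions above give only
partial ones. The package uses, throughout: density ranking by
($\rho$ desc, count desc, gray asc); nearest-denser-neighbor distance ties
to the lower gray; center candidacy by ($\gamma$ desc, $\rho$ desc, gray
asc). A single-level histogram takes $\delta = 1$ by convention so
$\gamma$ stays defined, and is returned as a one-cluster result.

## The entropy fitness and the parameter search

The two free parameters are bounded by the 8-bit setting: the cut-off
distance $d_c \in [1, 10]$ (about 2% of the 256-level range, the usual
neighborhood-size rule for density peaks) and the cluster count
$k \in [2, 40]$ (beyond ~40 clusters an 8-bit medical image is
over-segmented). Their quality signal is the Shannon entropy of the
segmented image,
$$H = -\sum_c q_c \log_2 q_c,$$
over the cluster frequencies $q_c$: a segmentation that spreads pixels
over many well-populated regions retains more of the image's information.
$H \le \log_2 k_\mathrm{eff}$ always, with equality only for equally
populated clusters.

The fruit-fly optimizer (`foa_optimize()`) maximizes $H$ with a swarm
anchor holding the current $(d_c, k)$ location. Each generation, every fly
proposes `anchor + U(-5, 5)` per coordinate (a *random* step rather than a
fixed one, which helps escape local optima), proposals are clamped into
the box ($k$ rounded half-up), scored, and the anchor relocates to the
best proposal whenever it improves the best value found so far — so the
convergence trace is non-decreasing. Defaults are population 10 and 10
generations (100 evaluations).

A design note on the coordinate geometry: the classic fruit-fly
formulation scores a fly by the reciprocal distance of its $(X, Y)$
coordinates to the origin, $S = 1/\sqrt{X^2 + Y^2}$, and feeds $S$ to the
fitness. For this problem that transform is unusable: under uniform ±5
steps the probability that $S$ reaches even 28 is about
$\pi (1/28)^2 / 100 \approx 4\times10^{-5}$ per evaluation, so a
100-evaluation run would essentially never propose a large cluster count,
and the optimizer could not cover its own search range. The package
therefore treats the two decision variables as the swarm coordinates
directly — the anchor *is* $(d_c, k)$ — which preserves the smell/vision
alternation and the random step while making every cell of the parameter
box reachable.

Because only $\lceil d_c \rceil \in \{1..10\}$ and integer
$k \in \{2..40\}$ matter, the search space collapses onto a 390-cell
lattice; `grid_search()` enumerates it exhaustively and is therefore a
deterministic upper bound used by the tests to calibrate both stochastic
optimizers. Fitness evaluations are memoized per lattice cell.

## Quality metrics

Besides entropy, results carry the between-class variance **SEC**:
clusters are ordered by mean gray and each adjacent pair contributes the
classical two-class Otsu variance
$$\frac{N M}{(N+M)^2}\,(U_1 - U_2)^2,$$
with $N, M$ the pixel counts and $U_1, U_2$ the mean grays. Larger SEC
means stronger contrast between neighboring regions. "Adjacent" is
adjacency in mean-gray order — the histogram view has no spatial notion.
One-cluster segmentations take SEC 0 by convention.

## Baselines

* **Exhaustive grid** — ground truth for the search, 390 evaluations.
* **Weighted 1-D k-means** (`kmeans_gray()`) — Lloyd's algorithm on the
  present gray levels weighted by counts, k-means++ seeding, 10 restarts
  keeping the best weighted within-cluster sum of squares (a single start
  occasionally converges to a clearly inferior optimum; the tests
  cross-check against `stats::kmeans` on count-expanded data). Run at a
  fixed `k` (default 7, a common choice for brain images).
* **Real-coded GA** (`ga_optimize()`) — tournament selection (size 2),
  extended arithmetic crossover (rate 0.9), uniform-reset mutation,
  elitism of one; population 10, 20 generations — 200 evaluations, twice
  the fruit-fly budget. Two operator details were tuned once against the
  grid oracle and then frozen: the blend coefficient is drawn per gene
  from $U(-1, 2)$ rather than $U(0, 1)$, because the entropy objective
  peaks on the *boundary* of the box (small $d_c$, large $k$) and purely
  interior averaging cannot reach corners (children are repaired by
  clamping); and the mutation rate is 0.15 per gene, which keeps enough
  diversity for the 200-evaluation budget to refine the final integer
  cell. With these settings the GA matches the grid optimum within 1% on
  20/20 seeds for each standard phantom, and both optimizers reach
  consistent optima while the fruit-fly search spends half the
  evaluations.

## The phantom generator

All tests run on synthetic phantoms (`phantom_spec()`,
`phantom_generate()`): piecewise-constant regions (ellipses and
rectangles, painted in order) on a uniform background, plus additive
Gaussian pixel noise, rounded and clipped to `[0, 255]`, with exact
ground-truth labels. The defaults — 128×128 pixels, base grays 40/120/200
(at least 60 levels apart), noise σ = 5 — emulate the structure that
matters to a histogram method: a few dominant modes with noise-broadened
tails, resembling a lesion and an edema-like region on a dark background.
The standard test set holds five such phantoms (2–4 regions, one harder
case at σ = 8).

What phantoms do *not* emulate: Rician/speckle noise statistics of real
MRI/CT, bias fields, partial-volume edges, and anatomical texture.
Passing tests therefore demonstrate the correctness of the clustering,
the optimizers and the metrics under known conditions — not clinical
segmentation quality.

Accuracy against ground truth is scored by `match_and_score()`: Hungarian
one-to-one matching of predicted clusters to truth regions on the
confusion matrix, or — since an entropy-maximal segmentation deliberately
over-segments each noisy mode into many gray clusters — a many-to-one
merge (`one_to_one = FALSE`) that maps each predicted cluster to the
truth region it overlaps most. On the default noiseless phantom the
pipeline recovers exactly 3 clusters centered at the 3 base grays with
accuracy 1.0; at σ = 5 the merged accuracy stays ≥ 0.99 because modes 60+
levels apart essentially never cross the midpoint at that noise level.

## Numerical and engineering choices

* Entropy uses base-2 logarithms (bits) and the standard Shannon sign;
  $0 \log 0 = 0$.
* `round_half_up()` (i.e. $\lfloor x + 0.5\rfloor$) everywhere a real is
  quantized — `round()`'s half-to-even rule would make results depend on
  parity.
* Color inputs collapse by ITU-R BT.601 luma; inputs deeper than 8 bits
  are rejected unless an explicit min-max rescale is requested, because
  the whole parameterization ($d_c$ range, 256 bins) assumes 256 levels.
* Every stochastic entry point takes a `seed`; identical seeds give
  byte-identical JSON reports and label images, and results depend on the
  image only through its histogram (pixel-permutation invariant).
* Reports contain no timestamps; the JSON schema ships in
  `inst/schema/`.

Problem sizes in the test suite were chosen to exercise every code path
while staying lightweight: 200 random sparse histograms (≤ 20 levels,
≤ 10⁴ pixels) against a brute-force pixel-pair oracle, 5 phantoms × 20
seeds × (FOA + GA) against the exhaustive grid, and 128×128 phantoms for
the end-to-end runs.

## Known limitations

* Pure histogram method: spatially disconnected tissues with the same
  gray range always share a label; no spatial regularization.
* The entropy objective almost always prefers the largest admissible
  $k$ on noisy images — it measures information retention, not parsimony.
  Region-level interpretation should use the merged accuracy view or SEC.
* 8-bit only by design; DICOM windowing must happen upstream.
* The fruit-fly budget of 100 evaluations on a 390-cell lattice leaves
  the success rate against the exhaustive optimum at roughly 9 runs in
  10; runs that reach the $k$ bound only in the last generations may
  leave $d_c$ unrefined.
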