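# foadpc

Unsupervised segmentation of 8-bit grayscale images — brain CT/MRI slices
and similar — by **density-peaks clustering of the gray-level histogram**,
with the clustering's two free parameters chosen automatically by a
**random-step fruit-fly optimizer** that maximizes the entropy of the
segmented image.

## Who this is for

Researchers who need reproducible, training-free segmentation of
single-channel medical images, and anyone studying density-peaks
clustering or swarm-based parameter selection on a small, fully
controllable benchmark: the package ships a synthetic phantom generator
with exact ground truth, so every claim is testable without any external
image data.

## The method

Gray levels $g \in \{0..255\}$ are the clustered points, pixel counts
$n(g)$ their weights, and $d_{ij} = |g_i - g_j|$ the distance. For each
present level:

- local density $\rho(g) = \sum_{|g-g'|<d_c} n(g')$ — pixels within the
  cut-off distance $d_c$;
- separation $\delta(g)$ — distance to the nearest level of higher
  density rank (the top-ranked level takes its maximum distance);
- center score $\gamma = \rho \cdot \delta$.

The $k$ levels with the largest $\gamma$ become cluster centers — no
manual reading of the $\rho$–$\delta$ decision graph — and every other
level inherits the label of its nearest denser neighbor. Each pixel then
takes its gray level's cluster.

The parameters $d_c \in [1,10]$ and $k \in [2,40]$ are selected by a
fruit-fly optimizer: a swarm anchor holds the current $(d_c, k)$; each
generation every fly proposes `anchor + U(-5,5)` per coordinate, the
proposals are clamped into the box and scored by the Shannon entropy
$H = -\sum_c q_c \log_2 q_c$ of the resulting cluster-size distribution,
and the anchor relocates on improvement (elitism — the convergence trace
never decreases). Results also carry the between-class variance **SEC**
(summed adjacent-pair Otsu variance, larger = stronger region contrast).

Baselines with the identical objective: exhaustive grid search over the
390 effective $(d_c, k)$ cells (a deterministic upper bound), a real-coded
genetic algorithm (twice the evaluation budget), and weighted 1-D k-means
on the histogram. See `vignettes/foadpc-methods.Rmd` for the full model,
design decisions and limitations.

## Worked example

```r
library(foadpc)

# a 128x128 phantom: background 40, ellipse 120, rectangle 200, noise sd 5
ph  <- phantom_generate(phantom_spec(seed = 42))
res <- segment_image(ph$image, method = "foa", seed = 1)
res
#> <segmentation_result: method=foa d_c=1 k=40 effective_k=40>
#>   entropy = 4.9836 bits, SEC = 1990.76, evaluations = 100

round(res$trace, 4)
#> [1] 4.2354 4.4248 4.6253 4.7639 4.8989 4.9836 4.9836 4.9836 4.9836 4.9836

# exhaustive search over all 390 parameter cells finds the same optimum
segment_image(ph$image, method = "grid")
#> <segmentation_result: method=grid d_c=1 k=40 effective_k=40>
#>   entropy = 4.9836 bits, SEC = 1990.76, evaluations = 390

# merging gray clusters onto the 3 true regions recovers every pixel
match_and_score(res$labels, ph$truth, one_to_one = FALSE)
#> [1] 1
```

Reading the numbers: the optimizer converged by generation 6 to
`d_c = 1, k = 40` — on noisy images the entropy objective favors many
fine gray clusters (4.98 bits of the at most `log2(40) = 5.32`), and the
grid search confirms this is the global optimum. The fine clusters
nest cleanly inside the three true regions, so the merged pixel accuracy
is 1. On the noiseless version the pipeline returns exactly 3 clusters
centered at the base grays 40/120/200.

Artifacts: `write_report(res, "report.json")` (schema in
`inst/schema/`), `write_label_image(res$labels, mean_gray_palette(res),
"labels.png")`, `decision_graph(res$model$profile, "dg.csv")`,
`write_trace(res, "trace.csv")`.

From the shell (after install):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","foadpc",package="foadpc"))')" \
  segment scan.png --method foa --pop 10 --gen 10 --seed 1 \
  --out labels.png --report report.json
```

Input formats: PNG, PGM (P2/P5), TIFF; color collapses by BT.601 luma;
more than 8 bits per sample requires an explicit `--rescale`.

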