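---
title: "Latent motifs: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent motifs: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdict)
```

This vignette records the model behind `netdict`, the conventions the
implementation commits to, and the reasoning behind the choices that were
genuinely open. The README shows the user-facing workflow; here we explain
*why* the machinery looks the way it does.

## Mesoscale patches and uniform k-path sampling

A mesoscale patch is the `k x k` adjacency matrix `A_x` of the subgraph
induced by an ordered k-path `x`. Ordering nodes along a path solves the
`k!` representation ambiguity of an unordered k-node subgraph and guarantees
connectedness of the sample, which independent node sampling on sparse
graphs does not. Entries at positions `(i, i+1)` ("on-chain") are 1 by
construction; all other off-diagonal entries ("off-chain") carry the signal.
Diagonal entries record self-edges.

Uniform sampling over k-paths is implemented exactly, not by MCMC. With
`w_j(v)` the number of j-step walk extensions from `v` (computed by sparse
matrix-vector products in `walk_counts()`), drawing `x_1` proportional to
`w_{k-1}` and each successor proportional to `w_{k-i-1}` gives every k-walk
probability `1/total` exactly; rejecting walks with repeated nodes leaves the
exact uniform distribution on k-paths. A Markov-chain sampler with the same
target would add mixing error and burn-in/thinning parameters that nothing
in the package could verify; the dynamic program costs `O(k |E|)`
preprocessing and makes the samplers testable against enumeration oracles
(`enumerate_k_paths()`), which the test suite exploits heavily (chi-square
uniformity at 1e5 draws on enumerable fixtures). The rejection cap defaults
to 1e6 discarded walks; the sampler records its empirical acceptance rate,
which is also the natural diagnostic for "k too large for this graph".
Self-edges participate in walks (a walk may step `v -> v`) but never
survive the distinctness filter, so they never enter patches as path steps.

## The dictionary model and its fitting

The fitted object is a `k^2 x r` matrix `W` whose reshaped columns are the
latent motifs. Entries are clipped to `[0, 1]`, not merely kept nonnegative:
motifs are meant to be read as weighted k-node networks, and weights above 1
would have no interpretation against binary patches.

Fitting is classical online matrix factorization: at step `t` a minibatch of
`N` patches is coded by nonnegative least squares against the current
dictionary, the sufficient statistics are updated with the balanced `1/t`
schedule,

```
P_t = (1 - 1/t) P_{t-1} + (1/t) H H' / N
Q_t = (1 - 1/t) Q_{t-1} + (1/t) X H' / N ,
```

and `W` is refit by block coordinate descent on the quadratic surrogate
`tr(W'WP) - 2 tr(W'Q)` with entrywise projection onto `[0, 1]`. Any
weighting schedule with the same fixed points would be admissible; `1/t` is
the one with standard convergence guarantees for online NMF, and the
surrogate objective is verifiably non-increasing across update sweeps
(a unit test asserts this).

Numerical conventions:

* **Coding** (`code_patches()`) solves `min_{h >= 0} ||x - Wh||^2 + lambda
  ||h||_1` by exact cyclic coordinate descent, vectorized across the
  minibatch, to a 1e-8 tolerance on the largest coordinate change. The
  coordinate update uses the soft-shrinkage step `lambda/2` that matches
  this objective. `lambda` defaults to 0; the dictionary entries' box
  constraint already discourages degenerate solutions.
* **Degenerate atoms.** A motif with (numerically) zero aggregate code mass
  `P_jj` was never used; its column is skipped with a warning in a direct
  `update_dictionary()` call and retained silently at its current value
  inside `ndl()` (a motif may simply become active later in the stream).
  Zero-norm atoms are likewise inactive in coding (`h_j = 0`).
* **Initialization** is i.i.d. uniform on `[0, 1]` from the run seed; with a
  fixed seed the whole fit is bitwise reproducible. The defaults `T = 100`
  minibatches of `N = 1000` paths are deliberately generous; the desk-scale
  fixtures in the tests use far smaller values (8-30 iterations of 100-300
  paths), which already reach the documented recovery behaviour.
* **Symmetry** is not enforced on `W` during learning — the data are
  symmetric, so symmetry emerges — and motifs are symmetrized
  (`(L + L')/2`) only for display and community diagnostics.

## Reconstruction conventions

`reconstruct()` samples `T` k-paths (default `100 |E| / (k-1)`, covering
each edge about 100 times on-chain in expectation), codes each patch, and
averages reconstructed entries per unordered node pair over all (path,
position) incidences. Three conventions matter:

* **Diagonal.** Patch diagonals are carried in the data but excluded from
  the coding objective and from accumulation: pair weights concern node
  pairs, and self-edge reconstruction is out of scope.
* **Clipping.** Nonnegative combinations can exceed 1, so reconstructed
  entries are clipped to `[0, 1]` *before* averaging; weights are
  confidences and must stay in the unit interval.
* **Masking** (`mask_on_chain = TRUE`). For denoising, the on-chain entries
  of every motif are zeroed, on-chain positions are dropped from the coding
  objective, and on-chain incidences are discarded in accumulation. Without
  this, every observed edge is certified by the trivially-1 on-chain entries
  of the patches it anchors — the k = 2 dictionary reconstructs any graph
  perfectly and is useless as an anomaly detector (a test asserts its AUC is
  exactly 0.5). Masked scoring makes an edge's weight depend only on its
  off-chain appearances, i.e. on independent structural corroboration.

Thresholding a weighted reconstruction into a binary graph keeps pairs with
weight **strictly** greater than `theta` — one rule, applied everywhere; a
"at least 0.5" reading is recovered at any `theta` just below 0.5.

## Two distances and the error bound

`weighted_jaccard_distance()` is the plain weighted Jaccard
`1 - sum(min)/sum(max)` over node pairs. It reduces exactly to one minus the
Jaccard index on binary graphs and is the right summary when every pair
matters equally.

The reconstruction guarantee, however, is stated for the
**coverage-weighted** variant (`coverage_jaccard_distance()`), in which each
pair is weighted by its incidence count — the Monte-Carlo estimate of its
probability of being covered by a uniformly random k-path. The reason is
visible in the proof sketch: with coverage weights the numerator telescopes
into `E||A_x - Ahat_x||_1 / (k(k-1))`, and because `2(k-1)` of the `k(k-1)`
ordered positions of every patch are on-chain — hence true edges — at least
a `2/k` fraction of the total coverage mass sits on edges, lower-bounding
the denominator. Dividing gives exactly

```
JD_cov(G, G_recons;W) <= E_x ||A_x - Ahat_x;W||_1 / (2(k-1)) .
```

The unweighted distance up-weights rarely covered pairs and can genuinely
exceed the right-hand side (we observed violations on heavy-tailed fixtures
at k = 3 that persist as the number of sampled paths grows), so
`reconstruction_error_bound()` reports the coverage-weighted distance for its
`satisfied` field and the unweighted one alongside for reference. On the
right-hand side, `mean_patch_l1_error()` measures the **raw** approximation
`W h` over all `k^2` entries — clipping and diagonal-skipping are averaging
conventions of the reconstruction, not part of the patch approximation
error; using the clipped, masked error would silently shrink the bound below
what it can guarantee. The test suite checks the inequality for 100 random
dictionaries across five fixture families at `k` in {3, 6, 11}, within two
Monte-Carlo standard errors of the bound estimate.

## Generators and corruption models

The generators implement the textbook constructions directly, with the
ambiguities resolved as follows:

* **ER / SBM** draw the binomial edge count and then a uniform subset of
  pairs — equal in law to independent pair flips, and much faster. With one
  community the SBM code path *is* the ER code path, so the specialization
  is exact, seed for seed.
* **WS** starts from the ring lattice (`n k / 2` edges) and rewires each
  edge independently with probability `p` by detaching one end (chosen with
  equal probability) and reattaching it to a uniformly random node,
  redrawing on self-loops and duplicates. Edge count is conserved exactly —
  `WS(100, 20, .)` always has 1000 edges.
* **BA** grows from `n0` isolated nodes; each arrival attaches `n0` edges to
  distinct existing nodes with probability proportional to degree. The first
  arrival faces an all-zero degree sequence, where "proportional to degree"
  is undefined; it attaches uniformly (and necessarily to all `n0` seeds).
  The edge count is exactly `n0 (n - n0)`.
* **-ER** removes `floor(|E_0|/2)` edges chosen uniformly from the
  complement `E_0` of a uniformly random spanning tree (Wilson's loop-erased
  random walk algorithm, tested for uniformity against a Kirchhoff count on
  an enumerable fixture), guaranteeing a connected observation. The floor
  makes odd counts deterministic.
* **+ER** exists in two printed variants under one name; both are
  implemented and explicitly tagged: `+ER-uniform` adds exactly
  `floor(|E|/2)` uniformly random nonadjacent pairs, `+ER-block` selects 5%
  of the nodes and fills absent pairs among them with probability 0.3.
* **+WS** plants a `WS(n0, k, p)` network on a random node subset (ring
  order = selection order). Generated edges already present in the graph are
  logged and excluded from the false-edge label set, so labels are never
  contradictory.

What the synthetic fixtures emulate — and what they do not: the SBM supplies
dense planted communities, BA supplies heavy-tailed degrees, WS supplies
local clustering. No single fixture combines all three the way real social
and PPI networks do, and the denoising experiment is sensitive to this: a
planted WS ring is itself *more* locally clustered than a sparse ER-like
community, in which case a structure-based detector rightly scores ring
edges as more plausible than the "true" edges, and the AUC drops below 0.5.
The packaged denoising fixture therefore uses within-community density 0.5
(the reference SBM configuration), making the planted ring the anomaly. A
passing test shows NDR separates planted noise from structured truth under
those conditions; it does not certify performance on networks whose true
structure is weaker than the corruption's.

## Evaluation protocol

For additive noise, the candidates are all observed edges ("confidence the
edge is true"; an anomaly-detection reading is `1 - score`). For subtractive
noise, classifying all nonedges would be inflated by the vast number of
pairs between low-degree nodes, so negatives are sampled without
replacement with probability proportional to the product of the endpoint
degrees in the observed graph, in equal number to the removed edges. AUC is
the tie-corrected Mann-Whitney statistic (equal to the trapezoidal area of
the threshold-sweep ROC); `select_threshold()` picks the
accuracy-maximizing `theta` on a 50% split and reports held-out accuracy,
precision, recall and F-score. Adamic-Adar terms from common neighbours of
degree 1 are skipped (the formula's `1/ln|N(z)|` is undefined there; such
neighbours can only arise in degenerate configurations). The spectral
baseline is the rank-d (default 32) truncated eigendecomposition of the
adjacency matrix, scored by the corresponding bilinear form.

## Problem sizes and limitations

The test fixtures use graphs of 50-300 nodes, minibatches of 100-300
patches, and reconstructions from a few thousand paths; these sizes already
exhibit every qualitative behaviour the package documents (exact sampler
uniformity, chain/clique/two-type dictionary recovery, bound satisfaction,
denoising separation) while keeping the default suite fast. The
implementation itself is vectorized (grouped categorical draws for walk
batches, coordinate descent across whole minibatches, keyed accumulation
for pair averaging) and handles thousands of nodes comfortably; it is not,
however, engineered for web-scale graphs, multigraphs, directed graphs or
continuous-weight inputs, and the MCMC sampling mode of the motif-sampling
literature is deliberately out of scope. Dictionary quality at very large
`k` (say, beyond ~30) is limited by path-rejection rates on sparse graphs,
which the sampler reports rather than hides.
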