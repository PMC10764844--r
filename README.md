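# netdict: latent-motif dictionaries for network reconstruction and denoising

Networks from systems biology and social systems carry structure at an
intermediate ("mesoscale") level — between single edges and whole-graph
summaries — that degree distributions and global clustering coefficients do
not capture. `netdict` studies this structure through *k-node mesoscale
patches*: the adjacency matrices `A_x` of subgraphs induced by uniformly
random **k-paths** `x = (x_1, ..., x_k)` (walks with distinct nodes). The
package is aimed at anyone who wants an interpretable low-rank summary of a
graph's connectivity patterns, or who needs to score edges of a possibly
corrupted network — e.g. flagging suspect interactions in a protein-protein
interaction (PPI) network or predicting missing links.

## The model

**Network dictionary learning (NDL).** Column-wise vectorized patches are
streamed in minibatches and factored by online nonnegative matrix
factorization,

    X  ≈  W H,     X ∈ {0,1}^(k² × N),  W ∈ [0,1]^(k² × r),  H ≥ 0,

so each patch is approximated by a nonnegative linear combination of `r`
**latent motifs** `L_1, ..., L_r` — k-node weighted networks obtained by
reshaping the columns of `W`. The fit maintains the aggregate statistics
`P_t = (1 − 1/t) P_{t−1} + (1/t) H Hᵀ/N` and
`Q_t = (1 − 1/t) Q_{t−1} + (1/t) X Hᵀ/N` and refits `W` by projected block
coordinate descent, so memory does not grow with the network.

**Network denoising and reconstruction (NDR).** Given any dictionary
(learned from the same or a different network), sample `T` k-paths, code
each patch as `Â_x = W ĥ`, and set the reconstructed weight `A_recons(u,v)`
to the mean of the reconstructed entries over every (path, position)
incidence of the pair `{u, v}`. Thresholding the weights at `θ` gives a
binary reconstruction; the weight of an edge of a corrupted network is a
confidence that the edge is real.

**Error bound.** The coverage-weighted Jaccard distance between a graph and
its weighted reconstruction satisfies

    JD(G, G_recons;W)  ≤  E_x ‖A_x − Â_x;W‖₁ / (2(k − 1)),

so a dictionary that approximates patches well is guaranteed to reconstruct
the network well (`reconstruction_error_bound()` estimates both sides).

Supporting machinery: exact (dynamic-programming) uniform k-walk/k-path
samplers with enumeration oracles; ER / Watts–Strogatz / Barabási–Albert /
stochastic-block-model generators; the −ER / +ER / +WS corruption models
with ground-truth labels (uniform spanning trees via Wilson's algorithm);
Jaccard / preferential-attachment / Adamic–Adar / spectral link-prediction
baselines; ROC/AUC and threshold-selection evaluation.

## Worked example

```r
library(netdict)

## a three-community stochastic block model
B <- matrix(0.01, 3, 3); diag(B) <- 0.5
g <- sbm_graph(c(60, 60, 60), B, seed = 1)
g
#> netdict_graph: 180 nodes, 2755 edges

## learn r = 16 latent motifs at scale k = 6
fit <- ndl(g, k = 6, r = 16, iterations = 20, minibatch = 300, seed = 1)
fit
#> Network dictionary (ndl fit)
#>   scale k = 6 , motifs r = 16
#>   learned over 20 minibatches of 300 k-paths
#>   mean patch L1 coding residual (last minibatch): 4.714

## reconstruct the network from its own dictionary
rec <- reconstruct(g, fit, n_paths = 20000, seed = 2)
reconstruction_accuracy(g, rec, theta = 0.4)
#> jaccard: 0.9282   rand: 0.9868

## the patch-error bound holds with room to spare
reconstruction_error_bound(g, fit, n_samples = 1000, seed = 3, check = TRUE, n_paths = 20000)
#> bound: 0.4772   achieved JD: 0.2039

## denoising: plant structured false edges, score the observed edges
noisy <- corrupt_add_ws(g, n0 = 30, k = 8, p = 0.3, seed = 4)
noisy
#> corruption_record [ +WS ]: 2755 true edges -> 2853 observed; 98 added, 0 removed
cand <- candidate_sets(noisy)
fit_obs <- ndl(noisy$observed, k = 6, r = 16, iterations = 15,
               minibatch = 250, seed = 5)
sp <- ndr_scores(noisy, fit_obs, cand$pairs, labels = cand$labels,
                 n_paths = 6000, seed = 6)
roc_auc(sp)$auc
#> 0.794   # vs 0.133 for preferential attachment on the same candidates
```

The reconstruction Jaccard accuracy of 0.93 says that after thresholding at
θ = 0.4 the reconstructed edge set agrees with the original on 93% of the
union of the two edge sets. In the denoising run the dictionary is learned
from the corrupted network only; an AUC of 0.79 means a uniformly chosen
true edge outranks a uniformly chosen planted edge ~79% of the time, while
preferential attachment is badly misled because the planted ring raises the
degrees of the nodes it touches.

A command-line front-end over the same functions ships in
`inst/scripts/netdict.R` with subcommands `generate`, `corrupt`, `sample`,
`learn`, `reconstruct` and `denoise`; every run writes a JSON manifest of
its resolved configuration and seed.

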