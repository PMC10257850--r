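# zinbclust

Joint dimensionality reduction and clustering of single-cell RNA-seq
count matrices in R.

Single-cell count data are high-dimensional, sparse, and inflated with
technical zeros (dropout). `zinbclust` fits a variational autoencoder
whose decoder models raw counts with a zero-inflated negative binomial
(ZINB) likelihood, regularizes the latent space with both a per-sample
Gaussian KL and a maximum-mean-discrepancy (MMD) penalty on the
aggregate posterior (the mutual-information-regularized VAE objective),
and then fine-tunes the embedding jointly with a deep-embedded-clustering
head: Student-t soft assignments $q_{ij}$ to learnable centers $r_j$,

$$q_{ij} = \frac{(1 + \lVert z_i - r_j\rVert^2)^{-1}}
                {\sum_{j'} (1 + \lVert z_i - r_{j'}\rVert^2)^{-1}},
\qquad
\mathcal{L}_{\mathrm{cluster}} = KL(P \,\Vert\, Q),$$

where $P$ squares and renormalizes $Q$ with an inverse-frequency
correction. The minimized objective is

$$\mathcal L = \tfrac{1}{2c}\,\mathrm{NLL}_{\mathrm{ZINB}}
 + (1-\alpha)\, D_{KL}\!\left(q_\phi(z\mid x)\,\Vert\, p(z)\right)
 + (\alpha+\lambda-1)\,\mathrm{MMD}\!\left(q_\phi(z), p(z)\right)
 + \gamma\, KL(P \Vert Q).$$

The package also ships the standard preprocessing pipeline (detection
filtering, log1p, top-500-variance gene selection, per-cell centering),
clustering metrics (ARI, NMI, silhouette, Calinski–Harabasz, K-NN
preservation, stability CV), readers/writers for 10x-style Matrix Market
and dense CSV/TSV matrices, and synthetic benchmark generators, so the
entire pipeline runs and is tested without external data. The encoder,
decoder, analytic backpropagation and Adam optimizer are implemented in
the package (base R matrix algebra with two C++ kernels); see the
methods vignette (`vignettes/zinbclust-methods.Rmd`) for the model,
parameter meanings and design decisions.

## Worked example

Simulate counts with three planted cell populations, fit the model, and
evaluate recovery:

```r
library(zinbclust)

sim <- simulate_zinb_counts(zinb_sim_config(), seed = 11)  # 300 x 1000
dim(sim$counts)
#> [1]  300 1000

fit <- zinbclust(sim$counts, k = 3,
                 pretrain_epochs = 100, finetune_epochs = 100, seed = 5)
fit
#> Deep embedded clustering fit (ZINB variational autoencoder)
#>   cells: 300, latent dim: 10, clusters: 3
#>   cluster sizes: 100, 100, 100
#>   final loss: 806.8902 (clustering KL 0.09902)

ari(sim$labels, fit$cluster)
#> [1] 1
```

The printed loss is the per-cell objective (ZINB negative log-likelihood
summed over the 500 selected genes, plus the latent regularizers); the
clustering KL is the per-cell divergence between the sharpened target and
the current soft assignments — small and shrinking means the head has
settled. An ARI of 1 against the planted labels is perfect recovery of
the three populations. The fitted object supports `summary()`, `coef()`
(cluster centers), `fitted()` (soft assignments), `predict()` (embed or
classify new cells) and `plot()` (latent PCA colored by cluster).

A command-line interface over the same functions is installed at
`inst/cli/zinbclust.R` (subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `run`), and `run_pipeline()` executes the whole workflow from
a YAML configuration, writing embedding, labels, per-epoch losses,
metrics JSON, config snapshot and log to an output directory.

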