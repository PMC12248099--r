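# fabgene

Embedding-informed frequentist and Bayesian (FAB) hypothesis tests for
genomics screens.

## The problem

Modern genomics screens test hypotheses in very high dimension: does a
perturbation shift a p-dimensional expression profile at all, does a drug's
viability pattern across cell lines relate to baseline expression of
hundreds of genes, which of K gene knockouts change a dependency score.
Classical tests (Hotelling's T², the global F-test, the two-sided t-test)
spread their power uniformly over all directions of the parameter space and
are badly underpowered when p approaches or exceeds the sample size.

Biological signals, however, are not uniform in gene space: they
concentrate near low-dimensional subspaces determined by how genes relate
to each other. Text-derived gene embeddings — numerical vectors produced by
large language models from gene descriptions — encode a general-purpose
notion of gene-gene similarity, and the principal subspace of an embedding
matrix `E` (the span of its top left singular vectors) turns out to capture
a disproportionate share of real biological signal vectors.

`fabgene` turns that observation into tests. Each test is derived as the
Neyman–Pearson likelihood ratio of the data's marginal density under a
*spiked Gaussian prior*

```
theta ~ N_p(0,  nu * E E' + gamma * I_p)
```

against the null density, so it is Bayes-optimal on average over signals
near the embedding subspace — while its rejection threshold is computed
under the exact frequentist null, so the level is controlled *whether or
not the embedding is informative*.

## The tests

**Two-sample mean test** (`fab_two_sample`). For samples
`x_i1 ~ N_p(mu1, Sigma)`, `x_i2 ~ N_p(mu2, Sigma)` and
`y = x̄1 − x̄2`, the oracle FAB statistic is the log likelihood ratio
`log N(y; 0, ηΣ + Ψ) − log N(y; 0, ηΣ)` with `η = 1/n1 + 1/n2`; its diffuse
limit (`nu → ∞`, `gamma → 0`) is the projection statistic
`T_LFAB = y' A (A' Σ A)^{-1} A' y`, `A = Σ^{-1} E`. The practical variant
replaces `Σ` by a whitening matrix `Σ̃` independent of the data and the
pooled covariance `S`:

```
T_AFAB = (n1 n2 / (n1+n2)) * y' Ã (Ã' S Ã)^{-1} Ã' y ,   Ã = Σ̃^{-1} E,
((n1+n2−d−1) / (d (n1+n2−2))) * T_AFAB  ~  F(d, n1+n2−d−1)   under H,
```

an embedding-projected Hotelling test with an *exact* F null. `Σ̃ = I`
gives the naive variant; the split-sample variant spends a fraction
`1 − r` of each sample on a shrinkage estimate
`Σ̃ = S̃ + p/(10 n_held) I`, which can add power when `Σ` is nearly
low-rank. A random-projection baseline (Gaussian `p × d` projection) is
included for comparison.

**Linear-hypothesis F-test** (`fab_ftest`). For viability scores
`x ~ N_n(G theta, σ² I)` with expression design `G`, the self-normalized
profile `y = x/‖x‖` is uniform on the sphere under `H: theta = 0`, and the
FAB statistic is `−n log( y' (G Ψ G' + σ̃² I)^{-1} y )` with a Monte Carlo
null on the sphere. Its diffuse limit is exactly the classical global
F-test of `x` on the reduced `n × d` design `G E` with `(d, n−d)` degrees
of freedom — usable even when `n ≤ p` defeats the classical F-test.

**Scalar FAB t-tests** (`fab_ttest`). For per-gene difference scores
`y ~ N_K(theta, η diag(σ²_1..σ²_K))`, gene k's prior moments `(m_k, v_k)`
are the Gaussian conditional mean and variance of `theta_k` given the
*other* genes' scores under the spiked prior — information borrowed across
genes through the embedding, never from gene k itself. The p-value
`p = 1 − | G_ν(t + b) − G_ν(−t) |`, with `t` the usual t score and
`b = 2 m_k σ̃ √η / v_k`, is exactly Uniform(0,1) under the null and reduces
exactly to the classical two-sided p-value when `b = 0`.

The package also provides the alignment diagnostic
(`embedding_alignment`: the profile `α_k = ‖U_{1:k}' y‖²/‖y‖²` against its
Haar-rotation null band), the simulation harness (`power_study` and the
generators behind it), Benjamini–Hochberg utilities, and delimited-text
readers. A thin command-line front end lives at `inst/scripts/fabgene`.

## Worked example

```r
library(fabgene)
set.seed(1)
p <- 100; d <- 10; n1 <- 40; n2 <- 40
Sigma <- make_covariance(p, decay_power = 20, seed = 2)   # trace-50, fast decay
eb    <- make_embedding_basis(p, d, seed = 3)             # synthetic embedding
sig   <- make_signal(eb$U, gamma_noise = 1/3, seed = 4)   # unit signal near col(E)
dat   <- simulate_two_sample(Sigma, 0.6 * sig$delta, n1, n2, seed = 5)

fab_two_sample(dat$x1, dat$x2, eb$E, variant = "naive")
#> 	Naive AFAB two-sample test (d = 10, identity whitening)
#> data:  dat$x1 vs dat$x2
#> T_AFAB = 35.446, df_num = 10, df_den = 69, p-value = 0.002351

fab_two_sample(dat$x1, dat$x2, variant = "rp", d = d, seed = 6)
#> 	Random-projection Hotelling test (d = 10)
#> data:  dat$x1 vs dat$x2
#> T_RP = 13.114, df_num = 10, df_den = 69, p-value = 0.3325
```

The same dataset, the same projection dimension: the embedding-guided test
rejects (p ≈ 0.002) because the mean shift lies near the embedding
subspace, while a random projection misses it (p ≈ 0.33). The diagnostic
shows why — the signal's alignment profile escapes the Haar null band:

```r
embedding_alignment(eb$E, sig$delta, n_reps = 100, seed = 7, standardize = FALSE)
#> Embedding-alignment diagnostic (p = 100 )
#>   k =    1: alignment 0.001  null band [0.000, 0.051]
#>   k =    5: alignment 0.128  null band [0.012, 0.127]
#>   k =   10: alignment 0.379  null band [0.034, 0.208]
#>   k =   50: alignment 0.614  null band [0.380, 0.630]
#>   k =  100: alignment 1.000  null band [1.000, 1.000]
```

At `k = d = 10` the signal carries 38% of its norm in the 10-dimensional
embedding subspace, against ~10% (band up to 21%) for a random rotation.

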