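---
title: "Embedding-informed FAB testing: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-informed FAB testing: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabgene)
```

# The FAB principle

All tests in this package follow one construction. To test `H: theta = 0`
with data density `p_theta(y)`, pick a prior `pi(theta)` expressing where
alternatives are believed to live, and reject when the marginal-vs-null
likelihood ratio `p_pi(y) / p_0(y)` exceeds its `1 - alpha` quantile *under
the null*. By the Neyman–Pearson lemma this maximizes power averaged over
`pi` among all level-`alpha` tests; because the threshold is a null
quantile, the level holds exactly even if the prior is useless. The prior
here is always the spiked Gaussian

$$\theta \sim N_p(0,\; \nu E E^\top + \gamma I_p),$$

whose mass concentrates near the column space of a gene-embedding matrix
`E` as `nu / gamma` grows. `nu` and `gamma` are in squared units of the
effect being tested; `nu` weights the d-dimensional embedding component,
`gamma` keeps the prior full-rank (and the matrix invertible), and only
their ratio matters for where power is concentrated.

# The two-sample family

For `y = x̄1 − x̄2` with common covariance `Sigma`, the oracle statistic
(`t_fab_oracle`) is the exact log ratio
`log N(y; 0, ηΣ + Ψ) − log N(y; 0, ηΣ)`, `η = 1/n1 + 1/n2`. Its null law is
`0.5 * Σ_j w_j χ²_1(j) + c` with weights `w_j = 1/(η λ_j + 1)`, `λ_j` the
eigenvalues of `Σ^{1/2} Ψ^{-1} Σ^{1/2}` — a weighted chi-square whose
quantiles we take by Monte Carlo (`oracle_null_quantile`). The quadratic
form `y'[(ηΣ)^{-1} − (ηΣ+Ψ)^{-1}]y` is exposed separately
(`t_fab_quadratic`); the two are affinely related (log ratio = quadratic/2
plus a data-free constant), so either induces the same test. We made the
log-ratio the canonical form because it is unambiguous about leading
constants; the package's tests verify the affine relation and the
weighted-chi-square law directly.

Letting `gamma -> 0` and `nu -> Inf` puts all prior mass on the embedding
subspace and yields the projection statistic
`T_LFAB = y' A (A' Σ A)^{-1} A' y`, `A = Σ^{-1}E`, which depends on `E`
only through its column space. Replacing the unknown `Σ` inside the
projection by a whitening matrix `Σ̃` chosen independently of the data, and
the outer `Σ` by the pooled sample covariance `S`, gives the practical
statistic `T_AFAB` — a Hotelling T² computed on the d-dimensional
projected data, hence the *exact* scaled-F null
`((n1+n2−d−1)/(d(n1+n2−2))) T ~ F(d, n1+n2−d−1)`. The whitening matrix
only moves power: `Σ̃ = I` (naive) is always valid, while whitening toward
the true `Σ` is provably at least as powerful for signals in `col(E)` —
the package checks this ordering by paired simulation.

**Split-sample variant.** To get a data-driven `Σ̃` without breaking
independence, a seeded shuffle assigns the first `ceiling(r * n_j)`
observations of each sample to `(y, S)` and the remainder to
`Σ̃ = S̃ + p/(10 n_held) I`. The ceiling convention makes `r = 0.66`,
`n = 50` a 33/17 split; the same test subset serves both `y` and `S`. The
ridge keeps `Σ̃` positive definite when `p` exceeds the held-out count. If
a held-out sample has fewer than two rows, `S̃` uses the other sample
alone; with no usable held-out rows the whitening degenerates to the ridge
alone, with a warning.

**Screens with a single treated profile.** When one sample has one row
(the perturbation-screen convention), `S` comes from the other sample
alone with divisor `n − 1`, and the F degrees of freedom use the effective
total `n1 + n2`; with `n2 = 1` these reduce to `(d, n1 − d)`, consistent
with the Wishart degrees of freedom of the control-only covariance.

**Numerical choices.** Every SPD solve symmetrizes and tries Cholesky
first, falling back to an eigen-decomposition with eigenvalue floor 1e-12
and a warning. The fast-decay simulated covariances (eigenvalue ratio
1e20) are numerically PSD only; the sampler therefore uses an eigen square
root with flooring at zero when Cholesky refuses. Singular projected
covariances (`A' S A`) raise an error naming `d` and the available degrees
of freedom rather than returning a garbage statistic.

# The linear F-test

For `x ~ N_n(G theta, σ² I)`, inference is based on the self-normalized
profile `y = x/‖x‖`, uniform on the sphere under the null for any `σ²` —
this is what makes every statistic in the module scale-invariant. The
finite-prior statistic `−n log(y'(GΨG' + σ̃²I)^{-1} y)` needs a point-mass
value `σ̃²`; since the null is the uniform sphere regardless, `σ̃²` affects
only power. We default it to `var(x)`, a reasonable magnitude match, and
document that the choice is heuristic. The Monte Carlo null simulates
standard normal vectors, normalizes, and evaluates the statistic
(n_mc = 10000 by default, seed required); Monte Carlo p-values are
reported as `(1 + #{null ≥ obs})/(1 + n_mc)` so they are never zero.

The diffuse limit is the classical global F-test on the reduced design
`G E` with `(d, n−d)` degrees of freedom — exact, Monte-Carlo-free, and
free of `(nu, gamma, σ̃²)`, which is why `mode = "limit"` is the default.
No intercept is added anywhere (the sampling model has none); a `center`
flag mean-centers `x` and the columns of `G` for users whose data need it.
An exact fit (zero residual) is reported as `p = 0` with an unbounded
statistic and a method-label flag rather than an error.

# The scalar FAB t-tests

Difference scores condense replicate matrices to
`y ~ N_K(theta, η diag(σ²))`. Gene k's prior moments are the conditional
mean and variance of `theta_k` given `y_{−k}` under the joint spiked-prior
model — computed for all genes from one Cholesky inverse of `(Ψ + ηD)`
followed by closed-form submatrix-inverse downdates, O(K) per gene after
one O(K³) factorization. The leave-one-out structure is the point: since
`(m_k, v_k)` and the error-sd estimate `σ̃ = sqrt(mean(σ̂²_{−k}))` never
touch gene k's own data, the per-gene null distribution is untouched.

The p-value is `p = 1 − |G_ν(t + b) − G_ν(−t)|` with
`t = y_k/(σ̂_k √η)` and shift `b = 2 m_k σ̃ √η / v_k`. Two exact
properties pin this form down, and both are enforced by tests: (i) for any
`b` fixed independently of gene k, `P(p ≤ α) = α` exactly under the null —
the rejection region is `t ≥ t_hi` or `t ≤ −t_hi − b` with total null mass
`α` by the symmetry of the t distribution; (ii) `b = 0` recovers the
classical two-sided p-value exactly. The shift's scale comes from the
equal-likelihood-ratio endpoints of the Bayes-optimal acceptance interval,
which satisfy `z_lo + z_hi = −2 m · sd(y_k)/v`; we estimate `sd(y_k)` by
`σ̃ √η` with `σ̃` on the standard-deviation scale. Degrees of freedom are
`n1 + n2 − 2`, the only value consistent with the pooled `σ̂_k`.

`(nu, gamma)` can be supplied or selected by maximizing the Gaussian
marginal likelihood of `y` over a logarithmic grid (9 points over
`10^-2..10^2` for `nu`, `10^-3..10^1` for `gamma`), ties broken toward the
smaller, more conservative values. Selection uses the whole score vector;
strictly per-gene validity is guaranteed for fixed hyperparameters, and
the simulation tests confirm calibration is preserved in practice at the
panel sizes studied.

# The alignment diagnostic

`α_k = ‖U_{1:k}' y‖² / ‖y‖²` measures how much of a signal the first `k`
embedding principal axes capture; under a Haar-random rotation
`E[α_k] = k/p`, and the pointwise 2.5%/97.5% band over 100 Haar draws
(Gaussian-QR construction with the positive-diagonal sign convention) is
the reference display. Whether to standardize embedding columns before the
decomposition is exposed as a flag: standardization (the default) is the
conventional preprocessing for heterogeneous embedding coordinates, but
the raw-matrix subspace is also legitimate, and for well-behaved
embeddings the two differ little. Rank reduction returns principal scores
`U_d diag(s_d)` — the p × d object whose column space equals that of the
best rank-d approximation, which is all the downstream projection
statistics use. Singular-vector signs follow a largest-entry-positive
convention so results are platform-reproducible.

# The synthetic-data generators and what passing means

The generators reproduce the structure of the study conditions: covariance
eigenvalues are an equi-spaced sequence between 0.1 and 1 raised to the
20th (fast decay) or 5th (slow decay) power, trace-normalized to 50, with
Haar eigenvectors; embeddings are i.i.d. standard normal `p × d` matrices;
signals are `delta = v/‖v‖` with `v ~ N_p(Uz, γ_noise I)`, `z ~ N_d(0, I)`
(the mean is the subspace image `Uz`; noise levels 1, 2/3, 1/3 give
decreasing average distance to the subspace). The full-scale study uses
`p = 200`, `d = 10`, `n1 = n2 = 50`, 15 instances × 100 realizations; the
package's own test runs use a scaled-down version (`p = 60`, `d = 5`,
5 × 50, plus `p ≤ 50` calibration nulls) so the whole suite completes in
about a minute while exercising identical code paths. One embedding matrix
is fixed per study (a `redraw_embedding` flag redraws it per instance);
instance `i` of each cell is seeded as a deterministic offset of the base
seed so any cell can be reproduced in isolation.

These generators are Gaussian, homoscedastic, and exactly spiked; real
screen data are none of those things (counts, batch structure, heavy
tails, non-Gaussian covariance spectra). Passing calibration here
certifies the distributional mathematics — exact F nulls, uniform
p-values, limit identities — not robustness to real-data violations. The
practical tests' level depends only on Gaussianity of the profiles and
independence of the whitening matrix, which is why those two assumptions
get the direct Monte Carlo checks.

# Design decisions taken where the design was open

* **Canonical oracle form.** The log likelihood ratio, not a particular
  quadratic-form rendering, is the implemented statistic; both are
  exported and their affine equivalence is tested, so the induced decision
  rule is unambiguous.
* **Modelling-idiom surface.** Test results are base R `htest` objects
  (printable, familiar); building blocks are plain functions so every
  intermediate quantity is testable in isolation.
* **Seeding.** Every stochastic function takes an explicit `seed` and
  restores the caller's RNG state, making all simulation tables pure
  functions of their seeds.
* **Split rounding.** `ceiling(r n)` to the test set; rounding is not
  dictated by the formulas, and the ceiling keeps the test set no smaller
  than intended.
* **Hyperparameter defaults.** `nu = 1, gamma = 1e-4` for the Monte Carlo
  F-test (near-diffuse), marginal-likelihood selection for the t panel,
  and the limiting (parameter-free) modes as defaults wherever they exist.
* **BH only.** Benjamini–Hochberg is the only multiplicity adjustment
  offered, computed on non-missing p-values with the multiplicity equal to
  their count.

# Known limitations

* Gaussian sampling models throughout; no permutation or rank-based
  fallbacks.
* The adaptive t-panel selection shares the score vector across genes;
  fully data-split hyperparameter selection is not implemented.
* The split-sample variant requires at least one held-out observation per
  sample and at least two in one of them for a data-driven `Σ̃`.
* `prior_moments` factorizes a K × K matrix; panels beyond a few thousand
  genes would want the low-rank (Woodbury) route, which is not implemented
  because the target panels are small.
* The alignment diagnostic completes rectangular bases to square ones via
  QR, so profile entries beyond `min(p, D)` reflect arbitrary orthogonal
  completion directions (the profile is still exact as a function of the
  completed basis).
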