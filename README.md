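# zippca

Zero-inflated probabilistic PCA for denoising microbiome count data.

Microbiome sequencing produces sample-by-taxon count matrices that are
sparse (often 40–90% zeros), overdispersed, and distorted by library sizes
that vary over orders of magnitude. Some zeros reflect true absence,
others only limited sequencing depth. `zippca` is for researchers who want
to remove these technical artifacts *model-wise* — before ordination,
diversity estimation, or differential-abundance (DA) testing — rather than
by rarefying or ad-hoc scaling.

## The model

Counts follow a zero-inflated negative binomial (or Poisson) latent factor
model:

```
z_ij ~ Bern(eta_ij),            logit(eta_ij) = c_i + tau_j
f_i  ~ N_k(0, I)
log mu_ij = alpha_i0 + beta_0j + gamma_j v_i + f_i' beta_j
x_ij | z, f  =  0                     if z_ij = 1   (biological zero)
             ~  NB(mu_ij, phi_j)      if z_ij = 0   (variance mu + mu^2/phi)
```

`alpha_i0` absorbs library size, the rank-k term captures taxon
covariance, `gamma_j` is an optional per-taxon covariate (group) effect,
and `z_ij` separates biological from technical zeros. The model is fitted
by fast deterministic mean-field variational inference (diagonal Gaussian
posteriors for `f_i`, Bernoulli posteriors for `z_ij`), maximizing an
evidence lower bound by guarded block coordinate ascent with compiled
inner kernels. The fitted posterior yields:

* `denoised_matrix()` — the empirical-Bayes posterior mean of the latent
  signal `(1 - z_ij) exp(beta_0j + gamma_j v_i + f_i' beta_j)`, free of
  library-size and sampling noise;
* `composition_poi()` / `composition_nb()` — row-stochastic estimates of
  the underlying compositions (the NB variant corrects for
  overdispersion via the gamma–Poisson representation);
* `alpha_diversity()`, `compare_alpha()` — Shannon/Simpson indices and
  group comparisons;
* `ordinate()` — intrinsic (factor-score) or denoise-then-PCA/t-SNE
  ordination;
* `da_test()` — covariate-adjusted fit, denoise, `log2(1+x)`, per-taxon
  Welch t-tests, Benjamini–Hochberg FDR.

Synthetic benchmark scenarios (`simulate_zippca()`, scenarios M1–M6, and
`simulate_da()`, M7–M9) generate sparse, overdispersed, zero-inflated
counts with full ground truth, and `procrustes_error()`,
`projection_distance()`, `composition_errors()`, `recovery_errors()`
implement the standard evaluation criteria for factor recovery,
composition estimation, and data recovery.

## Worked example

```r
library(zippca)

sim <- trim_sim(simulate_zippca(sim_config("M1", n = 60, p = 30, k = 2, seed = 42)))
sim$counts
#> zippca count matrix: 60 samples x 30 taxa (40.2% zeros)

fit <- fit_zippca(sim$counts, fit_config(family = "zinb", k = 2,
                                         max_iter = 100, tol = 1e-5))
fit
#> ZIPPCA fit (zinb, k = 2): 60 x 30, ELBO -6278.885, 74 iterations

xhat <- denoised_matrix(fit)
round(rbind(raw      = recovery_errors(sim$signal, sim$counts$counts),
            denoised = recovery_errors(sim$signal, xhat)), 3)
#>          log_mse pearson wasserstein
#> raw        2.618   0.501       0.277
#> denoised   1.700   0.773       0.124
```

Denoising cuts the log-scale mean squared error against the true latent
signal from 2.62 to 1.70 and raises the mean taxon-wise Pearson
correlation from 0.50 to 0.77 — the observed counts are noisy, unevenly
scaled realizations of the signal, and the model strips both distortions.
The loadings are recovered up to rotation with a symmetric Procrustes
error of 0.144 (0 is perfect, 2 is the maximum). Compositions and
diversity follow directly:

```r
rho <- composition_nb(fit)
head(alpha_diversity(rho), 3)
#>   sample_id  shannon   simpson
#> 1        s1 2.541073 0.1204840
#> 2        s2 2.548964 0.1190133
#> 3        s3 2.518096 0.1318001

round(composition_errors(sim$composition, rho), 4)
#>   frobenius          kl shannon_mse simpson_mse
#>      1.2084      0.1493      0.0788      0.0032
```

A command-line interface wrapping the same functions ships in
`inst/exec/zippca` (subcommands `simulate`, `fit`, `denoise`, `compose`,
`alpha`, `ordinate`, `da`, `eval`).

See `vignettes/zippca-methods.Rmd` for the model, the variational bound,
identifiability conventions, generator defaults, and known limitations.

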