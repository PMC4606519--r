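# bayesbreg

Bayesian whole-genome regression under the **BayesB** model, with five
interchangeable MCMC kernels, a synthetic-data simulator, and
MCMC/prediction diagnostics.

## The problem

In genomic prediction the number of marker covariates far exceeds the
number of phenotyped individuals. BayesB handles this with a spike-and-slab
prior on each marker effect: writing the model with a data-augmented effect
$\alpha_j = \beta_j\,\delta_j$,

$$y_i = \mu + \sum_{j=1}^{k} X_{ij}\,\beta_j\,\delta_j + e_i,$$

$$\delta_j \sim \mathrm{Bernoulli}(1-\pi), \quad
\beta_j \mid \sigma^2_j \sim N(0, \sigma^2_j), \quad
\sigma^2_j \sim \nu_\beta S^2_\beta\,\chi^{-2}_{\nu_\beta}, \quad
\sigma^2_e \sim \nu_e S^2_e\,\chi^{-2}_{\nu_e},$$

so each effect is exactly zero with probability $\pi$ and scaled-$t$
otherwise ($\pi = 0$ recovers BayesA). Classically the effect and its
locus variance are updated jointly by Metropolis–Hastings with the prior
as proposal (100 cycles per locus), or by an "efficient" MH variant with a
0.5 point-mass proposal (5 cycles). The indicator augmentation makes all
full conditionals available in closed form, so plain Gibbs sampling works
too. This package implements all five kernels behind one interface:

| kind                | update of $(\delta_j,\beta_j,\sigma^2_j)$ |
|---------------------|--------------------------------------------|
| `single_site_gibbs` | each from its full conditional ($\delta_j$ given current $\beta_j$) |
| `joint_gibbs`       | $\delta_j$ with $\beta_j$ marginalised, then $\beta_j$ |
| `pseudo_gibbs`      | Carlin–Chib-style pseudo prior for excluded effects |
| `mh`                | MH, prior proposal, default 100 cycles/locus |
| `efficient_mh`      | MH, 0.5 point-mass proposal, default 5 cycles/locus |

All five target the same posterior; the Gibbs kernels are typically 2–3×
more effective-samples-per-second than the MH baselines. The hot sweep is
compiled (Rcpp); a pure-R reference implementation of every kernel walks
the identical RNG path and is used to validate it.

## Worked example

```r
library(bayesbreg)

# a synthetic cohort: 500 individuals, 200 markers, 5% QTL, h2 = 0.25
cfg <- sim_config(n_individuals = 500, n_markers = 200, pi_true = 0.95,
                  heritability = 0.25, seed = 7)
dat <- simulate_dataset(cfg)
train <- dat$split$train; test <- dat$split$test

G <- center_genotypes(train$raw)
hyper <- default_hyperparameters(train$y, G, pi = 0.95)
spec <- sampler_spec("joint_gibbs", chain_length = 10000, burn_in = 1000, seed = 1)
draws <- run_chain(G, train$y, hyper, spec)
draws
#> posterior_draws: joint_gibbs, 9000 stored of 10000 iterations (burn-in 1000, thin 1)
#>   200 markers; wall 4.59s; posterior mean mu 2.4650, sigma2_e 10.2059

# predict the held-out individuals (test set centred with TRAINING means)
G_test <- center_genotypes(test$raw, means = G$col_means)
report <- efficiency_report(draws, G_test, test$y, bv_test = test$bv)
report
#> efficiency_report [joint_gibbs]: ESS(sigma2_e) 6728 in 4.59s (1465.1/s)
#>   mean mu 2.4650, mean sigma2_e 10.2059, accuracy 0.515
```

Reading the numbers: the simulated intercept was 2.5 and the realised
residual variance 9.58, so the posterior means (2.465, 10.21) recover the
truth; 9,000 stored draws of $\sigma^2_e$ are worth ≈ 6,700 independent
samples; GEBV correlate 0.515 with held-out *phenotypes* (bounded by
$\sqrt{h^2}$-style noise) and 0.943 with the true breeding values. The
posterior inclusion frequencies single out the real QTL:

```r
head(sort(draws$delta_freq, decreasing = TRUE), 3)
#>  mrk_24  mrk_81 mrk_194
#>   1.000   1.000   0.995      # true effects: 1.401, -1.505, -1.097
```

Sampler correctness can be audited directly (Geweke joint-distribution
test, comparing prior simulation against kernel/data-regeneration
simulation):

```r
hy <- hyperparameters(pi = 0.5, nu_beta = 10, s2_beta = 1, nu_e = 10,
                      s2_e = 1, tau2 = 1)           # proper prior for mu
geweke_test("joint_gibbs", hy, n = 8, k = 2, n_samples = 50000)
```

## Command line

```sh
BIN=$(Rscript -e 'cat(system.file("exec", "bayesb", package = "bayesbreg"))')
Rscript $BIN simulate --n-individuals 200 --n-markers 50 --out-dir sim
Rscript $BIN run --genotypes sim/genotypes_train.tsv \
                 --phenotypes sim/phenotypes_train.tsv \
                 --sampler joint --chain-length 20000 --pi 0.9 --out-dir out
Rscript $BIN summarize --chain out/chain_joint.tsv \
                 --manifest out/run_manifest_joint.json --out-dir out
```

Every run writes a JSON manifest (config, seed, input checksums, version);
`run --manifest <file>` reproduces a chain byte-for-byte.

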