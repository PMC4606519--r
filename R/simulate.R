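#' Simulation configuration
#'
#' Generative settings for the synthetic genotype/phenotype generator used
#' to exercise the samplers.  Defaults describe the benchmark world: a
#' desk-scale cohort with a trait of heritability 0.25 and a sparse genetic
#' architecture (95% null markers), split roughly 81/19 into training and
#' testing (the 3206/3961 proportion of the reference setting).
#'
#' @param n_individuals number of individuals.
#' @param n_markers number of markers.
#' @param maf_low,maf_high minor-allele-frequency bounds in (0, 0.5].
#' @param pi_true proportion of null marker effects.
#' @param heritability target narrow-sense h2 in `[0, 1)`; realised exactly
#'   per dataset (residual variance set from the realised genetic variance).
#' @param mu_true intercept (trait units).
#' @param train_fraction proportion of individuals used for training.
#' @param s2_beta,nu_beta scale and degrees of freedom of the scaled-t from
#'   which non-null effects are drawn (matching the model's marginal prior).
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000, n_markers = 1000,
                       maf_low = 0.05, maf_high = 0.5, pi_true = 0.95,
                       heritability = 0.25, mu_true = 2.5,
                       train_fraction = 3206 / 3961, s2_beta = 1,
                       nu_beta = 4, seed = 1L) {
  stopifnot(n_individuals >= 0, n_markers >= 0,
            maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            pi_true >= 0, pi_true <= 1,
            heritability >= 0, heritability < 1,
            train_fraction > 0, train_fraction < 1,
            s2_beta > 0, nu_beta > 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 maf_low = maf_low, maf_high = maf_high,
                 pi_true = pi_true, heritability = heritability,
                 mu_true = mu_true, train_fraction = train_fraction,
                 s2_beta = s2_beta, nu_beta = nu_beta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate raw genotypes
#'
#' Per marker, an allele frequency is drawn uniformly on
#' `[maf_low, maf_high]` and genotype codes are Binomial(2, p), independent
#' across individuals and markers (no linkage disequilibrium).
#'
#' @param cfg a [sim_config()].
#' @return integer matrix of 0/1/2 codes with individual/marker dimnames.
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_individuals; k <- cfg$n_markers
  p <- stats::runif(k, cfg$maf_low, cfg$maf_high)
  raw <- matrix(stats::rbinom(n * k, 2L, rep(p, each = max(n, 1))), n, k)
  dimnames(raw) <- list(if (n > 0) paste0("ind_", seq_len(n)),
                        if (k > 0) paste0("mrk_", seq_len(k)))
  raw
}

#' Simulate marker effects from the model's mixture prior
#'
#' Each effect is 0 with probability `pi_true`, otherwise drawn from the
#' scaled-t implied by the hierarchy: `sigma2 ~ nu s2 / chisq(nu)`, then
#' `alpha ~ N(0, sigma2)`.
#'
#' @param cfg a [sim_config()].
#' @return numeric vector `alpha_true` of length `n_markers`.
#' @export
simulate_effects <- function(cfg) {
  k <- cfg$n_markers
  alpha <- numeric(k)
  nz <- stats::runif(k) >= cfg$pi_true
  if (any(nz)) {
    s2 <- draw_scaled_inv_chi2(cfg$nu_beta, cfg$s2_beta, n = sum(nz))
    alpha[nz] <- stats::rnorm(sum(nz), 0, sqrt(s2))
  }
  alpha
}

#' Simulate phenotypes at an exact target heritability
#'
#' Breeding values are `g = X_c alpha` on the centred genotypes; the
#' residual variance is set from the *realised* genetic variance,
#' `sigma2_e = var(g) (1 - h2) / h2`, so the realised heritability equals
#' the target exactly.  Degenerate cases (`var(g) = 0` or `h2 = 0`) fall
#' back to `sigma2_e = 1` with realised h2 = 0.
#'
#' @param raw raw genotype matrix (codes, not centred).
#' @param alpha_true marker effects.
#' @param cfg a [sim_config()].
#' @return list with `y` (named phenotype vector) and `truth` (class
#'   `sim_truth`: `alpha_true`, `sigma2_e_true`, `sigma2_g_realized`,
#'   `breeding_values`, `heritability_realized`).
#' @export
simulate_phenotypes <- function(raw, alpha_true, cfg) {
  if (ncol(raw) != length(alpha_true))
    stop("alpha_true length must match marker count")
  G <- center_genotypes(raw)
  g <- as.numeric(G$values %*% alpha_true)
  vg <- if (length(g) > 1) stats::var(g) else 0
  if (vg > 0 && cfg$heritability > 0) {
    s2e <- vg * (1 - cfg$heritability) / cfg$heritability
    h2r <- vg / (vg + s2e)
  } else {
    s2e <- 1
    h2r <- 0
  }
  n <- nrow(raw)
  y <- cfg$mu_true + g + stats::rnorm(n, 0, sqrt(s2e))
  names(y) <- rownames(raw)
  names(g) <- rownames(raw)
  truth <- structure(list(alpha_true = alpha_true, sigma2_e_true = s2e,
                          sigma2_g_realized = vg, breeding_values = g,
                          heritability_realized = h2r),
                     class = "sim_truth")
  list(y = y, truth = truth)
}

#' Random train/test split of a simulated dataset
#'
#' Individuals are partitioned uniformly at random without replacement;
#' both sides carry aligned genotype rows, phenotypes and breeding values.
#'
#' @param raw raw genotype matrix.
#' @param y phenotype vector.
#' @param truth a `sim_truth` (or `NULL`).
#' @param cfg a [sim_config()] (for `train_fraction`).
#' @return list with `train` and `test`, each holding `raw`, `y`, `bv`,
#'   `index`.
#' @export
train_test_split <- function(raw, y, truth, cfg) {
  n <- nrow(raw)
  n_train <- round(cfg$train_fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("degenerate partition: train_fraction leaves an empty side")
  idx <- sample.int(n, n_train)
  take <- function(ix) list(
    raw = raw[ix, , drop = FALSE],
    y = y[ix],
    bv = if (!is.null(truth)) truth$breeding_values[ix] else NULL,
    index = ix)
  list(train = take(sort(idx)), test = take(sort(setdiff(seq_len(n), idx))))
}

#' One-call synthetic dataset
#'
#' Seeds the RNG with `cfg$seed` and runs the full generator: genotypes,
#' effects, phenotypes, train/test split.
#'
#' @param cfg a [sim_config()].
#' @return list with `raw`, `y`, `truth`, `split`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  raw <- simulate_genotypes(cfg)
  alpha <- simulate_effects(cfg)
  ph <- simulate_phenotypes(raw, alpha, cfg)
  split <- train_test_split(raw, ph$y, ph$truth, cfg)
  list(raw = raw, y = ph$y, truth = ph$truth, split = split, cfg = cfg)
}
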