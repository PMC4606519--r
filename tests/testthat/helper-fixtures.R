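# Shared fixtures: everything is generated in code, no stored data.

# small polymorphic genotype matrix + centred container
make_G <- function(n, k, seed = 1, maf = 0.3) {
  set.seed(seed)
  repeat {
    raw <- matrix(rbinom(n * k, 2L, maf), n, k,
                  dimnames = list(paste0("ind_", seq_len(n)),
                                  paste0("mrk_", seq_len(k))))
    G <- center_genotypes(raw)
    if (!any(G$monomorphic)) return(list(raw = raw, G = G))
  }
}

# a ready-to-run tiny training problem
tiny_problem <- function(n = 40, k = 6, pi = 0.5, seed = 3) {
  gg <- make_G(n, k, seed = seed)
  set.seed(seed + 1000)
  y <- phenotypes(rnorm(n, 2, 1), rownames(gg$raw))
  hyper <- default_hyperparameters(y, gg$G, pi = pi)
  list(raw = gg$raw, G = gg$G, y = y, hyper = hyper)
}

# hand-built state with explicit residual (for conditional-draw tests)
make_state <- function(residual, mu = 0, beta = NULL, delta = NULL,
                       sigma2_j = NULL, sigma2_e = 1, k = 1) {
  structure(list(mu = mu,
                 beta = if (is.null(beta)) rep(0, k) else beta,
                 delta = if (is.null(delta)) rep(0L, k) else as.integer(delta),
                 sigma2_j = if (is.null(sigma2_j)) rep(1, k) else sigma2_j,
                 sigma2_e = sigma2_e,
                 residual = residual),
            class = "bayesb_state")
}

# brute-force probability that delta_j = 1 for explicit small vectors,
# evaluating d_j and exp(-w'w/2s2e) directly (single-site form)
bf_prob_single_site <- function(w, xj, beta, s2e, pi) {
  d_j <- exp(-sum((w - xj * beta)^2) / (2 * s2e))
  e0 <- exp(-sum(w^2) / (2 * s2e))
  (1 - pi) * d_j / ((1 - pi) * d_j + pi * e0)
}

# brute-force marginal probability via grid integration of the multivariate
# likelihood f(w | beta) f(beta | sigma2_j) over beta
bf_prob_joint <- function(w, xj, s2j, s2e, pi, grid_pts = 20001, width = 12) {
  sd_b <- sqrt(s2j)
  bg <- seq(-width * sd_b, width * sd_b, length.out = grid_pts)
  db <- bg[2] - bg[1]
  ll <- colSums(matrix(dnorm(rep(w, length(bg)),
                             outer(xj, bg), sqrt(s2e), log = TRUE),
                       nrow = length(w))) +
    dnorm(bg, 0, sd_b, log = TRUE)
  mx <- max(ll)
  h1 <- exp(mx) * sum(exp(ll - mx)) * db
  h0 <- prod(dnorm(w, 0, sqrt(s2e)))
  h1 * (1 - pi) / (h1 * (1 - pi) + h0 * pi)
}
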