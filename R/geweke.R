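#' Geweke joint-distribution test of a sampler kernel
#'
#' Correctness check for an MCMC transition kernel: draws of (parameters,
#' data) obtained by (a) prior-then-likelihood simulation and (b) a
#' successive-conditional simulator that alternates the transition kernel
#' with data regeneration must agree in distribution.  First and second
#' moments of `mu`, `sigma2_e` and the number of included markers are
#' compared by z-score, with the autocorrelation of route (b) absorbed into
#' an ESS-based standard error.
#'
#' The test needs a proper joint prior, so `hyper` must carry a finite
#' `tau2` (proper normal prior on the overall mean); the flat default would
#' make route (a) impossible.  Moment comparisons of `sigma2_e^2` require
#' reasonably light prior tails; degrees of freedom around 10 work well.
#'
#' @param kind sampler kind (see [sampler_spec()]).
#' @param hyper a [hyperparameters()] with finite `tau2`.
#' @param n,k individuals and markers of the toy dataset.
#' @param n_samples draws per route.
#' @param mh_cycles cycles for the MH kinds (defaults as in
#'   [sampler_spec()]).
#' @param seed RNG seed.
#' @return `data.frame` with one row per compared moment: `stat`,
#'   `mean_marginal`, `mean_successive`, `se`, `z`.
#' @export
geweke_test <- function(kind, hyper, n = 8, k = 2, n_samples = 50000,
                        mh_cycles = NULL, seed = 1L) {
  kind <- match.arg(kind, .sampler_kinds)
  if (is.infinite(hyper$tau2))
    stop("geweke_test needs a proper prior for mu (finite tau2)")
  if (is.null(mh_cycles))
    mh_cycles <- switch(kind, mh = 100L, efficient_mh = 5L, 1L)
  is_mh <- kind %in% c("mh", "efficient_mh")

  set.seed(seed)
  # polymorphic toy genotypes
  repeat {
    raw <- matrix(stats::rbinom(n * k, 2L, 0.4), n, k)
    G <- center_genotypes(raw)
    if (!any(G$monomorphic)) break
  }

  prior_draw <- function() {
    mu <- stats::rnorm(1, hyper$mu0, sqrt(hyper$tau2))
    s2e <- draw_scaled_inv_chi2(hyper$nu_e, hyper$s2_e)
    if (is_mh) {
      s2j <- ifelse(stats::runif(k) < hyper$pi, 0,
                    draw_scaled_inv_chi2(hyper$nu_beta, hyper$s2_beta, k))
      delta <- as.integer(s2j > 0)
      beta <- ifelse(delta == 1, stats::rnorm(k, 0, sqrt(pmax(s2j, 1e-300))),
                     0)
    } else {
      s2j <- draw_scaled_inv_chi2(hyper$nu_beta, hyper$s2_beta, k)
      delta <- as.integer(stats::runif(k) < 1 - hyper$pi)
      beta <- stats::rnorm(k, 0, sqrt(s2j))
    }
    list(mu = mu, beta = beta, delta = delta, s2j = s2j, s2e = s2e)
  }

  stats_of <- function(st)
    c(mu = st$mu, mu2 = st$mu^2, s2e = st$s2e, s2e2 = st$s2e^2,
      nincl = sum(st$delta), nincl2 = sum(st$delta)^2)

  # route (a): marginal-conditional (iid prior draws)
  A <- matrix(0, n_samples, 6)
  for (i in seq_len(n_samples)) A[i, ] <- stats_of(prior_draw())

  # route (b): successive-conditional (kernel + data regeneration)
  hp <- .hyper_plist(hyper)
  kcode <- .kind_code(kind)
  st <- prior_draw()
  B <- matrix(0, n_samples, 6)
  Xa <- G$values
  for (i in seq_len(n_samples)) {
    alpha <- st$beta * st$delta
    y <- st$mu + as.numeric(Xa %*% alpha) +
      stats::rnorm(n, 0, sqrt(st$s2e))
    sw <- .cpp_sweep(Xa, y, unname(G$xtx), unname(G$monomorphic), hp,
                     kcode, mh_cycles, FALSE, st$mu, st$beta, st$delta,
                     st$s2j, st$s2e)
    st <- list(mu = sw$mu, beta = sw$beta, delta = sw$delta,
               s2j = sw$sigma2_j, s2e = sw$sigma2_e)
    B[i, ] <- stats_of(st)
  }

  nm <- c("mu", "mu2", "sigma2_e", "sigma2_e2", "n_incl", "n_incl2")
  res <- lapply(1:6, function(s) {
    a <- A[, s]; b <- B[, s]
    se_a <- stats::sd(a) / sqrt(n_samples)
    se_b <- stats::sd(b) / sqrt(.ess_quiet(b))
    se <- sqrt(se_a^2 + se_b^2)
    data.frame(stat = nm[s], mean_marginal = mean(a),
               mean_successive = mean(b), se = se,
               z = (mean(a) - mean(b)) / se)
  })
  do.call(rbind, res)
}
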