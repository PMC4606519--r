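test_that("scaled inverse chi-square draws match their closed-form moments", {
  expect_error(draw_scaled_inv_chi2(-1, 1), "nu")
  expect_error(draw_scaled_inv_chi2(4, 0), "s2")
  set.seed(1)
  x <- draw_scaled_inv_chi2(10, 3, n = 2e5)
  # mean nu*s2/(nu-2) = 3.75; MC se via sd/sqrt(n)
  expect_lt(abs(mean(x) - 3.75), 3 * sd(x) / sqrt(length(x)))
  # quantile-transform oracle: median = nu*s2/median(chisq_nu)
  set.seed(2)
  y <- draw_scaled_inv_chi2(4, 1, n = 2e5)
  expect_equal(median(y), 4 / qchisq(0.5, 4), tolerance = 0.02)
})

test_that("draw_mu samples the exact conjugate full conditional", {
  # e_mu = [1,3], sigma2_e = 4 -> N(2, 2)
  st <- make_state(residual = c(1, 3), mu = 0, sigma2_e = 4)
  hy <- hyperparameters(pi = 0.5)
  set.seed(3)
  draws <- replicate(2e4, draw_mu(st, hy)$mu)
  expect_lt(abs(mean(draws) - 2), 4 * sqrt(2 / 2e4))
  expect_equal(var(draws), 2, tolerance = 0.05)
  # residual bookkeeping: residual shifts by the drawn mean
  set.seed(4)
  st2 <- draw_mu(st, hy)
  expect_equal(st2$residual, c(1, 3) - st2$mu)
  # proper-prior variant reduces to precision-weighted normal
  hyp <- hyperparameters(pi = 0.5, mu0 = 10, tau2 = 1e-12)
  set.seed(5)
  expect_equal(draw_mu(st, hyp)$mu, 10, tolerance = 1e-4)
})

test_that("draw_sigma2_e uses scale (nu_e s2_e + e'e)/(nu_e + n), df nu_e + n", {
  # hand case: nu_e = 4, s2_e = 1, n = 2, e'e = 6 -> draw = 10 / chisq(6)
  st <- make_state(residual = c(sqrt(3), sqrt(3)))
  hy <- hyperparameters(pi = 0.5, nu_e = 4, s2_e = 1)
  set.seed(6); a <- draw_sigma2_e(st, hy)$sigma2_e
  set.seed(6); b <- 10 / rchisq(1, 6)
  expect_equal(a, b)
  # n = 0 recovers the prior nu_e * s2_e / chisq(nu_e)
  st0 <- make_state(residual = numeric(0))
  set.seed(7); a0 <- draw_sigma2_e(st0, hy)$sigma2_e
  set.seed(7); b0 <- 4 / rchisq(1, 4)
  expect_equal(a0, b0)
})

test_that("draw_sigma2_j honours the mode contract", {
  hy <- hyperparameters(pi = 0.5, nu_beta = 4, s2_beta = 1)
  # nu_b = 4, s2_b = 1, beta = 2 -> scale (4+4)/5 = 1.6, df 5
  set.seed(8); a <- draw_sigma2_j(2, 1, hy, mode = "single_site")
  set.seed(8); b <- 8 / rchisq(1, 5)
  expect_equal(a, b)
  # joint mode uses the same law even when delta = 0 (beta is still defined)
  set.seed(9); a2 <- draw_sigma2_j(2, 0, hy, mode = "joint")
  set.seed(9); b2 <- 8 / rchisq(1, 5)
  expect_equal(a2, b2)
  # pseudo mode with delta = 0: prior recovery nu*s2/chisq(nu)
  set.seed(10); a3 <- draw_sigma2_j(2, 0, hy, mode = "pseudo")
  set.seed(10); b3 <- 4 / rchisq(1, 4)
  expect_equal(a3, b3)
})

test_that("draw_beta_given_delta targets N(rhs/c, s2e/c) or the prior", {
  # rhs = 2, xtx = 2, s2e = 1, s2j = 1 -> c = 3, N(2/3, 1/3)
  set.seed(11)
  x <- replicate(2e4, draw_beta_given_delta(2, 2, 1, 1, 1))
  expect_equal(mean(x), 2 / 3, tolerance = 0.02)
  expect_equal(var(x), 1 / 3, tolerance = 0.02)
  # excluded: prior draw N(0, s2j) regardless of rhs
  set.seed(12)
  y <- replicate(2e4, draw_beta_given_delta(100, 2, 4, 1, 0))
  expect_lt(abs(mean(y)), 4 * 2 / sqrt(2e4))
  expect_equal(var(y), 4, tolerance = 0.1)
  # large s2j: least-squares limit N(rhs/xtx, s2e/xtx)
  set.seed(13)
  z <- replicate(2e4, draw_beta_given_delta(2, 2, 1e12, 1, 1))
  expect_equal(mean(z), 1, tolerance = 0.02)
  expect_equal(var(z), 0.5, tolerance = 0.03)
})

test_that("single-site inclusion probability matches direct evaluation", {
  # boundary and ratio-free cases
  expect_identical(prob_delta1_single_site(5, 2, 1, 1, 0), 1)
  expect_identical(prob_delta1_single_site(5, 2, 1, 1, 1), 0)
  expect_equal(prob_delta1_single_site(5, 2, 0, 1, 0.3), 0.7)
  # hand case: beta 1, rhs 2, xtx 2, s2e 1, pi 0.5 -> 1/(1+e^-1)
  expect_equal(prob_delta1_single_site(2, 2, 1, 1, 0.5), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  # direct-evaluation oracle with explicit vectors, w = [1,-1], X = [1,-1]
  w <- c(1, -1); xj <- c(1, -1)
  expect_equal(prob_delta1_single_site(sum(xj * w), sum(xj^2), 1, 1, 0.5),
               bf_prob_single_site(w, xj, 1, 1, 0.5), tolerance = 1e-10)
})

test_that("univariate marginal likelihood matches density evaluation", {
  expect_error(log_marglik_univariate(1, 0, 1, 1, 1), "xtx")
  # sigma2_j = 0 collapses m1 onto m0
  expect_equal(log_marglik_univariate(3, 2, 0, 1.5, 1),
               log_marglik_univariate(3, 2, 7, 1.5, 0))
  # rhs 2, xtx 2, s2j 1, s2e 1: m1 = N(2; 0, 6), m0 = N(2; 0, 2)
  expect_equal(exp(log_marglik_univariate(2, 2, 1, 1, 1)),
               dnorm(2, 0, sqrt(6)), tolerance = 1e-12)
  expect_equal(exp(log_marglik_univariate(2, 2, 1, 1, 0)),
               dnorm(2, 0, sqrt(2)), tolerance = 1e-12)
  # closed form at the mode: rhs = 0
  expect_equal(log_marglik_univariate(0, 2, 1, 1, 0) -
                 log_marglik_univariate(0, 2, 1, 1, 1),
               0.5 * log((2 * 1 + 1) / 1), tolerance = 1e-12)
})

test_that("joint inclusion probability matches integration oracle", {
  expect_identical(prob_delta1_joint(3, 2, 1, 1, 0), 1)
  # sigma2_j = 0: m1 = m0 so probability is 1 - pi
  expect_equal(prob_delta1_joint(3, 2, 0, 1, 0.25), 0.75)
  # hand value ~ 0.5293
  expect_equal(prob_delta1_joint(2, 2, 1, 1, 0.5),
               dnorm(2, 0, sqrt(6)) /
                 (dnorm(2, 0, sqrt(6)) + dnorm(2, 0, sqrt(2))),
               tolerance = 1e-12)
  expect_equal(prob_delta1_joint(2, 2, 1, 1, 0.5), 0.5293, tolerance = 1e-4)
  # grid-integration oracle on explicit vectors
  set.seed(14)
  for (i in 1:5) {
    n <- sample(2:6, 1)
    xj <- rnorm(n); xj <- xj - mean(xj)
    w <- rnorm(n)
    s2j <- runif(1, 0.2, 2); s2e <- runif(1, 0.3, 2); pi <- runif(1, .1, .9)
    expect_equal(prob_delta1_joint(sum(xj * w), sum(xj^2), s2j, s2e, pi),
                 bf_prob_joint(w, xj, s2j, s2e, pi), tolerance = 1e-8)
  }
})

test_that("delta probabilities are monotone decreasing in pi", {
  pis <- seq(0, 1, by = 0.1)
  p_ss <- sapply(pis, function(p) prob_delta1_single_site(2, 2, 1, 1, p))
  p_j <- sapply(pis, function(p) prob_delta1_joint(2, 2, 1, 1, p))
  expect_true(all(diff(p_ss) <= 0))
  expect_true(all(diff(p_j) <= 0))
  expect_true(all(p_ss >= 0 & p_ss <= 1))
  expect_true(all(p_j >= 0 & p_j <= 1))
})

test_that("pseudo-prior parameters and probability behave as derived", {
  # hand case: rhs 3, xtx 2, lambda 1, s2e~ 1 -> mean 1, variance 1/3
  hy <- hyperparameters(pi = 0.5, pseudo_sigma2_e = 1, pseudo_sigma2_j = 1)
  ps <- pseudo_prior_params(3, 2, hy)
  expect_equal(ps$mean, 1)
  expect_equal(ps$variance, 1 / 3)
  # data-dominated limit
  ps2 <- pseudo_prior_params(3e9, 2e9, hy)
  expect_equal(ps2$mean, 1.5, tolerance = 1e-6)
  expect_lt(ps2$variance, 1e-8)
  # prior-mean defaults: nu = 4, s2 = 1 -> 2; requires nu > 2
  hyd <- hyperparameters(pi = 0.5, nu_beta = 4, s2_beta = 1, nu_e = 4, s2_e = 1)
  expect_equal(hyd$pseudo_sigma2_e, 2)
  expect_equal(hyd$pseudo_lambda, 1)
  hy2 <- hyperparameters(pi = 0.5, nu_beta = 2, nu_e = 2)
  expect_null(hy2$pseudo_sigma2_e)
  expect_error(pseudo_prior_params(1, 1, hy2), "pseudo-prior constants")
  # boundary and error cases
  expect_identical(prob_delta1_pseudo(2, 2, 1, 1, 1, 0, ps), 1)
  expect_error(prob_delta1_pseudo(2, 2, 1, 1, 1, 0.5,
                                  list(mean = 0, variance = -1)), "variance")
})

test_that("pseudo probability with exact constants equals the joint law", {
  # constants = current variances make the pseudo prior the exact full
  # conditional, and the inclusion law collapses onto the marginal one
  hy <- hyperparameters(pi = 0.5, pseudo_sigma2_e = 1, pseudo_sigma2_j = 1)
  ps <- pseudo_prior_params(2, 2, hy)  # mean 2/3, variance 1/3
  expect_equal(ps$mean, 2 / 3)
  expect_equal(prob_delta1_pseudo(2, 2, 1, 1, 1, 0.5, ps),
               prob_delta1_joint(2, 2, 1, 1, 0.5), tolerance = 1e-12)
  set.seed(15)
  for (i in 1:50) {
    rhs <- rnorm(1, 0, 3); xtx <- runif(1, 0.5, 10)
    s2j <- runif(1, 0.1, 3); s2e <- runif(1, 0.2, 3)
    pi <- runif(1); beta <- rnorm(1, 0, 2)
    hyx <- hyperparameters(pi = pi, pseudo_sigma2_e = s2e,
                           pseudo_sigma2_j = s2j)
    psx <- pseudo_prior_params(rhs, xtx, hyx)
    expect_equal(prob_delta1_pseudo(rhs, xtx, beta, s2j, s2e, pi, psx),
                 prob_delta1_joint(rhs, xtx, s2j, s2e, pi),
                 tolerance = 1e-12)
  }
})
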