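kinds <- c("single_site_gibbs", "joint_gibbs", "pseudo_gibbs", "mh",
           "efficient_mh")

test_that("sampler_spec validates and applies kind-specific defaults", {
  expect_equal(sampler_spec("mh", 100)$mh_cycles, 100L)
  expect_equal(sampler_spec("efficient_mh", 100)$mh_cycles, 5L)
  expect_equal(sampler_spec("joint_gibbs", 100)$burn_in, 10L)
  expect_error(sampler_spec("joint_gibbs", 100, burn_in = 100), "burn_in")
  expect_error(sampler_spec("joint_gibbs", 100, thin = 0), "thin")
  expect_error(sampler_spec("nope", 100), "arg")
})

test_that("same seed and spec give bit-identical chains", {
  p <- tiny_problem()
  sp <- sampler_spec("joint_gibbs", 300, seed = 42)
  a <- run_chain(p$G, p$y, p$hyper, sp)
  b <- run_chain(p$G, p$y, p$hyper, sp)
  expect_identical(a$mu, b$mu)
  expect_identical(a$alpha, b$alpha)
  expect_identical(a$sigma2_e, b$sigma2_e)
  # stored-row contract: floor((n_iter - burn_in)/thin)
  sp2 <- sampler_spec("joint_gibbs", 101, burn_in = 10, thin = 7, seed = 1)
  d <- run_chain(p$G, p$y, p$hyper, sp2)
  expect_equal(length(d$mu), (101 - 10) %/% 7)
  expect_equal(nrow(d$alpha), (101 - 10) %/% 7)
})

test_that("compiled and reference engines walk the same RNG path", {
  p <- tiny_problem(n = 30, k = 5, pi = 0.7, seed = 8)
  for (kind in kinds) {
    sp <- sampler_spec(kind, 150, burn_in = 30, seed = 99)
    a <- run_chain(p$G, p$y, p$hyper, sp, engine = "compiled")
    b <- run_chain(p$G, p$y, p$hyper, sp, engine = "reference")
    expect_lt(max(abs(a$mu - b$mu)), 1e-10)
    expect_lt(max(abs(a$alpha - b$alpha)), 1e-10)
    expect_lt(max(abs(a$sigma2_e - b$sigma2_e)), 1e-10)
    expect_equal(a$delta_freq, b$delta_freq)
  }
  # random-scan option stays in lockstep too
  spr <- sampler_spec("single_site_gibbs", 100, burn_in = 20, seed = 5,
                      random_scan = TRUE)
  a <- run_chain(p$G, p$y, p$hyper, spr, engine = "compiled")
  b <- run_chain(p$G, p$y, p$hyper, spr, engine = "reference")
  expect_lt(max(abs(a$alpha - b$alpha)), 1e-10)
})

test_that("at pi = 0 single-site and joint kernels are the same law (BayesA)", {
  p <- tiny_problem(n = 30, k = 5, pi = 0, seed = 2)
  a <- run_chain(p$G, p$y, p$hyper, sampler_spec("single_site_gibbs", 200, seed = 3))
  b <- run_chain(p$G, p$y, p$hyper, sampler_spec("joint_gibbs", 200, seed = 3))
  # both inclusion probabilities are exactly 1, so the RNG paths coincide
  expect_identical(a$alpha, b$alpha)
  expect_identical(a$sigma2_e, b$sigma2_e)
  expect_true(all(a$delta_freq == 1))
})

test_that("at pi = 1 no marker ever enters the model", {
  p <- tiny_problem(n = 30, k = 5, pi = 1, seed = 2)
  for (kind in c("single_site_gibbs", "joint_gibbs", "mh", "efficient_mh")) {
    d <- run_chain(p$G, p$y, p$hyper, sampler_spec(kind, 150, seed = 4))
    expect_true(all(d$alpha == 0))
    expect_true(all(d$delta_freq == 0))
  }
})

test_that("k = 0 reduces to the conjugate normal-mean model", {
  set.seed(20)
  n <- 50
  y <- rnorm(n, 3, 1)
  G0 <- center_genotypes(matrix(numeric(0), n, 0,
                                dimnames = list(paste0("i", 1:n), NULL)))
  hy <- hyperparameters(pi = 0.5, nu_e = 4, s2_e = 1)
  d <- run_chain(G0, y, hy, sampler_spec("joint_gibbs", 20000, seed = 6))
  # flat-prior posterior of mu integrates to mean ybar; check within MC error
  se <- sd(d$mu) / sqrt(effective_sample_size(d$mu))
  expect_lt(abs(mean(d$mu) - mean(y)), 4 * se)
  # sigma2_e posterior mean close to (nu_e s2_e + (n-1) var(y))/(nu_e + n - 2)
  closed <- (4 + sum((y - mean(y))^2)) / (4 + n - 1 - 2)
  se2 <- sd(d$sigma2_e) / sqrt(effective_sample_size(d$sigma2_e))
  expect_lt(abs(mean(d$sigma2_e) - closed), 5 * se2 + 0.02 * closed)
})

test_that("monomorphic markers are pinned out of the model", {
  set.seed(30)
  raw <- cbind(mono = rep(2L, 40),
               poly = rbinom(40, 2, 0.4))
  rownames(raw) <- paste0("i", 1:40)
  G <- center_genotypes(raw)
  y <- rnorm(40)
  hy <- default_hyperparameters(y, G, pi = 0.5)
  for (kind in c("single_site_gibbs", "mh")) {
    d <- run_chain(G, y, hy, sampler_spec(kind, 200, seed = 7))
    expect_equal(unname(d$delta_freq[["mono"]]), 0)
    expect_true(all(d$alpha[, "mono"] == 0))
  }
})

test_that("MH acceptance weights reproduce hand-computed ratios", {
  # plain MH, move 0 -> s = 1 at rhs 2, xtx 2, s2e 1: ratio m1/m0 > 1
  lw0 <- bayesbreg:::.log_mh_weight(0, 2, 2, 1, 0.5, efficient = FALSE)
  lw1 <- bayesbreg:::.log_mh_weight(1, 2, 2, 1, 0.5, efficient = FALSE)
  expect_equal(exp(lw1 - lw0), dnorm(2, 0, sqrt(6)) / dnorm(2, 0, sqrt(2)),
               tolerance = 1e-12)
  expect_gt(exp(lw1 - lw0), 1)  # acceptance probability would be 1
  # efficient MH at pi = 0.9: weight ratio (m1 * 0.1) / (m0 * 0.9) ~ 0.1250
  el0 <- bayesbreg:::.log_mh_weight(0, 2, 2, 1, 0.9, efficient = TRUE)
  el1 <- bayesbreg:::.log_mh_weight(1, 2, 2, 1, 0.9, efficient = TRUE)
  expect_equal(exp(el1 - el0),
               dnorm(2, 0, sqrt(6)) * 0.1 / (dnorm(2, 0, sqrt(2)) * 0.9),
               tolerance = 1e-12)
  expect_equal(exp(el1 - el0), 0.1250, tolerance = 1e-3)
  # at pi = 0.5 the efficient weights reduce to the plain ones
  expect_equal(bayesbreg:::.log_mh_weight(1, 2, 2, 1, 0.5, TRUE) -
                 bayesbreg:::.log_mh_weight(0, 2, 2, 1, 0.5, TRUE),
               lw1 - lw0, tolerance = 1e-12)
})

test_that("residual bookkeeping survives full sweeps of every kernel", {
  p <- tiny_problem(n = 25, k = 6, pi = 0.6, seed = 12)
  for (kind in kinds) {
    set.seed(33)
    st <- new_model_state(p$G, p$y, p$hyper)
    for (it in 1:20)
      st <- bayesbreg:::.sweep_reference(st, p$G, p$hyper, kind,
                                         if (kind == "mh") 100 else 5, FALSE)
    st <- rebuild_residual(st, p$G, p$y)
    expect_lt(attr(st, "drift"), 1e-6)
  }
})

test_that("run_chain validates its inputs", {
  p <- tiny_problem()
  expect_error(run_chain(p$G, p$y[-1], p$hyper,
                         sampler_spec("joint_gibbs", 100)), "does not match")
  expect_error(run_chain(p$G, p$y, p$hyper, list(kind = "mh")),
               "sampler_spec")
  hy2 <- hyperparameters(pi = 0.5, nu_beta = 2, nu_e = 2)
  expect_error(run_chain(p$G, p$y, hy2, sampler_spec("pseudo_gibbs", 100)),
               "pseudo")
})
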