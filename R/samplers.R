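.sampler_kinds <- c("single_site_gibbs", "joint_gibbs", "pseudo_gibbs",
                    "mh", "efficient_mh")

#' Sampler specification
#'
#' @param kind one of `"single_site_gibbs"`, `"joint_gibbs"`,
#'   `"pseudo_gibbs"`, `"mh"`, `"efficient_mh"`.
#' @param chain_length total iterations.
#' @param burn_in iterations discarded (default 10% of `chain_length`).
#' @param thin storage stride.
#' @param seed RNG seed for the run.
#' @param mh_cycles Metropolis-Hastings cycles per locus visit; defaults to
#'   100 for `"mh"`, 5 for `"efficient_mh"`, ignored by the Gibbs kinds.
#' @param random_scan visit loci in random order each iteration (default:
#'   fixed ascending order).
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(kind, chain_length, burn_in = chain_length %/% 10,
                         thin = 1L, seed = 1L, mh_cycles = NULL,
                         random_scan = FALSE) {
  kind <- match.arg(kind, .sampler_kinds)
  if (is.null(mh_cycles))
    mh_cycles <- switch(kind, mh = 100L, efficient_mh = 5L, 1L)
  chain_length <- as.integer(chain_length)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  mh_cycles <- as.integer(mh_cycles)
  if (chain_length < 1) stop("chain_length must be >= 1")
  if (burn_in < 0 || burn_in >= chain_length)
    stop("burn_in must satisfy 0 <= burn_in < chain_length")
  if (thin < 1) stop("thin must be >= 1")
  if (mh_cycles < 1) stop("mh_cycles must be >= 1")
  structure(list(kind = kind, chain_length = chain_length,
                 burn_in = burn_in, thin = thin, seed = as.integer(seed),
                 mh_cycles = mh_cycles, random_scan = isTRUE(random_scan)),
            class = "sampler_spec")
}

.kind_code <- function(kind) {
  match(kind, .sampler_kinds) - 1L
}

#' Run a BayesB MCMC chain
#'
#' Initialises the state (`mu = mean(y)`, `beta = delta = 0`,
#' `sigma2_j = s2_beta`, `sigma2_e = var(y)`), then each iteration sweeps
#' the overall mean, all loci with the kernel named in `spec`, and the
#' residual variance.  Post-burn-in draws of `mu`, `sigma2_e` and every
#' `alpha_j = beta_j delta_j` are stored at stride `thin`.  The run is fully
#' determined by `spec$seed`.
#'
#' The pseudo-prior kernel requires the pseudo constants to be set in
#' `hyper` (they default to the prior means when both `nu > 2`).
#'
#' @param G a [center_genotypes()] object.
#' @param y phenotype vector.
#' @param hyper a [hyperparameters()] object.
#' @param spec a [sampler_spec()].
#' @param engine `"compiled"` (default) runs the C++ core; `"reference"`
#'   runs the pure-R kernels.  Both consume the RNG identically and yield
#'   matching chains (asserted by the test suite).
#' @param rebuild_every rebuild the residual from scratch every this many
#'   iterations, guarding against floating-point drift (0 disables).
#' @return object of class `posterior_draws`: stored draws (`mu`,
#'   `sigma2_e`, `alpha` matrix), per-marker inclusion frequencies
#'   (`delta_freq`), stored iteration indices, wall-clock seconds, the
#'   final state, and the spec/hyper used.
#' @export
run_chain <- function(G, y, hyper, spec,
                      engine = c("compiled", "reference"),
                      rebuild_every = 1000L) {
  engine <- match.arg(engine)
  check_dims(G, y)
  if (!inherits(spec, "sampler_spec")) stop("`spec` must be a sampler_spec")
  if (!inherits(hyper, "bayesb_hyper"))
    stop("`hyper` must be a bayesb_hyper")
  if (spec$kind == "pseudo_gibbs" &&
      (is.null(hyper$pseudo_sigma2_e) || is.null(hyper$pseudo_lambda)))
    stop("pseudo_gibbs requires pseudo-prior constants (see ?hyperparameters)")
  y <- as.numeric(y)

  set.seed(spec$seed)
  init <- new_model_state(G, y, hyper)

  if (engine == "compiled") {
    out <- .cpp_run_chain(G$values, y, unname(G$xtx), unname(G$monomorphic),
                          .hyper_plist(hyper), .kind_code(spec$kind),
                          spec$mh_cycles, spec$chain_length, spec$burn_in,
                          spec$thin, spec$random_scan, init$mu, init$beta,
                          init$delta, init$sigma2_j, init$sigma2_e,
                          as.integer(rebuild_every))
    draws <- out
    final <- structure(out$final, class = "bayesb_state")
  } else {
    t0 <- proc.time()[["elapsed"]]
    state <- init
    n_store <- (spec$chain_length - spec$burn_in) %/% spec$thin
    k <- G$n_markers
    mu_st <- numeric(n_store); s2e_st <- numeric(n_store)
    alpha_st <- matrix(0, n_store, k)
    iter_st <- integer(n_store)
    dfreq <- numeric(k)
    max_drift <- 0
    s <- 0L
    for (it in seq_len(spec$chain_length)) {
      state <- .sweep_reference(state, G, hyper, spec$kind, spec$mh_cycles,
                                spec$random_scan)
      if (rebuild_every > 0 && it %% rebuild_every == 0) {
        state <- rebuild_residual(state, G, y)
        max_drift <- max(max_drift, attr(state, "drift"))
      }
      if (it > spec$burn_in && (it - spec$burn_in) %% spec$thin == 0 &&
          s < n_store) {
        s <- s + 1L
        mu_st[s] <- state$mu
        s2e_st[s] <- state$sigma2_e
        alpha_st[s, ] <- state$beta * as.numeric(state$delta)
        dfreq <- dfreq + as.numeric(state$delta)
        iter_st[s] <- it
      }
    }
    draws <- list(mu = mu_st, sigma2_e = s2e_st, alpha = alpha_st,
                  delta_freq = if (n_store > 0) dfreq / n_store else dfreq,
                  iterations = iter_st,
                  wall_seconds = proc.time()[["elapsed"]] - t0,
                  max_drift = max_drift)
    final <- state
  }

  colnames(draws$alpha) <- G$marker_ids
  names(draws$delta_freq) <- G$marker_ids
  structure(list(mu = draws$mu,
                 sigma2_e = draws$sigma2_e,
                 alpha = draws$alpha,
                 delta_freq = draws$delta_freq,
                 iterations = draws$iterations,
                 sampler = spec$kind,
                 chain_length = spec$chain_length,
                 burn_in = spec$burn_in,
                 thin = spec$thin,
                 seed = spec$seed,
                 wall_seconds = draws$wall_seconds,
                 max_drift = draws$max_drift,
                 engine = engine,
                 hyper = hyper,
                 spec = spec,
                 final_state = final,
                 marker_ids = G$marker_ids),
            class = "posterior_draws")
}

# flatten hyper for the C++ side (NULL pseudo constants pass through)
.hyper_plist <- function(hyper) {
  list(pi = hyper$pi, nu_beta = hyper$nu_beta, s2_beta = hyper$s2_beta,
       nu_e = hyper$nu_e, s2_e = hyper$s2_e,
       pseudo_sigma2_e = hyper$pseudo_sigma2_e,
       pseudo_lambda = hyper$pseudo_lambda,
       mu0 = hyper$mu0, tau2 = hyper$tau2)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %s, %d stored of %d iterations (burn-in %d, thin %d)\n",
              x$sampler, length(x$mu), x$chain_length, x$burn_in, x$thin))
  cat(sprintf("  %d markers; wall %.2fs; posterior mean mu %.4f, sigma2_e %.4f\n",
              ncol(x$alpha), x$wall_seconds, mean(x$mu), mean(x$sigma2_e)))
  invisible(x)
}
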