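# Reference (pure-R) locus-update kernels.  These are the readable,
# unit-testable definitions of the five transition kernels; run_chain()
# executes the same algorithms through the compiled core by default, and the
# test suite asserts that both implementations consume R's RNG stream
# identically and produce matching chains.

# shared finaliser: apply the residual update and store the new locus state
.apply_locus <- function(state, G, j, a_old, b_new, d_new, s2j_new) {
  a_new <- if (d_new == 1) b_new else 0
  state <- update_residual(state, G, j, a_old, a_new)
  state$beta[j] <- b_new
  state$delta[j] <- as.integer(d_new)
  state$sigma2_j[j] <- s2j_new
  state
}

# monomorphic marker: delta pinned to 0, Gibbs kinds refresh from priors
.update_locus_mono <- function(state, G, j, hyper, gibbs) {
  if (!gibbs) return(state)
  s2 <- draw_scaled_inv_chi2(hyper$nu_beta, hyper$s2_beta)
  b <- stats::rnorm(1, 0, sqrt(s2))
  state$sigma2_j[j] <- s2
  state$beta[j] <- b
  state$delta[j] <- 0L
  state
}

#' Single-site Gibbs update of one locus
#'
#' Draws, in order, `delta_j` from its full conditional (which uses the
#' current `beta_j`), `beta_j` given the new indicator, and `sigma2_j`;
#' the residual is updated for the change in `alpha_j = beta_j delta_j`.
#'
#' @param state a `bayesb_state`.
#' @param G genotype matrix.
#' @param j marker index.
#' @param hyper a `bayesb_hyper`.
#' @return updated state.
#' @export
update_locus_single_site <- function(state, G, j, hyper) {
  if (G$monomorphic[[j]])
    return(.update_locus_mono(state, G, j, hyper, gibbs = TRUE))
  a_old <- state$beta[j] * as.numeric(state$delta[j])
  rhs <- adjusted_rhs(state, G, j)
  xtx <- G$xtx[[j]]
  p1 <- prob_delta1_single_site(rhs, xtx, state$beta[j], state$sigma2_e,
                                hyper$pi)
  d_new <- as.integer(stats::runif(1) < p1)
  b_new <- draw_beta_given_delta(rhs, xtx, state$sigma2_j[j],
                                 state$sigma2_e, d_new)
  s2_new <- draw_sigma2_j(b_new, d_new, hyper, mode = "single_site")
  .apply_locus(state, G, j, a_old, b_new, d_new, s2_new)
}

#' Joint Gibbs update of one locus
#'
#' Draws `delta_j` from its marginal full conditional (the current `beta_j`
#' integrated out), then `beta_j` and `sigma2_j` as in the single-site
#' kernel.
#'
#' @inheritParams update_locus_single_site
#' @return updated state.
#' @export
update_locus_joint <- function(state, G, j, hyper) {
  if (G$monomorphic[[j]])
    return(.update_locus_mono(state, G, j, hyper, gibbs = TRUE))
  a_old <- state$beta[j] * as.numeric(state$delta[j])
  rhs <- adjusted_rhs(state, G, j)
  xtx <- G$xtx[[j]]
  p1 <- prob_delta1_joint(rhs, xtx, state$sigma2_j[j], state$sigma2_e,
                          hyper$pi)
  d_new <- as.integer(stats::runif(1) < p1)
  b_new <- draw_beta_given_delta(rhs, xtx, state$sigma2_j[j],
                                 state$sigma2_e, d_new)
  s2_new <- draw_sigma2_j(b_new, d_new, hyper, mode = "joint")
  .apply_locus(state, G, j, a_old, b_new, d_new, s2_new)
}

#' Pseudo-prior Gibbs update of one locus
#'
#' Draws `delta_j` from its full conditional under the pseudo prior for the
#' excluded effect, then `beta_j` (from the exact full conditional when
#' included, from the pseudo prior when excluded -- the latter never touches
#' the residual since `alpha_j = 0`), then `sigma2_j` (prior draw when
#' excluded).
#'
#' @inheritParams update_locus_single_site
#' @return updated state.
#' @export
update_locus_pseudo <- function(state, G, j, hyper) {
  if (G$monomorphic[[j]])
    return(.update_locus_mono(state, G, j, hyper, gibbs = TRUE))
  a_old <- state$beta[j] * as.numeric(state$delta[j])
  rhs <- adjusted_rhs(state, G, j)
  xtx <- G$xtx[[j]]
  ps <- pseudo_prior_params(rhs, xtx, hyper)
  p1 <- prob_delta1_pseudo(rhs, xtx, state$beta[j], state$sigma2_j[j],
                           state$sigma2_e, hyper$pi, ps)
  d_new <- as.integer(stats::runif(1) < p1)
  b_new <- if (d_new == 1) {
    draw_beta_given_delta(rhs, xtx, state$sigma2_j[j], state$sigma2_e, 1)
  } else {
    stats::rnorm(1, ps$mean, sqrt(ps$variance))
  }
  s2_new <- draw_sigma2_j(b_new, d_new, hyper, mode = "pseudo")
  .apply_locus(state, G, j, a_old, b_new, d_new, s2_new)
}

# shared MH machinery: log target weight of a locus-variance state s
# (s = 0 is the point mass).  For the prior-proposal kernel the prior
# cancels against the proposal and only the marginal likelihood remains;
# for the efficient kernel the prior point masses survive (the continuous
# shape still cancels) and the symmetric 0.5/0.5 proposal drops out.
.log_mh_weight <- function(s, rhs, xtx, sigma2_e, pi, efficient) {
  lm <- if (s > 0) log_marglik_univariate(rhs, xtx, s, sigma2_e, 1)
        else log_marglik_univariate(rhs, xtx, 0, sigma2_e, 0)
  if (!efficient) return(lm)
  lm + if (s > 0) log1p(-pi) else log(pi)
}

.update_locus_mh <- function(state, G, j, hyper, cycles, efficient) {
  if (G$monomorphic[[j]]) return(state)  # MH kinds skip pinned markers
  a_old <- state$beta[j] * as.numeric(state$delta[j])
  rhs <- adjusted_rhs(state, G, j)
  xtx <- G$xtx[[j]]
  s_cur <- if (state$delta[j] == 1) state$sigma2_j[j] else 0
  lw_cur <- .log_mh_weight(s_cur, rhs, xtx, state$sigma2_e, hyper$pi,
                           efficient)
  zero_p <- if (efficient) 0.5 else hyper$pi
  for (cyc in seq_len(cycles)) {
    u <- stats::runif(1)
    s_prop <- if (u < zero_p) 0
              else draw_scaled_inv_chi2(hyper$nu_beta, hyper$s2_beta)
    lw_prop <- .log_mh_weight(s_prop, rhs, xtx, state$sigma2_e, hyper$pi,
                              efficient)
    u2 <- stats::runif(1)  # always consumed, for RNG lockstep
    accept <- if (lw_cur == -Inf) lw_prop > -Inf
              else if (lw_prop == -Inf) FALSE
              else log(u2) < lw_prop - lw_cur
    if (accept) { s_cur <- s_prop; lw_cur <- lw_prop }
  }
  if (s_cur > 0) {
    b_new <- draw_beta_given_delta(rhs, xtx, s_cur, state$sigma2_e, 1)
    .apply_locus(state, G, j, a_old, b_new, 1L, s_cur)
  } else {
    .apply_locus(state, G, j, a_old, 0, 0L, 0)
  }
}

#' Metropolis-Hastings update of one locus (prior proposal)
#'
#' The classic BayesB locus update: the locus variance (0 = point mass) is
#' proposed from its mixture prior for `cycles` cycles; because proposal and
#' prior coincide, the acceptance ratio reduces to the ratio of marginal
#' likelihoods of the sufficient statistic.  After the last cycle the effect
#' is drawn once from its full conditional (or set to 0).
#'
#' @inheritParams update_locus_single_site
#' @param cycles Metropolis-Hastings cycles per locus visit (classic
#'   default 100).
#' @return updated state.
#' @export
update_locus_mh <- function(state, G, j, hyper, cycles = 100) {
  .update_locus_mh(state, G, j, hyper, cycles, efficient = FALSE)
}

#' Efficient Metropolis-Hastings update of one locus
#'
#' As [update_locus_mh()] but the proposal puts probability 0.5 on the point
#' mass (rather than `pi`), so the prior point masses enter the acceptance
#' ratio while the continuous prior shape still cancels.  Typically run
#' with far fewer cycles (default 5).
#'
#' @inheritParams update_locus_mh
#' @return updated state.
#' @export
update_locus_mh_efficient <- function(state, G, j, hyper, cycles = 5) {
  .update_locus_mh(state, G, j, hyper, cycles, efficient = TRUE)
}

# Fisher-Yates permutation mirroring the compiled implementation
.scan_order <- function(k, random) {
  ord <- seq_len(k)
  if (!random || k < 2) return(ord)
  for (i in k:2) {
    j <- min(floor(stats::runif(1) * i) + 1, i)
    tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
  }
  ord
}

# one full reference sweep: mu, all loci, sigma2_e
.sweep_reference <- function(state, G, hyper, kind, cycles, random_scan) {
  state <- draw_mu(state, hyper)
  upd <- switch(kind,
    single_site_gibbs = update_locus_single_site,
    joint_gibbs = update_locus_joint,
    pseudo_gibbs = update_locus_pseudo,
    mh = function(s, G, j, h) update_locus_mh(s, G, j, h, cycles),
    efficient_mh = function(s, G, j, h)
      update_locus_mh_efficient(s, G, j, h, cycles))
  for (j in .scan_order(G$n_markers, random_scan))
    state <- upd(state, G, j, hyper)
  draw_sigma2_e(state, hyper)
}
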