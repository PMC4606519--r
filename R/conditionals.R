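# Stateless full-conditional draws and inclusion-probability formulas shared
# by all sampler kernels.  Everything here uses R's global RNG; callers seed
# with set.seed().

#' Draw from a scaled inverse chi-square distribution
#'
#' Returns `nu * s2 / rchisq(nu)`, i.e. a draw from
#' \eqn{\nu S^2 \chi^{-2}_\nu}.  Mean is \eqn{\nu S^2/(\nu-2)} for
#' \eqn{\nu > 2}.
#'
#' @param nu degrees of freedom (> 0).
#' @param s2 scale (> 0).
#' @param n number of draws.
#' @return numeric vector of positive draws.
#' @export
draw_scaled_inv_chi2 <- function(nu, s2, n = 1) {
  if (!is.numeric(nu) || nu <= 0) stop("`nu` must be > 0")
  if (!is.numeric(s2) || s2 <= 0) stop("`s2` must be > 0")
  nu * s2 / stats::rchisq(n, df = nu)
}

#' Gibbs draw of the overall mean
#'
#' Full conditional of `mu` under a flat prior: normal with mean
#' `mean(e_mu)` and variance `sigma2_e/n`, where `e_mu = y - X alpha =
#' residual + mu`.  With a proper prior N(`mu0`, `tau2`) (finite `tau2` in
#' the hyperparameters) the usual conjugate precision-weighted form is used.
#' The residual is updated to reflect the new value.
#'
#' @param state a `bayesb_state`.
#' @param hyper a `bayesb_hyper` (for `mu0`/`tau2`).
#' @return updated state.
#' @export
draw_mu <- function(state, hyper) {
  n <- length(state$residual)
  em <- mean(state$residual) + state$mu
  if (is.infinite(hyper$tau2)) {
    m <- em
    v <- state$sigma2_e / n
  } else {
    prec <- n / state$sigma2_e + 1 / hyper$tau2
    m <- (n * em / state$sigma2_e + hyper$mu0 / hyper$tau2) / prec
    v <- 1 / prec
  }
  mu_new <- stats::rnorm(1, m, sqrt(v))
  state$residual <- state$residual - (mu_new - state$mu)
  state$mu <- mu_new
  state
}

#' Gibbs draw of the residual variance
#'
#' Scaled inverse chi-square with scale `(nu_e * s2_e + e'e) / (nu_e + n)`
#' and `nu_e + n` degrees of freedom.
#'
#' @param state a `bayesb_state`.
#' @param hyper a `bayesb_hyper`.
#' @return updated state.
#' @export
draw_sigma2_e <- function(state, hyper) {
  n <- length(state$residual)
  ee <- sum(state$residual^2)
  state$sigma2_e <- (hyper$nu_e * hyper$s2_e + ee) /
    stats::rchisq(1, df = hyper$nu_e + n)
  state
}

#' Gibbs draw of one locus variance
#'
#' In `single_site` and `joint` modes the full conditional is always the
#' scaled inverse chi-square with scale
#' `(nu_beta * s2_beta + beta_j^2) / (nu_beta + 1)` and `nu_beta + 1`
#' degrees of freedom (`beta_j` is defined even when excluded).  In `pseudo`
#' mode this form applies only when `delta_j = 1`; when `delta_j = 0` the
#' locus variance is refreshed from its prior (scale `s2_beta`, df
#' `nu_beta`).
#'
#' @param beta_j current effect.
#' @param delta_j inclusion indicator (0/1).
#' @param hyper a `bayesb_hyper`.
#' @param mode one of `"single_site"`, `"joint"`, `"pseudo"`.
#' @return positive scalar.
#' @export
draw_sigma2_j <- function(beta_j, delta_j, hyper,
                          mode = c("single_site", "joint", "pseudo")) {
  mode <- match.arg(mode)
  if (mode == "pseudo" && delta_j == 0) {
    draw_scaled_inv_chi2(hyper$nu_beta, hyper$s2_beta)
  } else {
    (hyper$nu_beta * hyper$s2_beta + beta_j^2) /
      stats::rchisq(1, df = hyper$nu_beta + 1)
  }
}

#' Gibbs draw of one marker effect given its indicator
#'
#' When included, normal with mean `rhs/c_j` and variance `sigma2_e/c_j`
#' where `c_j = xtx + sigma2_e/sigma2_j`; when excluded, a prior draw
#' N(0, `sigma2_j`).
#'
#' @param rhs adjusted right-hand side \eqn{X_j'w}.
#' @param xtx marker cross-product \eqn{X_j'X_j}.
#' @param sigma2_j locus variance.
#' @param sigma2_e residual variance.
#' @param delta_j inclusion indicator (0/1).
#' @return scalar draw.
#' @export
draw_beta_given_delta <- function(rhs, xtx, sigma2_j, sigma2_e, delta_j) {
  stopifnot(sigma2_j > 0, sigma2_e > 0)
  if (delta_j == 1) {
    c_j <- xtx + sigma2_e / sigma2_j
    stats::rnorm(1, rhs / c_j, sqrt(sigma2_e / c_j))
  } else {
    stats::rnorm(1, 0, sqrt(sigma2_j))
  }
}

# logit-scale inclusion probability with exact 0/1 at the prior boundary
.p_delta <- function(pi, log_ratio) {
  if (pi <= 0) return(1)
  if (pi >= 1) return(0)
  stats::plogis(log((1 - pi) / pi) + log_ratio)
}

#' Single-site inclusion probability
#'
#' Full conditional `Pr(delta_j = 1 | ELSE)` given the *current* effect
#' `beta_j`.  Computed in log space through the likelihood ratio
#' `r = (beta_j * rhs - beta_j^2 * xtx / 2) / sigma2_e`; the common factor
#' `exp(-w'w / 2 sigma2_e)` cancels algebraically and is never evaluated.
#'
#' @param rhs,xtx,sigma2_e locus sufficient statistics.
#' @param beta_j current effect value.
#' @param pi prior exclusion probability.
#' @return probability in `[0, 1]` (exactly 1 at `pi = 0`, 0 at `pi = 1`).
#' @export
prob_delta1_single_site <- function(rhs, xtx, beta_j, sigma2_e, pi) {
  r <- (beta_j * rhs - 0.5 * beta_j^2 * xtx) / sigma2_e
  .p_delta(pi, r)
}

#' Log marginal density of the locus sufficient statistic
#'
#' The univariate statistic \eqn{X_j'w} carries all the information in `w`
#' about the locus.  Given `delta = 1` it is normal with mean 0 and variance
#' `xtx^2 * sigma2_j + xtx * sigma2_e` (the effect integrated out); given
#' `delta = 0` the variance is `xtx * sigma2_e`.
#'
#' @param rhs observed \eqn{X_j'w}.
#' @param xtx marker cross-product (> 0; monomorphic markers must be
#'   excluded by the caller).
#' @param sigma2_j locus variance (ignored when `delta = 0`).
#' @param sigma2_e residual variance.
#' @param delta 0 or 1.
#' @return log density.
#' @export
log_marglik_univariate <- function(rhs, xtx, sigma2_j, sigma2_e, delta) {
  if (xtx <= 0) stop("xtx must be > 0 (monomorphic marker?)")
  v <- xtx * sigma2_e + if (delta == 1) xtx^2 * sigma2_j else 0
  stats::dnorm(rhs, 0, sqrt(v), log = TRUE)
}

#' Joint-kernel (marginal) inclusion probability
#'
#' `Pr(delta_j = 1)` with `beta_j` integrated out:
#' `m1 (1 - pi) / (m1 (1 - pi) + m0 pi)`, computed from
#' `log m1 - log m0` in log space.  Does not depend on the current `beta_j`.
#'
#' @inheritParams log_marglik_univariate
#' @param pi prior exclusion probability.
#' @return probability in `[0, 1]`.
#' @export
prob_delta1_joint <- function(rhs, xtx, sigma2_j, sigma2_e, pi) {
  dlm <- log_marglik_univariate(rhs, xtx, sigma2_j, sigma2_e, 1) -
    log_marglik_univariate(rhs, xtx, sigma2_j, sigma2_e, 0)
  .p_delta(pi, dlm)
}

#' Pseudo-prior normal parameters for an excluded effect
#'
#' Mean `rhs / (xtx + lambda)` and variance
#' `pseudo_sigma2_e / (xtx + lambda)` with
#' `lambda = pseudo_sigma2_e / pseudo_sigma2_j`.  The constants default to
#' the prior means (see [hyperparameters()]); choosing them equal to the
#' *current* `sigma2_e` and `sigma2_j` recovers the exact full conditional
#' of an included effect.
#'
#' @param rhs,xtx locus sufficient statistics.
#' @param hyper a `bayesb_hyper` carrying the pseudo constants.
#' @return list with `mean` and `variance`.
#' @export
pseudo_prior_params <- function(rhs, xtx, hyper) {
  if (is.null(hyper$pseudo_sigma2_e) || is.null(hyper$pseudo_lambda))
    stop("pseudo-prior constants are unset; supply pseudo_sigma2_e and ",
         "pseudo_sigma2_j explicitly (prior-mean defaults require nu > 2)")
  denom <- xtx + hyper$pseudo_lambda
  list(mean = rhs / denom, variance = hyper$pseudo_sigma2_e / denom)
}

#' Pseudo-prior-kernel inclusion probability
#'
#' The single-site probability augmented by the ratio of the two densities
#' of the current `beta_j`: its slab prior N(0, `sigma2_j`) versus the
#' pseudo prior.  Computed entirely in log space.
#'
#' @inheritParams prob_delta1_single_site
#' @param sigma2_j locus variance.
#' @param pseudo list with `mean` and `variance` (see
#'   [pseudo_prior_params()]).
#' @return probability in `[0, 1]`.
#' @export
prob_delta1_pseudo <- function(rhs, xtx, beta_j, sigma2_j, sigma2_e, pi,
                               pseudo) {
  if (pseudo$variance <= 0) stop("pseudo-prior variance must be > 0")
  r <- (beta_j * rhs - 0.5 * beta_j^2 * xtx) / sigma2_e
  lf1 <- stats::dnorm(beta_j, 0, sqrt(sigma2_j), log = TRUE)
  lf0 <- stats::dnorm(beta_j, pseudo$mean, sqrt(pseudo$variance), log = TRUE)
  .p_delta(pi, r + lf1 - lf0)
}
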