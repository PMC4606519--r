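#' BayesB hyperparameters
#'
#' Fixed quantities of the model: the prior exclusion probability `pi`, the
#' scaled inverse chi-square prior parameters for the locus variances
#' (`nu_beta`, `s2_beta`) and the residual variance (`nu_e`, `s2_e`), and
#' the constants of the pseudo prior used by the pseudo-prior Gibbs kernel.
#'
#' The pseudo prior for an excluded effect is normal with mean
#' \eqn{X_j'w/(X_j'X_j+\tilde\lambda)} and variance
#' \eqn{\tilde\sigma_e^2/(X_j'X_j+\tilde\lambda)} with
#' \eqn{\tilde\lambda = \tilde\sigma_e^2/\tilde\sigma_j^2}.  When not
#' supplied, the constants default to the prior means
#' \eqn{\tilde\sigma_e^2 = \nu_e S_e^2/(\nu_e-2)} and
#' \eqn{\tilde\sigma_j^2 = \nu_\beta S_\beta^2/(\nu_\beta-2)}, which
#' requires both degrees of freedom to exceed 2; otherwise the constants
#' are left unset and must be given explicitly before the pseudo-prior
#' kernel can run.
#'
#' `mu0`/`tau2` define an optional proper normal prior for the overall mean;
#' the default `tau2 = Inf` is the flat prior of the model, under which the
#' full conditional of `mu` is N(mean(e_mu), sigma2_e/n).  A finite `tau2`
#' is used by [geweke_test()], which needs a proper joint prior.
#'
#' @param pi prior probability that a marker effect is exactly zero.
#' @param nu_beta,s2_beta degrees of freedom and scale of the locus-variance
#'   prior.
#' @param nu_e,s2_e degrees of freedom and scale of the residual-variance
#'   prior.
#' @param pseudo_sigma2_e,pseudo_sigma2_j pseudo-prior constants; `NULL`
#'   selects the prior-mean defaults when they exist.
#' @param mu0,tau2 normal prior for the overall mean (`tau2 = Inf` = flat).
#' @return object of class `bayesb_hyper`.
#' @export
hyperparameters <- function(pi, nu_beta = 4, s2_beta = 1, nu_e = 4,
                            s2_e = 1, pseudo_sigma2_e = NULL,
                            pseudo_sigma2_j = NULL, mu0 = 0, tau2 = Inf) {
  stopifnot(is.numeric(pi), length(pi) == 1, pi >= 0, pi <= 1,
            nu_beta > 0, s2_beta > 0, nu_e > 0, s2_e > 0,
            is.finite(mu0), tau2 > 0)
  if (is.null(pseudo_sigma2_e) && nu_e > 2)
    pseudo_sigma2_e <- nu_e * s2_e / (nu_e - 2)
  if (is.null(pseudo_sigma2_j) && nu_beta > 2)
    pseudo_sigma2_j <- nu_beta * s2_beta / (nu_beta - 2)
  if (!is.null(pseudo_sigma2_e)) stopifnot(pseudo_sigma2_e > 0)
  if (!is.null(pseudo_sigma2_j)) stopifnot(pseudo_sigma2_j > 0)
  pseudo_lambda <- if (!is.null(pseudo_sigma2_e) && !is.null(pseudo_sigma2_j))
    pseudo_sigma2_e / pseudo_sigma2_j else NULL
  structure(list(pi = pi, nu_beta = nu_beta, s2_beta = s2_beta,
                 nu_e = nu_e, s2_e = s2_e,
                 pseudo_sigma2_e = pseudo_sigma2_e,
                 pseudo_sigma2_j = pseudo_sigma2_j,
                 pseudo_lambda = pseudo_lambda,
                 mu0 = mu0, tau2 = tau2),
            class = "bayesb_hyper")
}

#' Data-driven default hyperparameters
#'
#' The model prints no canonical hyperparameter values, so defaults follow
#' the standard genomic-prediction rule that puts the implied genetic
#' variance on the phenotypic scale: `nu_beta = nu_e = 4`,
#' `s2_e = var(y)/2`, and
#' `s2_beta = var(y) * h2 * (nu_beta - 2) / nu_beta /
#' ((1 - pi) * sum(xtx)/n)` with assumed heritability `h2 = 0.5`.
#'
#' @param y phenotype vector (training set).
#' @param G genotype matrix (training set), used for `sum(xtx)`.
#' @param pi prior exclusion probability.
#' @param h2_assumed heritability assumed by the scaling rule.
#' @param nu_beta,nu_e prior degrees of freedom.
#' @param ... passed through to [hyperparameters()].
#' @return object of class `bayesb_hyper`.
#' @export
default_hyperparameters <- function(y, G, pi, h2_assumed = 0.5,
                                    nu_beta = 4, nu_e = 4, ...) {
  vy <- stats::var(as.numeric(y))
  if (!is.finite(vy) || vy <= 0) vy <- 1
  msx <- sum(G$xtx) / G$n_individuals
  if (pi >= 1 || msx <= 0) {
    s2b <- vy  # no slab mass or no marker variation: scale is arbitrary
  } else {
    s2b <- vy * h2_assumed * (nu_beta - 2) / nu_beta / ((1 - pi) * msx)
  }
  hyperparameters(pi = pi, nu_beta = nu_beta, s2_beta = s2b,
                  nu_e = nu_e, s2_e = vy / 2, ...)
}
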