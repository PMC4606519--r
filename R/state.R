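#' Create an MCMC model state
#'
#' Holds the current values of all unknowns plus the maintained residual
#' vector `e = y - mu - sum_j X_j beta_j delta_j`.  Initialisation:
#' `mu = mean(y)`, `beta = 0`, `delta = 0`, `sigma2_j = s2_beta`,
#' `sigma2_e = var(y)`.
#'
#' @param G a [center_genotypes()] object.
#' @param y phenotype vector (length `G$n_individuals`).
#' @param hyper a [hyperparameters()] object (used for `s2_beta`).
#' @return object of class `bayesb_state`.
#' @export
new_model_state <- function(G, y, hyper) {
  check_dims(G, y)
  y <- as.numeric(y)
  k <- G$n_markers
  mu <- mean(y)
  structure(list(mu = mu,
                 beta = rep(0, k),
                 delta = rep(0L, k),
                 sigma2_j = rep(hyper$s2_beta, k),
                 sigma2_e = if (length(y) > 1) stats::var(y) else 1,
                 residual = y - mu),
            class = "bayesb_state")
}

#' Adjusted right-hand side for one locus
#'
#' Returns the sufficient scalar \eqn{X_j'w} where
#' \eqn{w = e + X_j \beta_j \delta_j} is the phenotype corrected for all
#' model terms except locus `j`.  Computed incrementally as
#' \eqn{X_j'e + X_j'X_j\,\beta_j\delta_j} without materialising `w`.
#'
#' @param state a `bayesb_state`.
#' @param G genotype matrix.
#' @param j marker index (1-based).
#' @return scalar.
#' @export
adjusted_rhs <- function(state, G, j) {
  if (j < 1 || j > G$n_markers) stop("marker index out of range")
  xj <- G$values[, j]
  sum(xj * state$residual) +
    G$xtx[[j]] * state$beta[j] * as.numeric(state$delta[j])
}

#' Incremental residual update after a change in one marker effect
#'
#' `residual <- residual - X_j (alpha_new - alpha_old)`, an O(n) operation.
#'
#' @param state a `bayesb_state`.
#' @param G genotype matrix.
#' @param j marker index.
#' @param alpha_old effect value currently reflected in the residual.
#' @param alpha_new new effect value.
#' @return updated state.
#' @export
update_residual <- function(state, G, j, alpha_old, alpha_new) {
  da <- alpha_new - alpha_old
  if (da != 0) state$residual <- state$residual - G$values[, j] * da
  state
}

#' Recompute the residual from scratch
#'
#' Guards against floating-point drift in the incremental bookkeeping.  The
#' maximum absolute deviation between the incremental and from-scratch
#' residual is attached as attribute `"drift"`.
#'
#' @param state a `bayesb_state`.
#' @param G genotype matrix.
#' @param y phenotype vector.
#' @return updated state (attribute `drift` holds the observed deviation).
#' @export
rebuild_residual <- function(state, G, y) {
  alpha <- state$beta * as.numeric(state$delta)
  fresh <- as.numeric(y) - state$mu
  if (G$n_markers > 0 && any(alpha != 0))
    fresh <- fresh - as.numeric(G$values %*% alpha)
  drift <- if (length(fresh)) max(abs(fresh - state$residual)) else 0
  state$residual <- fresh
  attr(state, "drift") <- drift
  state
}
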