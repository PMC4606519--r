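#' Effective sample size of an MCMC chain
#'
#' Initial-monotone-positive-sequence estimator: autocovariances are summed
#' in adjacent pairs, the sum is truncated at the first non-positive pair
#' and the pair sequence is forced non-increasing; ESS = N * gamma0 /
#' asymptotic variance, clipped to `[1, N]`.  A zero-variance chain returns
#' `N` with a warning (defined degenerate case).
#'
#' @param chain numeric vector of draws (length >= 10).
#' @return scalar ESS.
#' @export
effective_sample_size <- function(chain) {
  N <- length(chain)
  if (N < 10) stop("chain too short for ESS estimation (need >= 10)")
  m <- mean(chain)
  x <- chain - m
  g0 <- mean(x^2)
  if (g0 <= 0 || !is.finite(g0)) {
    warning("zero-variance chain; returning ESS = N by convention")
    return(N)
  }
  gam <- function(t) sum(x[seq_len(N - t)] * x[(t + 1):N]) / N
  var_sum <- -g0
  prev <- Inf
  t <- 0L
  while (t + 1L < N) {
    Gm <- gam(t) + gam(t + 1L)
    if (Gm <= 0) break
    Gm <- min(Gm, prev)   # enforce monotone non-increasing pair sums
    var_sum <- var_sum + 2 * Gm
    prev <- Gm
    t <- t + 2L
  }
  if (var_sum <= 0) return(N)
  min(max(N * g0 / var_sum, 1), N)
}

# ESS without the degenerate-case warning (used in bulk summaries)
.ess_quiet <- function(chain) {
  suppressWarnings(effective_sample_size(chain))
}

#' Posterior summaries of a chain
#'
#' Mean, standard deviation, ESS and ESS-based Monte-Carlo standard error
#' (`sd/sqrt(ESS)`) for `mu`, `sigma2_e` and every marker effect
#' `alpha_j`; marker rows also carry the posterior inclusion frequency.
#'
#' @param draws a [run_chain()] result.
#' @return `data.frame` with columns `parameter`, `mean`, `sd`, `ess`,
#'   `mcse`, `inclusion`.
#' @export
posterior_summary <- function(draws) {
  if (length(draws$mu) == 0) stop("no stored draws to summarise")
  one <- function(x) {
    s <- stats::sd(x)
    e <- .ess_quiet(x)
    c(mean = mean(x), sd = s, ess = e,
      mcse = if (s > 0) s / sqrt(e) else 0)
  }
  k <- ncol(draws$alpha)
  rows <- rbind(one(draws$mu), one(draws$sigma2_e),
                t(vapply(seq_len(k), function(j) one(draws$alpha[, j]),
                         numeric(4))))
  out <- data.frame(parameter = c("mu", "sigma2_e",
                                  paste0("alpha_", draws$marker_ids)),
                    rows, row.names = NULL)
  out$inclusion <- c(NA, NA, unname(draws$delta_freq))
  out
}

#' Genomic estimated breeding values
#'
#' `GEBV = X_test %*% alpha_hat`.  The test genotypes must be centred with
#' the *training* column means:
#' `center_genotypes(raw_test, means = G_train$col_means)`.
#'
#' @param G_test a [center_genotypes()] object for the test individuals.
#' @param alpha_hat named vector of posterior-mean marker effects (e.g.
#'   `colMeans(draws$alpha)`).
#' @return numeric GEBV vector (one per test individual).
#' @export
predict_gebv <- function(G_test, alpha_hat) {
  if (length(alpha_hat) != G_test$n_markers)
    stop("alpha_hat length does not match marker count")
  if (!is.null(names(alpha_hat))) {
    bad <- which(names(alpha_hat) != G_test$marker_ids)
    if (length(bad))
      stop("marker mismatch between genotypes and effects: ",
           paste(utils::head(G_test$marker_ids[bad], 5), collapse = ", "))
  }
  stats::setNames(as.numeric(G_test$values %*% unname(alpha_hat)),
                  G_test$individual_ids)
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBV and held-out phenotypes (or true
#' breeding values).
#'
#' @param gebv predicted values.
#' @param y_test observed values, same length (>= 3).
#' @return scalar correlation.
#' @export
prediction_accuracy <- function(gebv, y_test) {
  if (length(gebv) != length(y_test)) stop("length mismatch")
  if (length(gebv) < 3) stop("need at least 3 observations")
  if (stats::sd(gebv) == 0 || stats::sd(y_test) == 0)
    stop("correlation undefined for constant input")
  stats::cor(as.numeric(gebv), as.numeric(y_test))
}

#' Sampler-efficiency report
#'
#' Mirrors the usual benchmarking table: ESS of the residual-variance chain,
#' effective samples per wall-clock second (hardware-dependent), posterior
#' means, and (when a test set is given) prediction accuracy.
#'
#' @param draws a [run_chain()] result.
#' @param G_test optional test-set genotype matrix (centred with training
#'   means).
#' @param y_test optional test phenotypes.
#' @param bv_test optional true breeding values (adds `accuracy_truth`).
#' @return object of class `efficiency_report` (a named list, JSON-ready).
#' @export
efficiency_report <- function(draws, G_test = NULL, y_test = NULL,
                              bv_test = NULL) {
  ess <- .ess_quiet(draws$sigma2_e)
  acc <- acc_truth <- NULL
  if (!is.null(G_test) && !is.null(y_test)) {
    gebv <- predict_gebv(G_test, colMeans(draws$alpha))
    acc <- prediction_accuracy(gebv, y_test)
    if (!is.null(bv_test)) acc_truth <- prediction_accuracy(gebv, bv_test)
  }
  structure(list(sampler = draws$sampler,
                 chain_length = draws$chain_length,
                 stored_draws = length(draws$mu),
                 wall_seconds = draws$wall_seconds,
                 ess_sigma2_e = ess,
                 ess_per_second = ess / draws$wall_seconds,
                 posterior_mean_mu = mean(draws$mu),
                 posterior_mean_sigma2_e = mean(draws$sigma2_e),
                 prediction_accuracy = acc,
                 accuracy_truth = acc_truth,
                 note = "ess_per_second is hardware-dependent"),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("efficiency_report [%s]: ESS(sigma2_e) %.0f in %.2fs (%.1f/s)\n",
              x$sampler, x$ess_sigma2_e, x$wall_seconds, x$ess_per_second))
  cat(sprintf("  mean mu %.4f, mean sigma2_e %.4f%s\n",
              x$posterior_mean_mu, x$posterior_mean_sigma2_e,
              if (!is.null(x$prediction_accuracy))
                sprintf(", accuracy %.3f", x$prediction_accuracy) else ""))
  invisible(x)
}
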