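#' Model comparison statistics
#'
#' Fitted models are compared on six statistics: DIC and WAIC (fit, smaller
#' better) with their effective-parameter counts P_DIC and P_WAIC (complexity,
#' smaller better), the leave-one-out logarithmic score LS derived from
#' conditional predictive ordinates (predictive power, smaller better), and
#' the coefficient of determination R-squared on the log scale (explained
#' variation, larger better).
#'
#' @name evaluation
NULL

#' Pointwise log-likelihood matrix
#'
#' Entry (s, c): Gaussian log-density of the observed log response at cell c
#' under draw s's predictor and observation variance. Columns cover exactly
#' the observed (non-missing) cells, in column-major cell order.
#'
#' @param fit an [fit_gibbs()] result.
#' @param panel the [panel_data] the fit was produced from (preprocessed).
#' @return A draws x cells matrix.
#' @export
pointwise_loglik <- function(fit, panel = fit$design$panel) {
  stopifnot(inherits(fit, "stvc_fit"))
  z <- panel$y[fit$obs_cells]
  res2 <- sweep(fit$eta[, fit$obs_cells, drop = FALSE], 2, z)^2
  -0.5 * log(2 * pi * fit$sigma2) - res2 / (2 * fit$sigma2)
}

#' Deviance information criterion
#'
#' Posterior-mean deviance minus plug-in deviance gives the effective
#' parameter count; the plug-in is the posterior mean of the linear predictor
#' and of the observation variance.
#'
#' @param loglik draws x cells log-likelihood matrix.
#' @param fit the corresponding [fit_gibbs()] result.
#' @return list(dic, p_dic).
#' @export
compute_dic <- function(loglik, fit) {
  if (nrow(loglik) < 2) stopf("need at least two draws")
  dbar <- mean(-2 * rowSums(loglik))
  eta_hat <- colMeans(fit$eta[, fit$obs_cells, drop = FALSE])
  s2_hat <- mean(fit$sigma2)
  z <- fit$design$panel$y[fit$obs_cells]
  dhat <- -2 * sum(stats::dnorm(z, eta_hat, sqrt(s2_hat), log = TRUE))
  p_dic <- dbar - dhat
  list(dic = dhat + 2 * p_dic, p_dic = p_dic)
}

#' Watanabe-Akaike information criterion
#'
#' `lppd` is the summed log posterior-mean pointwise likelihood (stable
#' log-sum-exp); the penalty is the summed posterior variance of the pointwise
#' log-likelihood.
#'
#' @param loglik draws x cells log-likelihood matrix.
#' @return list(waic, p_waic).
#' @export
compute_waic <- function(loglik) {
  if (nrow(loglik) < 2) stopf("need at least two draws")
  lppd <- sum(col_log_mean_exp(loglik))
  p_waic <- sum(apply(loglik, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic)
}

#' Logarithmic score from conditional predictive ordinates
#'
#' The CPO of a cell is the harmonic mean over draws of its pointwise
#' likelihood (the standard MCMC estimator of the leave-one-out predictive
#' density), computed in log space. LS is the negative mean log-CPO; smaller
#' is better. Cells whose harmonic-mean estimator has a low effective sample
#' size are counted and reported, not failed.
#'
#' @param loglik draws x cells log-likelihood matrix.
#' @param min_ess effective-sample-size guard threshold.
#' @return list(ls, log_cpo, n_unstable).
#' @export
compute_cpo_ls <- function(loglik, min_ess = 10) {
  if (nrow(loglik) < 2) stopf("need at least two draws")
  S <- nrow(loglik)
  neg <- -loglik
  m <- apply(neg, 2, max)
  wsum <- colSums(exp(sweep(neg, 2, m)))
  log_cpo <- log(S) - (m + log(wsum))
  # importance-weight ESS of the harmonic-mean estimator per cell
  w2sum <- colSums(exp(2 * sweep(neg, 2, m)))
  ess <- wsum^2 / w2sum
  list(ls = -mean(log_cpo), log_cpo = log_cpo, n_unstable = sum(ess < min_ess))
}

#' Coefficient of determination on the log scale
#'
#' `1 - SS_res / SS_tot` over observed cells, with the posterior-mean
#' predictor as the fitted value; clamped to `[0, 1]`.
#'
#' @param fit an [fit_gibbs()] result.
#' @param panel the fitted [panel_data].
#' @export
compute_r2 <- function(fit, panel = fit$design$panel) {
  stopifnot(inherits(fit, "stvc_fit"))
  z <- panel$y[fit$obs_cells]
  sst <- sum((z - mean(z))^2)
  if (sst < 1e-300) stopf("response has zero variance; R-squared undefined")
  eta_hat <- colMeans(fit$eta[, fit$obs_cells, drop = FALSE])
  r2 <- 1 - sum((z - eta_hat)^2) / sst
  min(1, max(0, r2))
}

#' All six comparison statistics for one fitted model
#'
#' @param fit an [fit_gibbs()] result.
#' @param panel the fitted [panel_data].
#' @return An object of class `model_scorecard`:
#'   list(model_id, dic, waic, p_dic, p_waic, ls, r2, n_unstable_cpo).
#' @export
model_scorecard <- function(fit, panel = fit$design$panel) {
  ll <- pointwise_loglik(fit, panel)
  dic <- compute_dic(ll, fit)
  waic <- compute_waic(ll)
  cpo <- compute_cpo_ls(ll)
  structure(
    list(model_id = fit$design$spec$model_id,
         dic = dic$dic, waic = waic$waic,
         p_dic = dic$p_dic, p_waic = waic$p_waic,
         ls = cpo$ls, r2 = compute_r2(fit, panel),
         n_unstable_cpo = cpo$n_unstable),
    class = "model_scorecard"
  )
}

#' Comparison table across fitted models
#'
#' One row per scorecard (input order preserved) with the six statistics and,
#' per statistic, a flag for the winning model (smaller-better for
#' DIC/WAIC/P_DIC/P_WAIC/LS, larger-better for R-squared).
#'
#' @param scorecards a list of [model_scorecard()] objects (>= 2).
#' @return A data.frame with columns model, dic, waic, p_dic, p_waic, ls, r2
#'   and logical `best_*` flags.
#' @export
compare_models <- function(scorecards) {
  if (length(scorecards) < 2) stopf("need at least two scorecards")
  tab <- do.call(rbind, lapply(scorecards, function(s) {
    data.frame(model = s$model_id, dic = s$dic, waic = s$waic,
               p_dic = s$p_dic, p_waic = s$p_waic, ls = s$ls, r2 = s$r2)
  }))
  for (col in c("dic", "waic", "p_dic", "p_waic", "ls")) {
    tab[[paste0("best_", col)]] <- seq_len(nrow(tab)) == which.min(tab[[col]])
  }
  tab$best_r2 <- seq_len(nrow(tab)) == which.max(tab$r2)
  tab
}
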