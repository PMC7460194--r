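#' MCMC settings
#'
#' @param chains number of chains (>= 2, so split-R-hat is defined).
#' @param iter iterations per chain, including burn-in.
#' @param burnin discarded iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer root seed; chain c uses `seed + 100003 * (c - 1)`.
#' @export
mcmc_config <- function(chains = 2, iter = 5000, burnin = 2500, thin = 1,
                        seed = 1) {
  if (chains < 2) stopf("at least two chains are required for convergence diagnostics")
  if (burnin >= iter) stopf("burnin must be smaller than iter")
  list(chains = as.integer(chains), iter = as.integer(iter),
       burnin = as.integer(burnin), thin = as.integer(thin),
       seed = as.integer(seed))
}

# per-block constants used by the full-conditional updates:
# for each latent block, the likelihood contribution to its precision is
# diagonal (each cell loads on exactly one block coordinate), so the
# full-conditional precision is  Q/sigma2_f + diag(d)/sigma2.
#' @noRd
build_workspace <- function(design) {
  panel <- design$panel
  X <- panel$X
  I <- dim(X)[1]; T_ <- dim(X)[2]
  ws <- list(I = I, T_ = T_, ncell = I * T_)
  blocks <- list()
  for (b in design$blocks) {
    w <- list(kind = b$kind, dim = b$dim, cov = b$cov,
              constrained = b$constrained, absorb = b$absorb)
    if (!is.null(b$gmrf)) {
      w$Qd <- as.matrix(b$gmrf$Q)
      w$rankdef <- b$gmrf$rank_deficiency
      w$pinned <- b$gmrf$pinned
      w$component <- b$gmrf$component
      w$prior <- b$gmrf$precision_prior
    }
    if (b$kind %in% c("sc", "tc")) {
      w$Xp <- X[, , b$cov]
      w$d <- if (b$kind == "sc") rowSums(w$Xp^2) else colSums(w$Xp^2)
    } else if (b$kind == "si") {
      w$d <- rep(as.numeric(T_), I)
    } else if (b$kind == "ti") {
      w$d <- rep(as.numeric(I), T_)
    } else if (b$kind == "global") {
      A <- cbind(1, matrix(X, I * T_, dim(X)[3]))
      w$A <- A
      w$AtA <- crossprod(A)
    }
    blocks[[b$name]] <- w
  }
  ws$blocks <- blocks
  ws
}

# contribution of one block to the predictor surface
#' @noRd
block_contrib <- function(w, theta, I, T_) {
  switch(w$kind,
    intercept = matrix(theta, I, T_),
    global = matrix(w$A %*% theta, I, T_),
    sc = w$Xp * theta,
    tc = w$Xp * matrix(theta, I, T_, byrow = TRUE),
    si = matrix(theta, I, T_),
    ti = matrix(theta, I, T_, byrow = TRUE)
  )
}

# unconstrained Gaussian full conditional of one block:
# precision P and linear term bvec (mean = solve(P, bvec)), given the partial
# residual Rm = Z - eta_without_block
#' @noRd
block_moments <- function(w, Rm, sigma2, sigma2_f) {
  switch(w$kind,
    intercept = list(P = matrix(length(Rm) / sigma2, 1, 1),
                     b = sum(Rm) / sigma2),
    global = list(P = w$AtA / sigma2,
                  b = as.vector(crossprod(w$A, as.vector(Rm))) / sigma2),
    sc = list(P = w$Qd / sigma2_f + diag(w$d / sigma2, w$dim),
              b = rowSums(w$Xp * Rm) / sigma2),
    tc = list(P = w$Qd / sigma2_f + diag(w$d / sigma2, w$dim),
              b = colSums(w$Xp * Rm) / sigma2),
    si = list(P = w$Qd / sigma2_f + diag(w$d / sigma2, w$dim),
              b = rowSums(Rm) / sigma2),
    ti = list(P = w$Qd / sigma2_f + diag(w$d / sigma2, w$dim),
              b = colSums(Rm) / sigma2)
  )
}

# test hook: the exact (precision, linear term) pair the sampler uses for one
# block, given full current state — compared against a dense joint-Gaussian
# conditioning oracle in the test suite
#' @noRd
block_full_conditional <- function(design, state, sigma2, sigma2_field, Z, name) {
  ws <- build_workspace(design)
  eta <- linear_predictor(design, state)
  w <- ws$blocks[[name]]
  Cb <- block_contrib(w, state[[name]], ws$I, ws$T_)
  Rm <- Z - eta + Cb
  block_moments(w, Rm, sigma2, sigma2_field[[name]] %||% NA_real_)
}

#' Fit a model by blocked Gibbs sampling
#'
#' Each latent block is updated from its exact Gaussian full conditional
#' (prior structure matrix over its variance component, plus the diagonal
#' likelihood contribution), each variance component from its conjugate
#' inverse-Gamma full conditional, and missing response cells are imputed from
#' the current posterior predictive each sweep (data augmentation). Sum-to-zero
#' constraints are re-imposed by centering after each constrained block update,
#' with the removed mean absorbed into the intercept (SI/TI) or the paired SC
#' field (TC), leaving the predictor unchanged.
#'
#' @param design an [build_model()] design.
#' @param mcmc an [mcmc_config()].
#' @return An object of class `stvc_fit`: post-burn-in `draws` per block
#'   (stacked over chains), `sigma2` (observation variance) and
#'   `sigma2_field` draws, the per-draw predictor surfaces `eta`
#'   (draws x cells), pointwise log-likelihoods at observed cells, chain
#'   labels, and split-R-hat / effective-sample-size diagnostics for the
#'   global terms and variance components (a convergence warning is attached
#'   as `rhat_warning` when any exceeds 1.05).
#' @export
fit_gibbs <- function(design, mcmc = mcmc_config()) {
  stopifnot(inherits(design, "stvc_design"))
  panel <- design$panel
  if (!any(!is.na(panel$y))) stopf("no observed cells")
  ws <- build_workspace(design)
  I <- ws$I; T_ <- ws$T_; ncell <- ws$ncell
  zobs <- panel$y
  obs_cells <- which(!is.na(zobs))
  miss_cells <- which(is.na(zobs))
  zbar <- mean(zobs[obs_cells])
  a0 <- design$noise_prior[["shape"]]; b0 <- design$noise_prior[["rate"]]
  block_names <- names(ws$blocks)
  gmrf_names <- block_names[vapply(ws$blocks, function(w) !is.null(w$Qd), TRUE)]

  n_keep <- ((mcmc$iter - mcmc$burnin) %/% mcmc$thin) * mcmc$chains
  draws <- lapply(ws$blocks, function(w) matrix(NA_real_, n_keep, w$dim))
  s2_draws <- numeric(n_keep)
  s2f_draws <- matrix(NA_real_, n_keep, length(gmrf_names),
                      dimnames = list(NULL, gmrf_names))
  eta_draws <- matrix(NA_real_, n_keep, ncell)
  chain_id <- integer(n_keep)
  row <- 0L

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 100003L * (ch - 1L))
    state <- lapply(ws$blocks, function(w) numeric(w$dim))
    if ("global" %in% block_names) state$global[1] <- zbar else state$beta0[] <- zbar
    s2 <- stats::var(zobs[obs_cells])
    s2f <- stats::setNames(rep(0.1, length(gmrf_names)), gmrf_names)
    Z <- zobs
    Z[miss_cells] <- zbar
    eta <- linear_predictor(design, state)

    for (it in seq_len(mcmc$iter)) {
      for (nm in block_names) {
        w <- ws$blocks[[nm]]
        Cb <- block_contrib(w, state[[nm]], I, T_)
        eta_wo <- eta - Cb
        Rm <- Z - eta_wo
        mo <- block_moments(w, Rm, s2, if (nm %in% gmrf_names) s2f[[nm]] else NA_real_)
        U <- chol(mo$P)
        mn <- backsolve(U, backsolve(U, mo$b, transpose = TRUE))
        theta <- mn + backsolve(U, stats::rnorm(w$dim))
        if (!all(is.finite(theta))) {
          stopf("non-finite draw in block '%s' at iteration %d (chain %d)", nm, it, ch)
        }
        if (length(w$pinned)) theta[w$pinned] <- 0
        # predictor uses the raw draw; centering plus absorption below leaves
        # the predictor invariant, so eta needs no further correction
        eta <- eta_wo + block_contrib(w, theta, I, T_)
        if (isTRUE(w$constrained)) {
          cm <- mean(theta)
          theta <- theta - stats::ave(theta, w$component)
          if (identical(w$absorb, "intercept")) {
            if ("global" %in% block_names) state$global[1] <- state$global[1] + cm
            else state$beta0 <- state$beta0 + cm
          } else if (!is.null(w$absorb)) {
            state[[w$absorb]] <- state[[w$absorb]] + cm
          }
        }
        state[[nm]] <- theta
      }
      # variance components: conjugate Gamma updates on the precisions
      for (nm in gmrf_names) {
        w <- ws$blocks[[nm]]
        th <- state[[nm]]
        qf <- as.numeric(th %*% (w$Qd %*% th))
        s2f[[nm]] <- 1 / stats::rgamma(
          1, shape = w$prior[["shape"]] + (w$dim - w$rankdef) / 2,
          rate = w$prior[["rate"]] + qf / 2
        )
      }
      rss <- sum((Z - eta)^2)
      s2 <- 1 / stats::rgamma(1, shape = a0 + ncell / 2, rate = b0 + rss / 2)
      if (length(miss_cells)) {
        Z[miss_cells] <- eta[miss_cells] + stats::rnorm(length(miss_cells), 0, sqrt(s2))
      }
      if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
        row <- row + 1L
        for (nm in block_names) draws[[nm]][row, ] <- state[[nm]]
        s2_draws[row] <- s2
        if (length(gmrf_names)) s2f_draws[row, ] <- s2f
        eta_draws[row, ] <- eta
        chain_id[row] <- ch
      }
    }
  }

  # pointwise log-likelihood at observed cells
  zvec <- zobs[obs_cells]
  res2 <- sweep(eta_draws[, obs_cells, drop = FALSE], 2, zvec)^2
  loglik <- -0.5 * log(2 * pi * s2_draws) - res2 / (2 * s2_draws)

  fit <- structure(
    list(design = design, draws = draws, sigma2 = s2_draws,
         sigma2_field = s2f_draws, eta = eta_draws, loglik = loglik,
         obs_cells = obs_cells, chain = chain_id, mcmc = mcmc),
    class = "stvc_fit"
  )
  fit$diagnostics <- fit_diagnostics(fit)
  fit$rhat_warning <- any(fit$diagnostics$rhat > 1.05, na.rm = TRUE)
  fit
}

# split-R-hat and a crude autocorrelation-based effective sample size for the
# global terms and all variance components
#' @noRd
fit_diagnostics <- function(fit) {
  pars <- list()
  gb <- if ("global" %in% names(fit$draws)) "global" else "beta0"
  g <- fit$draws[[gb]]
  for (j in seq_len(ncol(g))) pars[[paste0(gb, "[", j, "]")]] <- g[, j]
  pars[["sigma2_obs"]] <- fit$sigma2
  for (nm in colnames(fit$sigma2_field)) {
    pars[[paste0("sigma2_", nm)]] <- fit$sigma2_field[, nm]
  }
  data.frame(
    parameter = names(pars),
    rhat = vapply(pars, split_rhat, 0, chain = fit$chain),
    ess = vapply(pars, ess_acf, 0),
    row.names = NULL
  )
}

#' @noRd
split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- length(v) %/% 2L
    halves <- c(halves, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  n <- min(lengths(halves))
  if (n < 2) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(n)])
  mns <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @noRd
ess_acf <- function(x, max_lag = 50L) {
  n <- length(x)
  if (stats::var(x) < 1e-300) return(n)
  ac <- stats::acf(x, lag.max = min(max_lag, n - 1L), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1L)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' @export
print.stvc_fit <- function(x, ...) {
  cat(sprintf(
    "<stvc_fit> model %d: %d draws (%d chains), max split-Rhat %.3f%s\n",
    x$design$spec$model_id, length(x$sigma2), x$mcmc$chains,
    max(x$diagnostics$rhat, na.rm = TRUE),
    if (isTRUE(x$rhat_warning)) " [convergence warning]" else ""
  ))
  invisible(x)
}

#' Posterior summaries with equal-tailed credible intervals
#'
#' One row per scalar quantity (every block coordinate, the observation
#' variance, and each field variance) with posterior mean, sd, equal-tailed
#' credible bounds at `level`, and a significance flag set when the interval
#' excludes zero (the usual convention for varying-coefficient surfaces).
#'
#' @param fit an [fit_gibbs()] result.
#' @param level credibility level (default 0.95: 2.5%/97.5% quantiles).
#' @return A data.frame (block, index, mean, sd, lower, upper, significant).
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "stvc_fit"))
  al <- (1 - level) / 2
  summ1 <- function(block, idx, v) {
    q <- unname(stats::quantile(v, c(al, 1 - al), type = 7))
    data.frame(block = block, index = idx, mean = mean(v), sd = stats::sd(v),
               lower = q[1], upper = q[2],
               significant = q[1] > 0 | q[2] < 0)
  }
  out <- list()
  for (nm in names(fit$draws)) {
    m <- fit$draws[[nm]]
    for (j in seq_len(ncol(m))) out[[length(out) + 1L]] <- summ1(nm, j, m[, j])
  }
  out[[length(out) + 1L]] <- summ1("sigma2_obs", 1L, fit$sigma2)
  for (nm in colnames(fit$sigma2_field)) {
    out[[length(out) + 1L]] <- summ1(paste0("sigma2_", nm), 1L, fit$sigma2_field[, nm])
  }
  do.call(rbind, out)
}
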