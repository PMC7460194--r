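# build a minimal fit-like object directly: eta draws, sigma2 draws, and the
# observed data they score
fake_fit <- function(eta_draws, sigma2, y, obs_cells = seq_along(y)) {
  panel <- list(y = y)
  structure(list(
    eta = eta_draws, sigma2 = sigma2, obs_cells = obs_cells,
    design = list(panel = panel, spec = list(model_id = 0L))
  ), class = "stvc_fit")
}

test_that("pointwise log-likelihood matches the Gaussian density cell by cell", {
  # single cell at the mode: log(1/sqrt(2 pi v))
  v <- 0.3
  f <- fake_fit(matrix(2, 1, 1), v, y = 2)
  expect_equal(as.numeric(pointwise_loglik(f)), log(1 / sqrt(2 * pi * v)))
  # shape: draws x observed cells, scalar-loop oracle
  set.seed(4)
  y <- c(1.2, 0.7, 2.1)
  eta <- matrix(rnorm(6), 2, 3)
  s2 <- c(0.5, 0.8)
  f3 <- fake_fit(eta, s2, y)
  ll <- pointwise_loglik(f3)
  expect_equal(dim(ll), c(2L, 3L))
  for (s in 1:2) {
    for (c in 1:3) {
      expect_equal(ll[s, c], dnorm(y[c], eta[s, c], sqrt(s2[s]), log = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  y <- c(1.5, 2.5, 2.0)
  eta <- matrix(rep(c(1.4, 2.6, 2.0), each = 20), 20, 3)
  f <- fake_fit(eta, rep(0.4, 20), y)
  ll <- pointwise_loglik(f)
  out <- compute_dic(ll, f)
  expect_equal(out$p_dic, 0, tolerance = 1e-10)
  dhat <- -2 * sum(dnorm(y, eta[1, ], sqrt(0.4), log = TRUE))
  expect_equal(out$dic, dhat, tolerance = 1e-10)
})

test_that("DIC's effective parameter count matches the conjugate closed form", {
  # Normal likelihood with known variance, Normal prior on the common mean:
  # p_dic -> n * posterior_variance / sigma0^2
  set.seed(7)
  n <- 40; sigma0 <- 0.7; tau0 <- 2; mu0 <- 0
  y <- rnorm(n, 1.3, sigma0)
  taun2 <- 1 / (1 / tau0^2 + n / sigma0^2)
  mun <- taun2 * (mu0 / tau0^2 + sum(y) / sigma0^2)
  S <- 4e4
  mu_draws <- rnorm(S, mun, sqrt(taun2))
  f <- fake_fit(matrix(mu_draws, S, n), rep(sigma0^2, S), y)
  out <- compute_dic(pointwise_loglik(f), f)
  expect_equal(out$p_dic, n * taun2 / sigma0^2, tolerance = 0.05)
})

test_that("WAIC degenerates correctly and its penalty is nonnegative", {
  y <- c(0.5, 1.5)
  eta <- matrix(rep(c(0.4, 1.2), each = 10), 10, 2)
  f <- fake_fit(eta, rep(0.25, 10), y)
  ll <- pointwise_loglik(f)
  out <- compute_waic(ll)
  expect_equal(out$p_waic, 0, tolerance = 1e-12)
  expect_equal(out$waic, -2 * sum(ll[1, ]), tolerance = 1e-10)
  # random posteriors: p_waic >= 0 always, and the stable lppd matches a
  # direct high-precision evaluation on a small, well-scaled toy
  set.seed(11)
  ll2 <- matrix(rnorm(5 * 200, -1, 0.3), 200, 5)
  out2 <- compute_waic(ll2)
  expect_gte(out2$p_waic, 0)
  lppd_direct <- sum(log(colMeans(exp(ll2))))
  p_direct <- sum(apply(ll2, 2, var))
  expect_equal(out2$waic, -2 * (lppd_direct - p_direct), tolerance = 1e-10)
})

test_that("CPO log score degenerates to the negative mean log-likelihood", {
  y <- c(0.5, 1.5, 1.0)
  eta <- matrix(rep(c(0.4, 1.2, 1.1), each = 15), 15, 3)
  f <- fake_fit(eta, rep(0.25, 15), y)
  ll <- pointwise_loglik(f)
  out <- compute_cpo_ls(ll)
  expect_equal(out$ls, -mean(ll[1, ]), tolerance = 1e-10)
  expect_equal(out$log_cpo, ll[1, ], tolerance = 1e-10)
})

test_that("model criteria are invariant to the order of draws", {
  set.seed(21)
  y <- rnorm(6, 1, 0.5)
  eta <- matrix(rnorm(300, 1, 0.2), 50, 6)
  s2 <- runif(50, 0.2, 0.4)
  f <- fake_fit(eta, s2, y)
  ll <- pointwise_loglik(f)
  perm <- sample(50)
  fp <- fake_fit(eta[perm, ], s2[perm], y)
  llp <- pointwise_loglik(fp)
  expect_equal(compute_waic(ll), compute_waic(llp), tolerance = 1e-12)
  expect_equal(compute_cpo_ls(ll)$ls, compute_cpo_ls(llp)$ls, tolerance = 1e-12)
  expect_equal(compute_dic(ll, f)$dic, compute_dic(llp, fp)$dic, tolerance = 1e-10)
})

test_that("R-squared matches the 1 - SSE/SST definition and is clamped", {
  y <- c(1, 2, 3, 4)
  f_perfect <- fake_fit(matrix(rep(y, each = 5), 5, 4), rep(0.1, 5), y)
  expect_equal(compute_r2(f_perfect), 1)
  f_null <- fake_fit(matrix(mean(y), 5, 4), rep(0.1, 5), y)
  expect_equal(compute_r2(f_null), 0)
  # printed 4-cell toy: fitted (1.2, 1.8, 3.1, 3.9)
  fit4 <- c(1.2, 1.8, 3.1, 3.9)
  f4 <- fake_fit(matrix(rep(fit4, each = 3), 3, 4), rep(0.1, 3), y)
  sse <- sum((y - fit4)^2); sst <- sum((y - mean(y))^2)
  expect_equal(compute_r2(f4), 1 - sse / sst, tolerance = 1e-12)
  f_bad <- fake_fit(matrix(10, 3, 4), rep(0.1, 3), y)
  expect_equal(compute_r2(f_bad), 0) # clamped at zero
  expect_error(compute_r2(fake_fit(matrix(1, 3, 4), rep(0.1, 3), rep(2, 4))),
               "zero variance")
})

test_that("the true model scores a lower log score than a noise-only model", {
  wins <- 0L
  for (seed in 1:10) {
    panel <- preprocess_panel(toy_raw_panel(I = 6, T_ = 5, beta = c(0.8),
                                            sigma = 0.2, seed = seed))
    g <- chain_graph(panel$area_ids)
    f_true <- fit_gibbs(build_model(stvc_model_spec(1, panel), panel, g),
                        quick_mcmc(iter = 300, burnin = 150, seed = seed))
    f_null <- fit_gibbs(intercept_only_design(panel),
                        quick_mcmc(iter = 300, burnin = 150, seed = seed))
    ls_true <- compute_cpo_ls(pointwise_loglik(f_true))$ls
    ls_null <- compute_cpo_ls(pointwise_loglik(f_null))$ls
    if (ls_true < ls_null) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the comparison table flags winners per criterion", {
  s1 <- structure(list(model_id = 1, dic = 10, waic = 11, p_dic = 2, p_waic = 2.5,
                       ls = 0.5, r2 = 0.9, n_unstable_cpo = 0), class = "model_scorecard")
  s2 <- structure(list(model_id = 2, dic = 20, waic = 21, p_dic = 4, p_waic = 5,
                       ls = 0.9, r2 = 0.5, n_unstable_cpo = 0), class = "model_scorecard")
  tab <- compare_models(list(s1, s2))
  expect_equal(tab$model, c(1, 2)) # input order preserved
  expect_true(all(unlist(tab[1, grep("^best_", names(tab))])))
  expect_false(any(unlist(tab[2, grep("^best_", names(tab))])))
  expect_error(compare_models(list(s1)), "at least two")
})
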