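test_that("the intercept-only posterior mean matches the sample mean of log y", {
  panel <- preprocess_panel(toy_raw_panel(I = 8, T_ = 5, beta = 0.2,
                                          sigma = 0.15, seed = 2))
  d <- intercept_only_design(panel)
  fit <- fit_gibbs(d, quick_mcmc(iter = 1500, burnin = 500, seed = 4))
  zbar <- mean(panel$y)
  draws <- fit$draws$beta0[, 1]
  mcse <- sd(draws) / sqrt(length(draws) / 10) # generous autocorrelation margin
  expect_lt(abs(mean(draws) - zbar), 3 * mcse + 1e-3)
})

test_that("identical seed and config give an identical draw history", {
  fx <- generate_panel(sim_config(rows = 3, cols = 3, n_years = 4, n_se = 2,
                                  n_ex = 0, n_time_invariant = 0, seed = 6))
  panel <- preprocess_panel(fx$panel)
  d <- build_model(stvc_model_spec(5, panel), panel, fx$graph)
  f1 <- fit_gibbs(d, quick_mcmc(iter = 200, burnin = 100, seed = 11))
  f2 <- fit_gibbs(d, quick_mcmc(iter = 200, burnin = 100, seed = 11))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$sigma2, f2$sigma2)
  f3 <- fit_gibbs(d, quick_mcmc(iter = 200, burnin = 100, seed = 12))
  expect_false(identical(f1$sigma2, f3$sigma2))
})

test_that("constrained blocks sum to zero in every stored draw", {
  fx <- generate_panel(sim_config(rows = 4, cols = 4, n_years = 6, n_se = 2,
                                  n_ex = 1, n_time_invariant = 0,
                                  si_scale = 0.2, ti_scale = 0.1, seed = 8))
  panel <- preprocess_panel(fx$panel)
  f2 <- fit_gibbs(build_model(stvc_model_spec(2, panel), panel, fx$graph),
                  quick_mcmc(iter = 300, burnin = 150, seed = 3))
  expect_lt(max(abs(rowSums(f2$draws$si))), 1e-8)
  expect_lt(max(abs(rowSums(f2$draws$ti))), 1e-8)
  f5 <- fit_gibbs(build_model(stvc_model_spec(5, panel), panel, fx$graph),
                  quick_mcmc(iter = 300, burnin = 150, seed = 3))
  for (nm in grep("^tc_", names(f5$draws), value = TRUE)) {
    expect_lt(max(abs(rowSums(f5$draws[[nm]]))), 1e-8)
  }
  expect_true(all(vapply(f5$draws, function(m) all(is.finite(m)), TRUE)))
})

test_that("the stored predictor agrees with the predictor recomputed from draws", {
  fx <- generate_panel(sim_config(rows = 3, cols = 4, n_years = 5, n_se = 2,
                                  n_ex = 0, n_time_invariant = 0, seed = 10))
  panel <- preprocess_panel(fx$panel)
  d <- build_model(stvc_model_spec(5, panel), panel, fx$graph)
  fit <- fit_gibbs(d, quick_mcmc(iter = 250, burnin = 150, seed = 5))
  for (s in c(1, 50, 200)) {
    state <- lapply(fit$draws, function(m) m[s, ])
    eta <- linear_predictor(d, state)
    expect_lt(max(abs(as.vector(eta) - fit$eta[s, ])), 1e-8)
  }
})

test_that("models 1 and 5 agree on the predictive mean when the truth is stationary", {
  fx <- generate_panel(sim_config(rows = 5, cols = 5, n_years = 6, n_se = 2,
                                  n_ex = 0, n_time_invariant = 0,
                                  sc_scale = 0, tc_scale = 0, sigma_obs = 0.15,
                                  missing_frac = 0, seed = 14))
  panel <- preprocess_panel(fx$panel)
  f1 <- fit_gibbs(build_model(stvc_model_spec(1, panel), panel, fx$graph),
                  quick_mcmc(iter = 400, burnin = 200, seed = 2))
  f5 <- fit_gibbs(build_model(stvc_model_spec(5, panel), panel, fx$graph),
                  quick_mcmc(iter = 400, burnin = 200, seed = 2))
  rmse <- sqrt(mean((colMeans(f1$eta) - colMeans(f5$eta))^2))
  expect_lt(rmse, 0.06) # both near the common (flat) truth
})

test_that("missing cells are imputed and diagnostics are reported", {
  fx <- generate_panel(sim_config(rows = 4, cols = 4, n_years = 5, n_se = 2,
                                  n_ex = 0, n_time_invariant = 0,
                                  missing_frac = 0.2, seed = 20))
  panel <- preprocess_panel(fx$panel)
  fit <- fit_gibbs(build_model(stvc_model_spec(4, panel), panel, fx$graph),
                   quick_mcmc(iter = 300, burnin = 150, seed = 9))
  expect_equal(ncol(fit$loglik), sum(!is.na(panel$y)))
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(is.logical(fit$rhat_warning))
  expect_error(mcmc_config(chains = 1), "two chains")
})

test_that("posterior summaries report equal-tailed intervals and significance", {
  set.seed(33)
  S <- 1e5
  fake <- structure(list(
    draws = list(beta0 = matrix(rnorm(S), S, 1), pos = matrix(abs(rnorm(S)) + 0.1, S, 1)),
    sigma2 = rep(1, S),
    sigma2_field = matrix(numeric(0), S, 0)
  ), class = "stvc_fit")
  ps <- posterior_summary(fake)
  b0 <- ps[ps$block == "beta0", ]
  expect_equal(b0$lower, -1.96, tolerance = 0.02)
  expect_equal(b0$upper, 1.96, tolerance = 0.02)
  expect_false(b0$significant)
  expect_true(ps[ps$block == "pos", "significant"])
  # degenerate draws: point mass
  fake2 <- structure(list(
    draws = list(beta0 = matrix(3.2, 50, 1)),
    sigma2 = rep(1, 50), sigma2_field = matrix(numeric(0), 50, 0)
  ), class = "stvc_fit")
  ps2 <- posterior_summary(fake2)
  expect_equal(ps2$mean[1], 3.2)
  expect_equal(ps2$sd[1], 0)
  expect_equal(ps2$lower[1], 3.2)
  expect_equal(ps2$upper[1], 3.2)
})
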