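# shared fixtures: all built in code, nothing on disk

path3_graph <- function() {
  area_graph(c("a", "b", "c"), list("b", c("a", "c"), "b"))
}

# random symmetric graph with edge probability p (may contain isolated nodes)
random_graph <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  ids <- sprintf("r%03d", seq_len(n))
  area_graph(ids, lapply(seq_len(n), function(i) ids[which(A[i, ] == 1L)]))
}

# a small raw panel built directly: log y = b0 + X %*% beta + noise
toy_raw_panel <- function(I = 10, T_ = 5, beta = c(0.5, -0.3), b0 = 3,
                          sigma = 0.1, seed = 1) {
  set.seed(seed)
  P <- length(beta)
  X <- array(stats::rnorm(I * T_ * P), c(I, T_, P))
  eta <- matrix(b0, I, T_)
  for (p in seq_len(P)) eta <- eta + X[, , p] * beta[p]
  y <- exp(eta + matrix(stats::rnorm(I * T_, 0, sigma), I, T_))
  panel_data(sprintf("a%02d", seq_len(I)), seq_len(T_), y, X,
             paste0("SE", seq_len(P)))
}

# path graph over a given id set (canonical sorted order)
chain_graph <- function(ids) {
  ids <- sort(as.character(ids))
  n <- length(ids)
  nb <- lapply(seq_len(n), function(i) ids[setdiff(c(i - 1L, i + 1L), c(0L, n + 1L))])
  area_graph(ids, nb)
}

# intercept-only design (flat prior on a single global mean)
intercept_only_design <- function(panel) {
  d <- build_model(stvc_model_spec(4, panel), panel, chain_graph(panel$area_ids))
  d$blocks <- d$blocks["beta0"]
  d
}

quick_mcmc <- function(iter = 400, burnin = 200, seed = 1) {
  mcmc_config(chains = 2, iter = iter, burnin = burnin, seed = seed)
}

# the study-condition generator settings used by the recovery experiments:
# 10 x 10 lattice, 10 years, 3 time-varying covariates at default scales
recovery_config <- function(seed) {
  sim_config(rows = 10, cols = 10, n_years = 10, n_se = 3, n_ex = 0,
             n_time_invariant = 0, seed = seed)
}
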