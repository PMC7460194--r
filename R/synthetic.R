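#' Synthetic areal panels with known ground truth
#'
#' The generator emulates the statistical structure of a county-by-year
#' healthcare-resource panel: a planar contiguity graph, correlated
#' standardized covariates in a socioeconomic and an environmental block (some
#' environmental ones constant over time), spatially autocorrelated true
#' coefficient surfaces, smooth temporal coefficient paths, and a positive
#' log-Gaussian response with missing cells. Every latent quantity is recorded
#' so parameter recovery and model comparison are testable without real data.
#'
#' @name synthetic
NULL

# eigen factor for sampling a zero-mean GMRF with covariance proportional to
# the pseudo-inverse of Q, restricted to the per-component sum-to-zero subspace
#' @noRd
gmrf_sample_factor <- function(spec) {
  Qd <- as.matrix(spec$Q)
  E <- eigen(Qd, symmetric = TRUE)
  keep <- E$values > max(E$values) * 1e-9
  V <- E$vectors[, keep, drop = FALSE]
  lam <- E$values[keep]
  # average marginal variance of the unit-sigma2 constrained field
  mvar <- rowSums(sweep(V^2, 2, lam, "/"))
  free <- setdiff(seq_len(spec$dim), spec$pinned)
  list(V = V, lam = lam, avg_var = mean(mvar[free]))
}

#' Draw spatially autocorrelated fields from the constrained intrinsic CAR
#'
#' Samples from the ICAR distribution restricted to the sum-to-zero subspace of
#' each connected component (via eigendecomposition of the structure matrix),
#' with the covariance normalized so the average marginal standard deviation
#' across areas equals `scale`. Isolated areas are set to zero, with a note.
#'
#' @param graph an [area_graph].
#' @param scale nonnegative target marginal standard deviation.
#' @param seed integer seed; draws are reproducible per (graph, scale, seed).
#' @param n_draws number of fields to draw.
#' @return A length-I vector (`n_draws = 1`) or an I x n_draws matrix.
#' @export
sample_icar_field <- function(graph, scale, seed = NULL, n_draws = 1) {
  stopifnot(inherits(graph, "area_graph"), scale >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n
  if (any(graph$m == 0L)) {
    message(sprintf("%d isolated area(s) set to 0", sum(graph$m == 0L)))
  }
  if (scale == 0) {
    out <- matrix(0, n, n_draws)
  } else {
    fac <- gmrf_sample_factor(icar_structure(graph))
    z <- matrix(stats::rnorm(ncol(fac$V) * n_draws), ncol(fac$V), n_draws)
    out <- fac$V %*% (z / sqrt(fac$lam)) * (scale / sqrt(fac$avg_var))
    out[graph$m == 0L, ] <- 0
  }
  if (n_draws == 1) as.vector(out) else out
}

#' Draw smooth temporal paths from a centered first-order random walk
#'
#' Cumulative sums of Normal(0, `scale`^2) increments, centered to sum to
#' zero. `scale` is the increment standard deviation; centering leaves the
#' increments untouched.
#'
#' @param T_ number of time points (>= 2).
#' @param scale nonnegative increment standard deviation.
#' @param seed integer seed.
#' @param n_draws number of paths.
#' @return A length-T vector (`n_draws = 1`) or a T x n_draws matrix.
#' @export
sample_rw1_path <- function(T_, scale, seed = NULL, n_draws = 1) {
  if (T_ < 2) stopf("RW1 path needs at least two time points")
  stopifnot(scale >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, T_, n_draws)
  if (scale > 0) {
    inc <- matrix(stats::rnorm(T_ * n_draws, 0, scale), T_, n_draws)
    out <- apply(inc, 2, cumsum)
    out <- sweep(out, 2, colMeans(out))
  }
  if (n_draws == 1) as.vector(out) else out
}

#' Generator settings
#'
#' Defaults are a miniature of the study conditions the models target: a
#' 10 x 10 lattice (100 areas) observed over 10 years, five socioeconomic and
#' five environmental covariates of which two environmental ones are
#' time-invariant, spatially autocorrelated true space-coefficients (marginal
#' sd `sc_scale`), smooth true time-coefficients (RW1 increment sd
#' `tc_scale`), log-scale observation noise sd `sigma_obs`, and 5% of response
#' cells missing completely at random. `beta0` puts the median response near
#' 30 per 10,000 — a realistic resource density.
#'
#' @param rows,cols lattice dimensions.
#' @param n_years number of time points.
#' @param n_se,n_ex socioeconomic / environmental covariate counts.
#' @param n_time_invariant how many EX covariates are constant over time.
#' @param rho AR(1) cross-correlation between adjacent covariate columns
#'   (exercises the collinearity the VIF screen exists for).
#' @param sc_scale,tc_scale,si_scale,ti_scale field scales (0 disables).
#' @param beta0 global intercept on the log-response scale.
#' @param sigma_obs observation noise sd (log scale).
#' @param missing_frac fraction of response cells masked missing (< 1).
#' @param misspecified_sc if `TRUE`, true SC fields are iid Gaussian instead
#'   of ICAR draws (robustness probe).
#' @param seed integer root seed.
#' @export
sim_config <- function(rows = 10, cols = 10, n_years = 10,
                       n_se = 5, n_ex = 5, n_time_invariant = 2,
                       rho = 0.4, sc_scale = 0.3, tc_scale = 0.1,
                       si_scale = 0, ti_scale = 0,
                       beta0 = log(30), sigma_obs = 0.2,
                       missing_frac = 0.05, misspecified_sc = FALSE,
                       seed = 1) {
  if (missing_frac >= 1) stopf("missing_frac must be < 1")
  if (n_se + n_ex < 1) stopf("need at least one covariate")
  if (n_time_invariant > n_ex) stopf("n_time_invariant cannot exceed n_ex")
  as.list(environment())
}

#' Generate a synthetic panel and its ground truth
#'
#' Assembles the log response as
#' `beta0 + sum_p (SC[p,i] + TC[p,t]) * x[i,t,p] (+ SI[i] + TI[t]) + noise`
#' through the same predictor code path the models use, exponentiates so all
#' responses are positive, masks a fraction of cells, and de-standardizes the
#' covariates with cosmetic means/scales so preprocessing has real work to do.
#'
#' @param config a [sim_config()] list.
#' @return `list(panel = panel_data, graph = area_graph, truth)`, where
#'   `truth` (class `synthetic_truth`) records `beta0`, `sc_fields` (I x P),
#'   `tc_paths` (T x P, `NA` columns for time-invariant covariates), optional
#'   `si_field`/`ti_path`, `sigma_obs`, the pre-noise predictor `eta`, the
#'   field scales and the seed. Truth coefficients are on the standardized
#'   covariate scale.
#' @export
generate_panel <- function(config = sim_config()) {
  set.seed(config$seed)
  graph <- make_lattice_graph(config$rows, config$cols)
  I <- graph$n; T_ <- config$n_years
  P <- config$n_se + config$n_ex
  names_p <- c(sprintf("SE%02d", seq_len(config$n_se)),
               sprintf("EX%02d", seq_len(config$n_ex)))
  blocks <- rep(c("SE", "EX"), c(config$n_se, config$n_ex))
  ti_flag <- rep(FALSE, P)
  if (config$n_time_invariant > 0) {
    ti_flag[P - seq_len(config$n_time_invariant) + 1L] <- TRUE
  }

  # correlated standardized covariates (Gaussian copula, AR(1) correlation)
  Sig <- config$rho^abs(outer(seq_len(P), seq_len(P), "-"))
  L <- chol(Sig)
  Z <- matrix(stats::rnorm(I * T_ * P), I * T_, P) %*% L
  X <- array(Z, c(I, T_, P))
  for (p in which(ti_flag)) X[, , p] <- X[, 1, p] # replicate year 1
  for (p in seq_len(P)) { # exact pooled standardization (population sd)
    v <- as.vector(X[, , p])
    X[, , p] <- (X[, , p] - mean(v)) / pop_sd(v)
  }

  # ground-truth coefficient fields and paths
  sc <- matrix(0, I, P, dimnames = list(graph$ids, names_p))
  for (p in seq_len(P)) {
    sc[, p] <- if (config$misspecified_sc) {
      stats::rnorm(I, 0, config$sc_scale)
    } else {
      sample_icar_field(graph, config$sc_scale)
    }
  }
  tc <- matrix(NA_real_, T_, P, dimnames = list(NULL, names_p))
  for (p in which(!ti_flag)) tc[, p] <- sample_rw1_path(T_, config$tc_scale)
  si <- if (config$si_scale > 0) sample_icar_field(graph, config$si_scale) else NULL
  ti_path <- if (config$ti_scale > 0) sample_rw1_path(T_, config$ti_scale) else NULL

  sc_list <- stats::setNames(lapply(seq_len(P), function(p) sc[, p]), as.character(seq_len(P)))
  tc_idx <- which(!ti_flag)
  tc_list <- stats::setNames(lapply(tc_idx, function(p) tc[, p]), as.character(tc_idx))
  eta <- predictor_core(X, beta0 = config$beta0, sc = sc_list,
                        tc = if (length(tc_list)) tc_list else NULL,
                        si = si, ti = ti_path)

  logy <- eta + matrix(stats::rnorm(I * T_, 0, config$sigma_obs), I, T_)
  y <- exp(logy)
  n_miss <- round(config$missing_frac * I * T_)
  if (n_miss > 0) y[sample(I * T_, n_miss)] <- NA_real_

  # cosmetic de-standardization so the emitted covariates carry units
  raw_mean <- stats::rnorm(P, 0, 2)
  raw_sd <- stats::runif(P, 0.5, 3)
  X_raw <- X
  for (p in seq_len(P)) X_raw[, , p] <- X[, , p] * raw_sd[p] + raw_mean[p]

  panel <- panel_data(graph$ids, seq_len(T_), y, X_raw, names_p,
                      blocks = blocks, time_invariant = ti_flag)
  truth <- structure(
    list(beta0 = config$beta0, sc_fields = sc, tc_paths = tc,
         si_field = si, ti_path = ti_path, sigma_obs = config$sigma_obs,
         eta = eta, field_scales = c(sc = config$sc_scale, tc = config$tc_scale,
                                     si = config$si_scale, ti = config$ti_scale),
         seed = config$seed),
    class = "synthetic_truth"
  )
  list(panel = panel, graph = graph, truth = truth)
}
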