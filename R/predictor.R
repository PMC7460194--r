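# Single source of the structured additive predictor
#
#   eta[i,t] = beta0 + sum_p beta_p x[i,t,p]            (global slopes)
#            + sum_p mu[p][i]  x[i,t,p]                 (space-coefficients SC)
#            + sum_p gamma[p][t] x[i,t,p]               (time-coefficients TC)
#            + xi[i] + psi[t]                           (space/time intercepts)
#
# Both the synthetic generator (evaluated at the recorded truth) and the model
# code (evaluated at a posterior draw) call this one routine, so the predictor
# algebra cannot drift between the two.

#' @noRd
predictor_core <- function(X, beta0 = 0, global = NULL, sc = NULL, tc = NULL,
                           si = NULL, ti = NULL) {
  I <- dim(X)[1]; T_ <- dim(X)[2]
  eta <- matrix(beta0, I, T_)
  if (!is.null(global)) {
    for (p in seq_along(global)) {
      if (global[[p]] != 0) eta <- eta + X[, , p] * global[[p]]
    }
  }
  if (!is.null(sc)) { # named list: covariate index -> length-I field
    for (nm in names(sc)) {
      p <- as.integer(nm)
      eta <- eta + X[, , p] * sc[[nm]]
    }
  }
  if (!is.null(tc)) { # named list: covariate index -> length-T path
    for (nm in names(tc)) {
      p <- as.integer(nm)
      eta <- eta + X[, , p] * matrix(tc[[nm]], I, T_, byrow = TRUE)
    }
  }
  if (!is.null(si)) eta <- eta + si
  if (!is.null(ti)) eta <- eta + matrix(ti, I, T_, byrow = TRUE)
  eta
}

#' Evaluate the structured additive linear predictor
#'
#' Computes the I x T predictor surface for one state (draw) of all latent
#' blocks of a model design.
#'
#' @param design a model design from [build_model()].
#' @param state a named list of block values, as stored per draw in a fit:
#'   one numeric vector per block name, with the block's dimension.
#' @return An I x T matrix.
#' @export
linear_predictor <- function(design, state) {
  stopifnot(inherits(design, "stvc_design"))
  X <- design$panel$X
  beta0 <- 0; global <- NULL; sc <- list(); tc <- list(); si <- NULL; ti <- NULL
  for (b in design$blocks) {
    v <- state[[b$name]]
    if (is.null(v)) stopf("state lacks block '%s'", b$name)
    if (length(v) != b$dim) stopf("block '%s' has length %d, expected %d", b$name, length(v), b$dim)
    switch(b$kind,
      intercept = { beta0 <- v },
      global = { beta0 <- v[1]; global <- v[-1] },
      sc = { sc[[as.character(b$cov)]] <- v },
      tc = { tc[[as.character(b$cov)]] <- v },
      si = { si <- v },
      ti = { ti <- v }
    )
  }
  predictor_core(X, beta0 = beta0, global = global,
                 sc = if (length(sc)) sc else NULL,
                 tc = if (length(tc)) tc else NULL,
                 si = si, ti = ti)
}
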