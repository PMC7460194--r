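#' Gaussian Markov random field prior structures
#'
#' The latent building blocks of the varying-coefficient models are improper
#' GMRFs defined through a sparse structure matrix `Q`:
#'
#' * the intrinsic CAR (Besag) prior on an areal graph, with
#'   `Q[i,i] = m_i` (neighbor count) and `Q[i,j] = -1` for adjacent areas,
#'   whose full conditional for area i is Normal(mean of neighbors, sigma2/m_i);
#' * the first-order random walk over time, penalizing squared successive
#'   differences, with tridiagonal `Q` = diag(1, 2, ..., 2, 1) off-diag -1.
#'
#' Both are rank-deficient (intrinsic): ICAR by one per connected component,
#' RW1 by one. The prior density is `exp(-x' Q x / (2 sigma2))`, invariant to
#' adding a constant within each component; identifiability in a model is
#' restored by sum-to-zero constraints where required.
#'
#' @name gmrf
NULL

#' @noRd
new_gmrf_spec <- function(Q, kind, component, rank_deficiency, constraint,
                          pinned = integer(0),
                          precision_prior = c(shape = 1, rate = 5e-5)) {
  structure(
    list(
      Q = Q, dim = nrow(Q), kind = kind, component = component,
      rank_deficiency = rank_deficiency, constraint = constraint,
      pinned = pinned, precision_prior = precision_prior
    ),
    class = "gmrf_spec"
  )
}

#' Intrinsic CAR structure matrix for an areal graph
#'
#' @param graph an [area_graph].
#' @param precision_prior Gamma (shape, rate) hyperprior on the field
#'   precision 1/sigma2; the diffuse default Gamma(1, 5e-5) is a common
#'   Bayesian areal-model choice.
#' @return A `gmrf_spec` with sparse `Q` (`Q[i,i] = m_i`, `Q[i,j] = -1` iff
#'   i ~ j), sum-to-zero constraint per connected component, rank deficiency
#'   equal to the number of components, and isolated areas pinned to zero.
#' @export
icar_structure <- function(graph, precision_prior = c(shape = 1, rate = 5e-5)) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n
  ii <- rep(seq_len(n), graph$m)
  jj <- unlist(graph$neighbors)
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n), ii), j = c(seq_len(n), jj),
    x = c(as.numeric(graph$m), rep(-1, length(ii))), dims = c(n, n)
  )
  new_gmrf_spec(Q, "icar", graph$component,
                rank_deficiency = max(graph$component),
                constraint = "sum-to-zero",
                pinned = which(graph$m == 0L),
                precision_prior = precision_prior)
}

#' First-order random-walk structure matrix
#'
#' @param T_ number of time points (>= 2).
#' @param precision_prior Gamma (shape, rate) hyperprior on 1/sigma2.
#' @return A `gmrf_spec` with tridiagonal `Q`, rank deficiency 1 and a
#'   sum-to-zero constraint.
#' @export
rw1_structure <- function(T_, precision_prior = c(shape = 1, rate = 5e-5)) {
  if (T_ < 2) stopf("RW1 needs at least two time points")
  d <- c(1, rep(2, T_ - 2), 1)
  Q <- Matrix::bandSparse(T_, k = c(-1, 0, 1),
                          diagonals = list(rep(-1, T_ - 1), d, rep(-1, T_ - 1)),
                          symmetric = FALSE)
  new_gmrf_spec(Q, "rw1", rep(1L, T_), rank_deficiency = 1L,
                constraint = "sum-to-zero", precision_prior = precision_prior)
}

#' Unnormalized GMRF log-density
#'
#' `-x' Q x / (2 sigma2)`; improper (unchanged by per-component constant
#' shifts).
#'
#' @param x numeric vector matching the spec dimension.
#' @param spec a `gmrf_spec`.
#' @param sigma2 positive variance component.
#' @export
gmrf_log_density <- function(x, spec, sigma2) {
  stopifnot(inherits(spec, "gmrf_spec"))
  if (length(x) != spec$dim) stopf("x has length %d, spec dimension is %d", length(x), spec$dim)
  -as.numeric(x %*% (spec$Q %*% x)) / (2 * sigma2)
}

#' Full conditional of one area under the intrinsic CAR prior
#'
#' Given the values of all other areas, area `i` is Normal with mean the
#' average of its neighbors' values and variance `sigma2 / m_i`.
#'
#' @param values length-I field vector.
#' @param i area index.
#' @param graph an [area_graph].
#' @param sigma2 positive variance component.
#' @return list(mean, variance).
#' @export
icar_full_conditional <- function(values, i, graph, sigma2) {
  stopifnot(inherits(graph, "area_graph"))
  if (graph$m[i] == 0L) stopf("area %d is isolated; its CAR full conditional is undefined", i)
  list(mean = mean(values[graph$neighbors[[i]]]), variance = sigma2 / graph$m[i])
}

#' Center a vector to zero mean per component
#'
#' Subtracts the mean within each connected component; the workhorse of the
#' sum-to-zero identifiability constraints.
#'
#' @param x numeric vector.
#' @param spec a `gmrf_spec` carrying component labels.
#' @export
apply_sum_to_zero <- function(x, spec) {
  stopifnot(inherits(spec, "gmrf_spec"))
  if (length(x) != spec$dim) stopf("dimension mismatch")
  x - stats::ave(x, spec$component)
}

#' Export a GMRF structure matrix as MatrixMarket
#'
#' @param spec a `gmrf_spec`.
#' @param path output `.mtx` path.
#' @export
write_structure_mtx <- function(spec, path) {
  Matrix::writeMM(methods::as(spec$Q, "CsparseMatrix"), path)
  invisible(path)
}
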