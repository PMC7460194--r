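#' Downstream products of a fitted model
#'
#' Tables of posterior time-coefficient paths and space-coefficient surfaces,
#' Getis-Ord hot-spot classification of areal surfaces, and complete
#' model-estimated response maps (including missing cells) on the original
#' measurement scale.
#'
#' @name spatial_summaries
NULL

#' Posterior time-coefficient table
#'
#' One row per (covariate, year) with the posterior mean and equal-tailed
#' credible band of the temporal coefficient path, on the standardized
#' covariate scale.
#'
#' @param fit an [fit_gibbs()] result from a model with TC blocks (3 or 5).
#' @param level credibility level.
#' @export
extract_tc_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "stvc_fit"))
  tc_blocks <- Filter(function(b) b$kind == "tc", fit$design$blocks)
  if (!length(tc_blocks)) stopf("model %d has no time-coefficient blocks", fit$design$spec$model_id)
  al <- (1 - level) / 2
  years <- fit$design$panel$years
  out <- lapply(tc_blocks, function(b) {
    m <- fit$draws[[b$name]]
    data.frame(
      covariate = fit$design$panel$covariate_names[b$cov],
      year = years,
      mean = colMeans(m),
      sd = apply(m, 2, stats::sd),
      lower = apply(m, 2, stats::quantile, al),
      upper = apply(m, 2, stats::quantile, 1 - al)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior space-coefficient table
#'
#' One row per (covariate, area), joinable to external geometries by
#' `area_id`; area order is the canonical panel order.
#'
#' @param fit an [fit_gibbs()] result from a model with SC blocks (4 or 5).
#' @param level credibility level.
#' @export
extract_sc_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "stvc_fit"))
  sc_blocks <- Filter(function(b) b$kind == "sc", fit$design$blocks)
  if (!length(sc_blocks)) stopf("model %d has no space-coefficient blocks", fit$design$spec$model_id)
  al <- (1 - level) / 2
  out <- lapply(sc_blocks, function(b) {
    m <- fit$draws[[b$name]]
    data.frame(
      covariate = fit$design$panel$covariate_names[b$cov],
      area_id = fit$design$panel$area_ids,
      mean = colMeans(m),
      sd = apply(m, 2, stats::sd),
      lower = apply(m, 2, stats::quantile, al),
      upper = apply(m, 2, stats::quantile, 1 - al)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Getis-Ord Gi* hot-spot classification of an areal surface
#'
#' Local Gi* with self-inclusive binary contiguity weights: for each area the
#' neighborhood sum (neighbors plus self) is compared with its expectation
#' under the global mean, standardized by the usual Gi* denominator. Areas are
#' classified by |z| thresholds 1.645 / 1.960 / 2.576 (90/95/99%) and sign
#' into hot/cold classes. A constant surface yields z = 0 everywhere and all
#' areas not-significant, with a warning.
#'
#' @param values length-I numeric areal surface.
#' @param graph the matching [area_graph].
#' @param thresholds the three |z| cutoffs.
#' @return An object of class `hotspot_result`: data.frame (area_id, z,
#'   class) with class levels hot-99/hot-95/hot-90/not-significant/
#'   cold-90/cold-95/cold-99.
#' @export
getis_ord_gstar <- function(values, graph,
                            thresholds = c(1.645, 1.960, 2.576)) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n
  if (length(values) != n) stopf("values must have length %d", n)
  if (n < 2) stopf("need at least two areas")
  xbar <- mean(values)
  s <- sqrt(sum(values^2) / n - xbar^2)
  if (s < 1e-12) {
    warnf("constant surface: all areas not-significant")
    z <- rep(0, n)
  } else {
    w <- graph$m + 1
    nbsum <- vapply(seq_len(n), function(i) {
      sum(values[c(i, graph$neighbors[[i]])])
    }, 0)
    z <- (nbsum - xbar * w) / (s * sqrt((n * w - w^2) / (n - 1)))
  }
  lev <- c("cold-99", "cold-95", "cold-90", "not-significant",
           "hot-90", "hot-95", "hot-99")
  cls <- cut(z, breaks = c(-Inf, -rev(thresholds), thresholds, Inf),
             labels = lev, right = FALSE)
  structure(
    data.frame(area_id = graph$ids, z = z, class = factor(cls, levels = lev)),
    class = c("hotspot_result", "data.frame")
  )
}

#' Model-estimated response surfaces on the original scale
#'
#' The posterior mean of the response at every cell — observed or missing —
#' back-transformed from the log scale with the full log-normal mean
#' `mean over draws of exp(eta + sigma2/2)` (unbiased on the original scale,
#' unlike exponentiating the posterior-mean predictor). Credible surfaces are
#' equal-tailed quantiles of the per-draw cell means.
#'
#' @param fit an [fit_gibbs()] result.
#' @param panel the fitted [panel_data].
#' @param level credibility level.
#' @return list(mean, lower, upper): I x T matrices with area/year dimnames,
#'   on the original beds-per-10,000-style scale.
#' @export
estimate_response_maps <- function(fit, panel = fit$design$panel, level = 0.95) {
  stopifnot(inherits(fit, "stvc_fit"))
  al <- (1 - level) / 2
  I <- length(panel$area_ids); T_ <- length(panel$years)
  cellmean <- exp(fit$eta + fit$sigma2 / 2) # recycles sigma2 over draws
  mk <- function(v) matrix(v, I, T_, dimnames = list(panel$area_ids, panel$years))
  list(
    mean = mk(colMeans(cellmean)),
    lower = mk(apply(cellmean, 2, stats::quantile, al)),
    upper = mk(apply(cellmean, 2, stats::quantile, 1 - al))
  )
}
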