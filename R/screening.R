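#' Progressive covariate screening
#'
#' Two screening steps reduce a large candidate covariate set to the modelling
#' set: (1) an iterative variance-inflation-factor filter applied within each
#' covariate block (socioeconomic and environmental separately), repeatedly
#' dropping the worst offender until all VIFs are at or below the threshold
#' (default 5, the strict convention); (2) a regression random forest ranks
#' the survivors by impurity importance (MDI) and permutation importance
#' (MDA), and the intersection of the two top-k sets is selected.
#'
#' @name screening
NULL

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from the least-squares regression of
#' column j on all other columns plus an intercept. Perfectly collinear
#' columns report `Inf` rather than erroring.
#'
#' @param X numeric n x p matrix or data.frame, n > p >= 2, no constant
#'   columns.
#' @return Length-p named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stopf("VIF needs at least two columns")
  if (n <= p) stopf("VIF needs more rows than columns")
  if (any(apply(X, 2, stats::sd) < 1e-12)) stopf("constant column: VIF undefined")
  vif <- numeric(p)
  for (j in seq_len(p)) {
    yj <- X[, j]
    fitj <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fitj$residuals^2) / sum((yj - mean(yj))^2)
    vif[j] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  names(vif) <- colnames(X)
  vif
}

#' Iterative within-block VIF filter
#'
#' Within each block independently: compute VIFs; while the largest exceeds
#' the threshold, drop the covariate with the largest VIF (ties broken toward
#' the one later in canonical order) and recompute. A block reduced to a
#' single covariate retains it unconditionally (VIF is undefined for p = 1).
#' Every elimination round is logged.
#'
#' @param X n x p covariate matrix with column names.
#' @param threshold VIF threshold (> 1); default 5.
#' @param block_labels length-p block labels (e.g. "SE"/"EX"); a single block
#'   by default.
#' @return list(retained = named list of survivor vectors per block,
#'   vif_table = data.frame logging round/block/covariate/vif/dropped).
#' @export
iterative_vif_filter <- function(X, threshold = 5, block_labels = NULL) {
  X <- as.matrix(X)
  if (threshold <= 1) stopf("threshold must exceed 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  block_labels <- block_labels %||% rep("all", ncol(X))
  log_rows <- list()
  retained <- list()
  for (blk in unique(block_labels)) {
    cols <- colnames(X)[block_labels == blk]
    round <- 0L
    while (TRUE) {
      round <- round + 1L
      if (length(cols) == 1L) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          round = round, block = blk, covariate = cols, vif = NA_real_,
          dropped = FALSE)
        break
      }
      vif <- compute_vif(X[, cols, drop = FALSE])
      worst <- max(vif)
      drop_j <- if (worst > threshold) max(which(vif == worst)) else NA_integer_
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        round = round, block = blk, covariate = cols, vif = unname(vif),
        dropped = seq_along(cols) %in% drop_j)
      if (is.na(drop_j)) break
      cols <- cols[-drop_j]
    }
    retained[[blk]] <- cols
  }
  list(retained = retained, vif_table = do.call(rbind, log_rows))
}

#' Random-forest covariate importance
#'
#' Fits a regression random forest and reports mean decrease in impurity
#' (variance-reduction importance, normalized to sum to one) and mean decrease
#' in accuracy (mean increase in out-of-bag squared error when the feature is
#' permuted, unscaled, averaged over `n_perm` permutation repeats).
#' Deterministic under `seed`.
#'
#' @param X n x p covariate matrix (n >= 30).
#' @param y length-n continuous response.
#' @param n_trees trees in the forest.
#' @param n_perm out-of-bag permutation repeats per feature.
#' @param seed integer seed.
#' @return list(mdi, mda): named length-p numeric vectors.
#' @export
forest_importance <- function(X, y, n_trees = 500, n_perm = 10, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 30) stopf("forest importance needs at least 30 rows")
  if (stats::sd(y) < 1e-12) stopf("constant response")
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = max(1L, ceiling(ncol(X) / 3)),
    importance = TRUE, nPerm = n_perm
  )
  imp <- randomForest::importance(rf, scale = FALSE)
  mdi <- imp[, "IncNodePurity"]
  list(mdi = mdi / sum(mdi), mda = imp[, "%IncMSE"])
}

#' Select covariates by top-k intersection of two importance rankings
#'
#' Returns the covariates in both the top-k by MDI and the top-k by MDA,
#' ordered by mean rank (ties in either ranking broken by the other indicator,
#' then input order). An empty intersection is returned with a warning.
#'
#' @param mdi,mda named importance vectors over the same covariates.
#' @param k top set size (<= number of covariates).
#' @export
select_covariates <- function(mdi, mda, k) {
  stopifnot(length(mdi) == length(mda), !is.null(names(mdi)))
  p <- length(mdi)
  if (k > p) stopf("k cannot exceed the number of covariates")
  mda <- mda[names(mdi)]
  ord_mdi <- order(-mdi, -mda, seq_len(p))
  ord_mda <- order(-mda, -mdi, seq_len(p))
  r_mdi <- match(seq_len(p), ord_mdi)
  r_mda <- match(seq_len(p), ord_mda)
  top <- intersect(names(mdi)[ord_mdi[seq_len(k)]], names(mdi)[ord_mda[seq_len(k)]])
  if (!length(top)) {
    warnf("top-%d MDI and MDA sets are disjoint; empty selection", k)
    return(character(0))
  }
  mr <- (r_mdi + r_mda)[match(top, names(mdi))] / 2
  top[order(mr, match(top, names(mdi)))]
}

#' Full two-step screening of a panel's covariates
#'
#' Pools all observed (area, year) rows (one observation each), runs the
#' iterative VIF filter within the SE and EX blocks separately, then ranks the
#' survivors with a random forest against the log response and selects the
#' top-k intersection.
#'
#' @param panel a preprocessed [panel_data].
#' @param vif_threshold VIF cut (default 5).
#' @param k top set size; default half the survivor count, rounded up.
#' @param n_trees,n_perm,seed forest settings.
#' @return An object of class `screening_result`: list(vif_table,
#'   retained_after_vif, mdi, mda, selected, config).
#' @export
screen_covariates <- function(panel, vif_threshold = 5, k = NULL,
                              n_trees = 500, n_perm = 10, seed = 1) {
  stopifnot(inherits(panel, "panel_data"))
  if (!panel$log_response) stopf("panel must be preprocessed before screening")
  obs <- which(!is.na(panel$y))
  P <- length(panel$covariate_names)
  Xmat <- matrix(panel$X, ncol = P,
                 dimnames = list(NULL, panel$covariate_names))[obs, , drop = FALSE]
  yv <- panel$y[obs]
  vf <- iterative_vif_filter(Xmat, vif_threshold, panel$blocks)
  kept <- unlist(vf$retained, use.names = FALSE)
  kept <- panel$covariate_names[panel$covariate_names %in% kept] # canonical order
  k <- k %||% ceiling(length(kept) / 2)
  imp <- forest_importance(Xmat[, kept, drop = FALSE], yv,
                           n_trees = n_trees, n_perm = n_perm, seed = seed)
  selected <- select_covariates(imp$mdi, imp$mda, k)
  structure(
    list(vif_table = vf$vif_table, retained_after_vif = vf$retained,
         mdi = imp$mdi, mda = imp$mda, selected = selected,
         config = list(vif_threshold = vif_threshold, k = k,
                       n_trees = n_trees, n_perm = n_perm, seed = seed)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> %d retained after VIF (threshold %g), %d selected (top-%d intersection)\n",
    length(unlist(x$retained_after_vif)), x$config$vif_threshold,
    length(x$selected), x$config$k
  ))
  if (length(x$selected)) cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
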