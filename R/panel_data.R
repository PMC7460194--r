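#' Space-time panel data
#'
#' A `panel_data` object holds an areal space-time observation table: a
#' response matrix `y` (areas x years, `NA` marking missing cells), a covariate
#' array `X` (areas x years x covariates), covariate block labels
#' (`"SE"` socioeconomic, `"EX"` environmental), time-invariance flags, and the
#' standardization metadata recorded by [preprocess_panel()].
#'
#' The motivating application is county-level hospital beds per 10,000 people
#' observed over a decade, modelled on the log scale with z-scored covariates.
#'
#' @param area_ids character area identifiers (will be sorted canonically).
#' @param years sorted vector of time labels.
#' @param y numeric I x T matrix, positive where observed, `NA` where missing.
#' @param X numeric I x T x P array of covariates (no missing values).
#' @param covariate_names length-P character.
#' @param blocks length-P character, each `"SE"` or `"EX"`.
#' @param time_invariant optional logical length-P; auto-detected when `NULL`.
#' @param log_response has `y` already been log-transformed?
#' @param standardization `NULL`, or a data.frame (covariate, mean, sd)
#'   recording the z-score applied to each covariate.
#' @return An object of class `panel_data`.
#' @export
panel_data <- function(area_ids, years, y, X, covariate_names,
                       blocks = NULL, time_invariant = NULL,
                       log_response = FALSE, standardization = NULL) {
  area_ids <- as.character(area_ids)
  I <- length(area_ids)
  T_ <- length(years)
  y <- as.matrix(y)
  if (!all(dim(y) == c(I, T_))) stopf("y must be %d x %d", I, T_)
  if (length(dim(X)) != 3L || !all(dim(X)[1:2] == c(I, T_))) {
    stopf("X must be an %d x %d x P array", I, T_)
  }
  P <- dim(X)[3]
  if (length(covariate_names) != P) stopf("covariate_names must have length %d", P)
  if (anyNA(X)) stopf("covariates must be complete (missing covariate cells are an error)")
  blocks <- blocks %||% ifelse(grepl("^EX", covariate_names, ignore.case = TRUE), "EX", "SE")
  if (!all(blocks %in% c("SE", "EX"))) stopf("blocks must be 'SE' or 'EX'")
  if (!log_response && any(y[!is.na(y)] <= 0)) {
    stopf("response must be positive at observed cells (a log transform is applied downstream)")
  }
  ord <- order(area_ids)
  y <- y[ord, , drop = FALSE]
  X <- X[ord, , , drop = FALSE]
  area_ids <- area_ids[ord]
  if (is.null(time_invariant)) time_invariant <- detect_time_invariant(X)
  dimnames(y) <- list(area_ids, years)
  dimnames(X) <- list(area_ids, years, covariate_names)
  structure(
    list(
      area_ids = area_ids, years = years, y = y, X = X,
      covariate_names = as.character(covariate_names),
      blocks = blocks, time_invariant = time_invariant,
      log_response = isTRUE(log_response), standardization = standardization
    ),
    class = "panel_data"
  )
}

#' @noRd
detect_time_invariant <- function(X) {
  apply(X, 3, function(m) all(abs(m - m[, 1]) < 1e-12))
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf(
    "<panel_data> %d areas x %d years, %d covariates (%d SE, %d EX, %d time-invariant)\n",
    length(x$area_ids), length(x$years), length(x$covariate_names),
    sum(x$blocks == "SE"), sum(x$blocks == "EX"), sum(x$time_invariant)
  ))
  cat(sprintf(
    "  response: %s, %d/%d cells observed\n",
    if (x$log_response) "log scale" else "original scale",
    sum(!is.na(x$y)), length(x$y)
  ))
  invisible(x)
}

#' Read a long-format panel CSV
#'
#' One row per (area, year); columns named through `schema`. Missing response
#' cells are encoded as empty/`NA` response values in present rows (they become
#' prediction targets); covariate values must be complete. A fully absent
#' (area, year) row is only accepted when every covariate is time-invariant, so
#' the covariates at that cell can be filled from the area's other years.
#'
#' @param path CSV path.
#' @param schema a list as returned by [panel_schema()].
#' @return A [panel_data] on the original (pre-transform) scale.
#' @export
read_panel_csv <- function(path, schema = panel_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema$area, schema$year, schema$response)
  if (!all(need %in% names(df))) {
    stopf("panel CSV lacks column(s): %s", paste(setdiff(need, names(df)), collapse = ", "))
  }
  covs <- schema$covariates %||% setdiff(names(df), need)
  if (!length(covs)) stopf("panel CSV has no covariate columns")
  if (anyDuplicated(df[, c(schema$area, schema$year)])) {
    stopf("duplicate (area, year) pair in panel CSV")
  }
  yv <- df[[schema$response]]
  if (any(!is.na(yv) & yv <= 0)) {
    stopf("nonpositive response value: the response is log-transformed and must be > 0")
  }
  if (anyNA(df[, covs])) stopf("covariates must be complete (missing covariate cells are an error)")
  areas <- sort(unique(as.character(df[[schema$area]])))
  years <- sort(unique(df[[schema$year]]))
  I <- length(areas); T_ <- length(years); P <- length(covs)
  ai <- match(as.character(df[[schema$area]]), areas)
  ti <- match(df[[schema$year]], years)
  y <- matrix(NA_real_, I, T_)
  y[cbind(ai, ti)] <- yv
  X <- array(NA_real_, c(I, T_, P))
  for (p in seq_len(P)) {
    m <- matrix(NA_real_, I, T_)
    m[cbind(ai, ti)] <- df[[covs[p]]]
    if (anyNA(m)) { # absent rows: fillable only for time-invariant covariates
      tiv <- all(apply(m, 1, function(r) length(unique(r[!is.na(r)])) <= 1L))
      if (!tiv || any(rowSums(!is.na(m)) == 0L)) {
        stopf(paste0(
          "covariate '%s' is undefined at absent (area, year) rows; ",
          "include those rows with an empty response instead"
        ), covs[p])
      }
      m <- matrix(apply(m, 1, function(r) r[!is.na(r)][1]), I, T_)
    }
    X[, , p] <- m
  }
  blocks <- schema$blocks %||% NULL
  panel_data(areas, years, y, X, covs, blocks = blocks)
}

#' Column mapping for [read_panel_csv()]
#'
#' @param area,year,response column names.
#' @param covariates covariate column names, or `NULL` for all other columns.
#' @param blocks optional per-covariate block labels; by default covariates
#'   whose name starts with `EX` are environmental and the rest socioeconomic.
#' @export
panel_schema <- function(area = "area_id", year = "year", response = "response",
                         covariates = NULL, blocks = NULL) {
  list(area = area, year = year, response = response,
       covariates = covariates, blocks = blocks)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel_csv()]: one row per (area, year), missing responses
#' written as empty cells.
#'
#' @param panel a [panel_data].
#' @param path output path.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "panel_data"))
  I <- length(panel$area_ids); T_ <- length(panel$years)
  df <- data.frame(
    area_id = rep(panel$area_ids, times = T_),
    year = rep(panel$years, each = I),
    response = as.vector(panel$y)
  )
  for (p in seq_along(panel$covariate_names)) {
    df[[panel$covariate_names[p]]] <- as.vector(panel$X[, , p])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Preprocess a panel: log response, z-score covariates
#'
#' Applies the preprocessing the models assume: the positive response is
#' replaced by its natural logarithm (so the log-Gaussian likelihood becomes
#' Gaussian), and each covariate is z-scored with a single mean and standard
#' deviation pooled over all space-time cells, so covariate contributions are
#' comparable on one dimensionless scale. Time-invariance flags are
#' re-detected. Idempotent on the covariate block; refuses to log-transform a
#' response that is already on the log scale.
#'
#' @param panel a raw [panel_data].
#' @return A [panel_data] with `log_response = TRUE` and `standardization`
#'   recording the per-covariate mean/sd (composed with any earlier z-score).
#' @export
preprocess_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  y <- panel$y
  if (!panel$log_response) {
    if (any(y[!is.na(y)] <= 0)) stopf("response must be positive to log-transform")
    y <- log(y)
  }
  P <- length(panel$covariate_names)
  mu <- numeric(P); sdv <- numeric(P)
  X <- panel$X
  for (p in seq_len(P)) {
    v <- as.vector(X[, , p])
    mu[p] <- mean(v)
    sdv[p] <- pop_sd(v)
    if (sdv[p] < 1e-12) stopf("covariate '%s' has zero variance; z-score undefined", panel$covariate_names[p])
    X[, , p] <- (X[, , p] - mu[p]) / sdv[p]
  }
  prev <- panel$standardization
  std <- data.frame(covariate = panel$covariate_names, mean = mu, sd = sdv,
                    stringsAsFactors = FALSE)
  if (!is.null(prev)) { # compose: x_new = (x_raw - (m0 + s0*m1)) / (s0*s1)
    std$mean <- prev$mean + prev$sd * mu
    std$sd <- prev$sd * sdv
  }
  panel_data(panel$area_ids, panel$years, y, X, panel$covariate_names,
             blocks = panel$blocks, log_response = TRUE, standardization = std)
}

# subset covariates by name, keeping panel metadata consistent
#' @export
#' @rdname panel_data
#' @param x a `panel_data`.
#' @param keep covariate names to retain.
subset_covariates <- function(x, keep) {
  stopifnot(inherits(x, "panel_data"))
  j <- match(keep, x$covariate_names)
  if (anyNA(j)) stopf("unknown covariate(s): %s", paste(keep[is.na(j)], collapse = ", "))
  std <- x$standardization
  if (!is.null(std)) std <- std[j, , drop = FALSE]
  panel_data(x$area_ids, x$years, x$y, x$X[, , j, drop = FALSE],
             x$covariate_names[j], blocks = x$blocks[j],
             time_invariant = x$time_invariant[j],
             log_response = x$log_response, standardization = std)
}
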