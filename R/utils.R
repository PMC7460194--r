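# Small numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise log-mean-exp of a draws x cells matrix
#' @noRd
col_log_mean_exp <- function(ll) {
  m <- apply(ll, 2, max)
  log(colMeans(exp(sweep(ll, 2, m)))) + m
}

# population standard deviation (divisor n): the z-score convention used for
# covariate standardization
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
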