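# MCMC convergence diagnostics shared by the regression and
# surplus-production samplers: split-chain potential scale reduction
# (R-hat) and effective sample size from per-chain autocorrelation.

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half before computing the classic
#' between-/within-chain variance ratio, so within-chain drift inflates
#' the statistic as well. Values near 1 indicate the chains sample the
#' same distribution; the package's samplers gate on R-hat < 1.05.
#'
#' @param chains numeric matrix, one column per chain (equal lengths).
#' @return R-hat, a scalar >= 1 (up to floating point).
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  if (n < 4) stop("need at least 4 draws per chain for split R-hat")
  half <- floor(n / 2)
  split_mat <- cbind(
    chains[seq_len(half), , drop = FALSE],
    chains[(n - half + 1):n, , drop = FALSE]
  )
  m <- ncol(split_mat)
  n2 <- nrow(split_mat)
  means <- colMeans(split_mat)
  vars <- apply(split_mat, 2, stats::var)
  w <- mean(vars)
  b <- n2 * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

#' Effective sample size across chains
#'
#' Sums per-chain effective sizes n / (1 + 2 * sum(rho_k)), truncating the
#' autocorrelation sum at the first negative autocorrelation (initial
#' positive sequence estimator).
#'
#' @param chains numeric matrix, one column per chain.
#' @return Estimated effective number of independent draws, total across
#'   chains.
#' @export
effective_size <- function(chains) {
  chains <- as.matrix(chains)
  per_chain <- apply(chains, 2, function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    neg <- which(rho < 0)
    if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
    n / (1 + 2 * sum(rho))
  })
  sum(per_chain)
}

# Apply both diagnostics to a draws array [iter x chain x param]; returns a
# tibble one row per parameter.
mcmc_diagnostics <- function(draws_array, param_names) {
  stats_list <- lapply(seq_along(param_names), function(j) {
    mat <- draws_array[, , j]
    tibble::tibble(
      parameter = param_names[j],
      rhat = split_rhat(mat),
      ess = effective_size(mat)
    )
  })
  dplyr::bind_rows(stats_list)
}
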