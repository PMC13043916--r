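#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-time estimator using Geyer's initial positive sequence:
#' `ESS = n / (-1 + 2 * sum Gamma_t)` where `Gamma_t = rho_{2t} + rho_{2t+1}`
#' summed while positive.
#'
#' @param x Numeric vector (one chain's trace of one parameter).
#' @return Effective sample size (at most `n`... up to noise).
#' @export
ess_mcmc <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(NA_real_)
  lag_max <- min(n - 2, 10000)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  tau <- 0
  t <- 0
  while (2 * t + 1 <= lag_max) {
    g <- rho[2 * t + 1] + rho[2 * t + 2]  # rho index is lag + 1
    if (g <= 0) break
    tau <- tau + 2 * g
    t <- t + 1
  }
  tau <- max(tau - 1, 1)
  n / tau
}

#' Split Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift also inflates the statistic). Values of 1-1.2
#' are expected for converged chains.
#'
#' @param chains List of numeric vectors (one per chain, equal lengths).
#' @return The split R-hat; `Inf` if chains have zero within-chain variance
#'   but differ between chains.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  n2 <- min(lengths(chains)) %/% 2
  if (n2 < 2) return(NA_real_)
  halves <- unlist(lapply(chains, function(x)
    list(x[seq_len(n2)], x[seq_len(n2) + n2])), recursive = FALSE)
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W == 0) return(if (B_over_n > 0) Inf else NA_real_)
  var_plus <- (n2 - 1) / n2 * W + B_over_n
  sqrt(var_plus / W)
}

#' MCMC diagnostics for a variable-rates posterior
#'
#' Per-parameter effective sample size (summed over chains) and split
#' Gelman-Rubin statistic for the regression coefficients, background rate,
#' lambda, scalar count and log-likelihood.
#'
#' @param vr A `"varrates"` fit.
#' @param ess_threshold,rhat_threshold Flagging thresholds (defaults 1000 and
#'   1.2).
#' @return Data frame with `parameter`, `ess`, `rhat`, `ok`.
#' @export
mcmc_diagnostics <- function(vr, ess_threshold = 1000, rhat_threshold = 1.2) {
  stopifnot(inherits(vr, "varrates"))
  pars <- c(vr$coef_names, "sigma2", "lambda", "n_scalars", "loglik")
  single <- length(vr$samples) < 2
  rows <- lapply(pars, function(p) {
    traces <- lapply(vr$samples, function(s) s[, p])
    ess <- sum(vapply(traces, ess_mcmc, 0), na.rm = TRUE)
    rhat <- if (single) NA_real_ else gelman_rubin(traces)
    data.frame(parameter = p, ess = ess, rhat = rhat,
               ok = ess >= ess_threshold &
                 (is.na(rhat) | rhat <= rhat_threshold))
  })
  do.call(rbind, rows)
}
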