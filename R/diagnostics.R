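#' Effective sample size of an MCMC draw sequence
#'
#' Autocorrelation-based ESS using Geyer's initial monotone sequence
#' estimator: autocorrelations are summed in consecutive pairs, truncated at
#' the first non-positive pair sum, and the pair sums are forced
#' non-increasing before summation. For a chain with integrated
#' autocorrelation time `tau`, ESS = n / tau.
#'
#' @param chain numeric vector of draws (length > 10).
#' @return scalar ESS; `NA` with a warning for a constant chain.
#' @export
ess <- function(chain) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n <= 10) stop("chain too short for ESS estimation")
  if (var(chain) == 0) {
    warning("constant chain: ESS is undefined")
    return(NA_real_)
  }
  lag_max <- min(n - 1, max(200, floor(10 * sqrt(n))))
  rho <- drop(stats::acf(chain, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  n_pairs <- floor(length(rho) / 2)
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  pos <- which(gam <= 0)
  if (length(pos) > 0) gam <- gam[seq_len(pos[1] - 1)]
  if (length(gam) == 0) return(n)  # immediate negative pair: ~white noise
  gam <- cummin(gam)
  tau <- max(-1 + 2 * sum(gam), 1 / n)
  n / tau
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(chains) {
  out <- list()
  for (ch in chains) {
    n <- length(ch)
    half <- floor(n / 2)
    out <- c(out, list(ch[seq_len(half)], ch[(n - half + 1):n]))
  }
  out
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws after
#' splitting each chain in half, so that both poor mixing between chains and
#' trends within chains inflate the statistic. Values near 1.00 indicate
#' convergence.
#'
#' @param chains a list of numeric draw vectors (>= 2 chains), or a matrix
#'   with one column per chain.
#' @return scalar R-hat; `NA` if the draws are constant.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2) stop("rhat requires at least 2 chains")
  pooled <- unlist(chains)
  if (var(pooled) == 0) return(NA_real_)
  z <- rank_normalize(pooled)
  lens <- vapply(chains, length, integer(1))
  idx <- rep(seq_along(chains), lens)
  zch <- split(z, idx)
  halves <- split_chains(zch)
  n <- min(vapply(halves, length, integer(1)))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Posterior summary of MCMC chains
#'
#' Per-parameter posterior mean, standard deviation, 2.5/50/97.5 percentiles
#' (the 95% credible interval), ESS summed over chains, and rank-normalized
#' split R-hat (reported when at least two chains are available).
#'
#' @param object an `scr_chains` from [run_mcmc()].
#' @param ... unused.
#' @return a data frame, one row per parameter.
#' @export
summary.scr_chains <- function(object, ...) {
  pars <- colnames(object$chains[[1]])
  out <- lapply(pars, function(p) {
    per_chain <- lapply(object$chains, function(m) m[, p])
    pooled <- unlist(per_chain)
    e <- if (var(pooled) == 0) NA_real_ else
      sum(vapply(per_chain, function(ch)
        suppressWarnings(ess(ch)), numeric(1)), na.rm = TRUE)
    r <- if (length(per_chain) >= 2) rhat(per_chain) else NA_real_
    data.frame(
      parameter = p,
      mean = mean(pooled), sd = sd(pooled),
      q2.5 = unname(quantile(pooled, 0.025)),
      median = unname(median(pooled)),
      q97.5 = unname(quantile(pooled, 0.975)),
      ess = e, rhat = r
    )
  })
  do.call(rbind, out)
}

#' @export
print.scr_chains <- function(x, ...) {
  cat(sprintf("<scr_chains: %s fit, %d chain(s) x %d kept iterations, %d parameters>\n",
              x$meta$mode, length(x$chains), nrow(x$chains[[1]]),
              ncol(x$chains[[1]])))
  cat("parameters:", paste(colnames(x$chains[[1]]), collapse = ", "), "\n")
  invisible(x)
}
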