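#' Density model parameters
#'
#' Parameters of the log-linear intensity model for activity-center (AC)
#' density: `log(lambda_h) = beta0 + sum_i beta[i] * xi[h, i]`, where
#' `xi[h, i]` is the i-th habitat covariate in window h. `beta0` is the log
#' intensity (log AC per km^2) at covariate value zero.
#'
#' @param beta0 intercept, log(AC km^-2).
#' @param beta numeric vector of covariate slopes (may be empty).
#' @return an object of class `density_params`.
#' @export
density_params <- function(beta0, beta = numeric(0)) {
  stopifnot(is.numeric(beta0), length(beta0) == 1, is.numeric(beta))
  structure(list(beta0 = beta0, beta = as.numeric(beta)),
            class = "density_params")
}

#' Per-window AC intensity surface
#'
#' Evaluates the log-linear intensity model on every habitat window and
#' accumulates the expected number of ACs `Lambda = sum_h lambda_h * area_h`
#' over the habitat region. Because the intensity is window-constant, the
#' surface is computed once per parameter value and point evaluations reduce
#' to window lookups.
#'
#' @param grid habitat `scr_grid`.
#' @param params a `density_params`.
#' @return an object of class `intensity_surface` with elements `lambda`
#'   (per-window intensity, AC km^-2), `log_lambda`, and `Lambda_total`
#'   (expected AC count over the habitat).
#' @export
window_intensities <- function(grid, params) {
  p <- length(params$beta)
  if (ncol(grid$covariates) != p) {
    stop(sprintf("density model has %d slope(s) but the grid has %d covariate(s)",
                 p, ncol(grid$covariates)))
  }
  eta <- rep(params$beta0, n_windows(grid))
  if (p > 0) eta <- eta + drop(grid$covariates %*% params$beta)
  lam <- exp(eta)
  if (any(!is.finite(lam))) {
    stop(sprintf("non-finite intensity in window %d (log-intensity %g)",
                 which(!is.finite(lam))[1], eta[which(!is.finite(lam))[1]]))
  }
  structure(list(lambda = lam, log_lambda = eta,
                 Lambda_total = sum(lam * window_areas(grid))),
            class = "intensity_surface")
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat(sprintf("<intensity_surface: %d windows, Lambda_total = %.4g expected ACs>\n",
              length(x$lambda), x$Lambda_total))
  invisible(x)
}

#' Bernoulli point process log-density of an AC location
#'
#' Log-probability density that a single individual, known to exist in the
#' population, has its AC at `s`: `log lambda(s) - log Lambda`. This is the
#' Poisson process conditioned on one point (a binomial point process with a
#' single point) and integrates to exactly 1 over the habitat because the
#' intensity is piecewise constant.
#'
#' Points outside the habitat extent evaluate to `-Inf` by default so MCMC
#' proposals can be rejected without error handling; `strict = TRUE` raises
#' instead.
#'
#' @param s coordinate pair or `n x 2` matrix.
#' @param surface an `intensity_surface` from [window_intensities()].
#' @param grid the habitat `scr_grid` the surface was built on.
#' @param strict raise an error for out-of-habitat points?
#' @return numeric vector of log-densities.
#' @export
log_bernoulli_pp <- function(s, surface, grid, strict = FALSE) {
  idx <- locate_window(grid, s, outside = if (strict) "error" else "na")
  out <- rep(-Inf, length(idx))
  ok <- !is.na(idx)
  out[ok] <- surface$log_lambda[idx[ok]] - log(surface$Lambda_total)
  out
}

#' Poisson point process log-density of an AC configuration
#'
#' Log-density of there being `N` ACs at the given locations under the
#' inhomogeneous Poisson process: `-Lambda + sum_i log lambda(s_i)`. The
#' additive constant `-log N!` is omitted: every MCMC use is invariant to
#' it, since `N` enters through the point configuration itself.
#'
#' @param S `n x 2` matrix of AC coordinates (may have zero rows).
#' @inheritParams log_bernoulli_pp
#' @return scalar log-density (up to the dropped constant); `-Inf` when any
#'   point lies outside the habitat.
#' @export
log_poisson_pp_acs <- function(S, surface, grid) {
  if (is.null(dim(S))) S <- matrix(S, ncol = 2)
  if (nrow(S) == 0) return(-surface$Lambda_total)
  lp <- log_bernoulli_pp(S, surface, grid)
  if (any(lp == -Inf)) return(-Inf)
  -surface$Lambda_total +
    sum(lp + log(surface$Lambda_total))
}

#' Categorical (discrete-cell) AC log-probability
#'
#' Baseline AC model in which an individual's AC is assigned to a habitat
#' cell with probability `lambda_h * area_h / Lambda`, and the cell centroid
#' is used downstream as the approximate AC location.
#'
#' @param cell window index (vectorized).
#' @param surface an `intensity_surface`.
#' @param grid the habitat grid.
#' @return log-probability of each cell.
#' @export
log_categorical_ac <- function(cell, surface, grid) {
  H <- length(surface$lambda)
  cell <- as.integer(cell)
  if (any(is.na(cell)) || any(cell < 1L) || any(cell > H)) {
    stop("cell index out of range")
  }
  log(surface$lambda[cell] * window_areas(grid)[cell]) -
    log(surface$Lambda_total)
}

#' Window centroids
#' @param grid an `scr_grid`.
#' @return `H x 2` matrix of window centroids.
#' @export
window_centroids <- function(grid) {
  w <- grid$windows
  cbind((w$xmin + w$xmax) / 2, (w$ymin + w$ymax) / 2)
}

#' Export an intensity surface in the grid CSV schema
#'
#' Writes the grid CSV (window bounds and covariates) with an extra
#' `lambda` column holding the per-window intensity.
#'
#' @param surface an `intensity_surface`.
#' @param grid the habitat grid the surface was built on.
#' @param path output CSV path.
#' @export
write_intensity <- function(surface, grid, path) {
  w <- grid$windows
  out <- data.frame(window_id = w$window_id, xmin = w$xmin, ymin = w$ymin,
                    xmax = w$xmax, ymax = w$ymax)
  if (ncol(grid$covariates) > 0) out <- cbind(out,
                                              as.data.frame(grid$covariates))
  out$lambda <- surface$lambda
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
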