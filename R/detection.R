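#' Detection model parameters
#'
#' Parameters of the continuous-space detection point process. The detection
#' intensity at location `y` for an individual with activity center `s`
#' factorizes as `lambda(y | s) = b(y) * tau(y | s, sigma)`, where
#' `log b_l = theta0 + sum_i theta[i] * zeta[l, i]` is the piecewise-constant
#' baseline intensity on the detection windows and `tau` is an isotropic
#' Gaussian distance-decay kernel.
#'
#' The kernel is UNNORMALIZED, `tau(s | s) = 1`, so `exp(theta0)` is the
#' detection intensity (detections per km^2) at zero distance from the AC —
#' the usual SCR half-normal convention. The normalized-kernel
#' parameterization differs only by the constant `2 pi sigma^2`, absorbed
#' into `theta0`.
#'
#' @param theta0 log baseline detection intensity intercept.
#' @param theta numeric vector of detection covariate slopes.
#' @param sigma kernel scale in km; must be positive.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(theta0, theta = numeric(0), sigma) {
  stopifnot(is.numeric(theta0), length(theta0) == 1,
            is.numeric(sigma), length(sigma) == 1)
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(theta0 = theta0, theta = as.numeric(theta), sigma = sigma),
            class = "detection_params")
}

baseline_intensity <- function(params, detgrid) {
  p <- length(params$theta)
  if (ncol(detgrid$covariates) != p) {
    stop(sprintf("detection model has %d slope(s) but the grid has %d covariate(s)",
                 p, ncol(detgrid$covariates)))
  }
  eta <- rep(params$theta0, n_windows(detgrid))
  if (p > 0) eta <- eta + drop(detgrid$covariates %*% params$theta)
  exp(eta)
}

window_matrix <- function(grid) {
  as.matrix(grid$windows[, c("xmin", "ymin", "xmax", "ymax")])
}

#' Gaussian distance-decay kernel
#'
#' `tau(y | s, sigma) = exp(-||y - s||^2 / (2 sigma^2))`, the unnormalized
#' isotropic Gaussian ("half-normal") kernel. Equals 1 exactly at `y = s`
#' and depends on `y` only through the distance to `s`.
#'
#' @param y,s coordinate pairs or `n x 2` matrices (recycled row-wise).
#' @param sigma kernel scale, km.
#' @return numeric vector of kernel values in (0, 1].
#' @export
kernel_value <- function(y, s, sigma) {
  stopifnot(sigma > 0)
  y <- as_point_matrix(y); s <- as_point_matrix(s)
  n <- max(nrow(y), nrow(s))
  y <- y[rep_len(seq_len(nrow(y)), n), , drop = FALSE]
  s <- s[rep_len(seq_len(nrow(s)), n), , drop = FALSE]
  exp(-rowSums((y - s)^2) / (2 * sigma^2))
}

#' Exact Gaussian kernel integral over a rectangular window
#'
#' Closed-form integral of [kernel_value()] over an axis-aligned rectangle:
#' `2 pi sigma^2 [Phi((x2-sx)/sigma) - Phi((x1-sx)/sigma)]
#' [Phi((y2-sy)/sigma) - Phi((y1-sy)/sigma)]` with `Phi` the standard normal
#' CDF. Always in `(0, 2 pi sigma^2)`; a degenerate (zero-area) window gives
#' 0 with a warning.
#'
#' @param s AC coordinate pair or `n x 2` matrix.
#' @param sigma kernel scale, km.
#' @param window numeric `c(xmin, ymin, xmax, ymax)` or a matrix with those
#'   columns (one row per window).
#' @return if `s` is a single point and `window` a single rectangle, a
#'   scalar; otherwise an `n x L` matrix of integrals in km^2.
#' @export
window_kernel_integral <- function(s, sigma, window) {
  stopifnot(sigma > 0)
  s <- as_point_matrix(s)
  if (is.null(dim(window))) window <- matrix(window, nrow = 1)
  window <- as.matrix(window)
  stopifnot(ncol(window) == 4)
  if (any(window[, 3] - window[, 1] <= 0 | window[, 4] - window[, 2] <= 0)) {
    warning("degenerate window with zero area; integral is 0")
  }
  out <- cpp_kernel_integral_matrix(s, window, sigma, Inf)
  zero <- window[, 3] - window[, 1] <= 0 | window[, 4] - window[, 2] <= 0
  out[, zero] <- 0
  if (length(out) == 1) out[1, 1] else out
}

#' Expected number of detections over the detection region
#'
#' `Lambda(o | s, theta, sigma) = sum_l b_l * integral of tau over window l`,
#' the expected detection count for an individual with AC `s`. `s` may lie
#' anywhere in the habitat, including the unsearched buffer, in which case
#' only the kernel mass reaching into the detection windows counts.
#'
#' @param s AC coordinate pair or `n x 2` matrix.
#' @param params a `detection_params`.
#' @param detgrid detection `scr_grid`.
#' @param trunc_mult windows whose nearest point is farther than
#'   `trunc_mult * sigma` from `s` are skipped (their kernel mass is below
#'   `exp(-trunc_mult^2/2)`); `Inf` (the default) computes the exact sum.
#' @return numeric vector of expected counts.
#' @export
expected_detections <- function(s, params, detgrid, trunc_mult = Inf) {
  s <- as_point_matrix(s)
  b <- baseline_intensity(params, detgrid)
  drop(cpp_lambda_integral(s, window_matrix(detgrid), b, params$sigma,
                           trunc_mult))
}

#' Detection point process log-density
#'
#' Log-density of an individual's `M` detection locations given its AC:
#' `-Lambda(o | s) + sum_j [log b_{l(y_j)} + log tau(y_j | s)]`. With zero
#' detections this reduces to `-Lambda`, whose exponential is the
#' conditional void probability `P(no detections | s)`.
#'
#' @param locations `M x 2` matrix of detection coordinates (possibly zero
#'   rows), all inside some detection window.
#' @param s the individual's AC coordinate pair.
#' @inheritParams expected_detections
#' @return scalar log-density.
#' @export
log_detection_pp <- function(locations, s, params, detgrid,
                             trunc_mult = Inf) {
  Lam <- expected_detections(s, params, detgrid, trunc_mult)
  if (is.null(locations) || NROW(locations) == 0) return(-Lam)
  locations <- as_point_matrix(locations)
  l <- locate_window(detgrid, locations, outside = "na")
  if (anyNA(l)) {
    j <- which(is.na(l))[1]
    stop(sprintf("detection location (%g, %g) lies outside every detection window",
                 locations[j, 1], locations[j, 2]))
  }
  b <- baseline_intensity(params, detgrid)
  s <- as_point_matrix(s)
  -Lam + sum(log(b[l])) -
    sum((locations[, 1] - s[1, 1])^2 + (locations[, 2] - s[1, 2])^2) /
    (2 * params$sigma^2)
}

#' Single-detection log-density
#'
#' Observation model for sampling where at most one detection per individual
#' is possible (e.g. dead recoveries): the location of the single detection
#' has density `lambda(y | s) / Lambda(o | s)`, a proper density over the
#' detection region. Repeating this over independent occasions gives the
#' binomial point process variant, see [log_binomial_pp_occasions()].
#'
#' @param y the detection coordinate pair.
#' @inheritParams log_detection_pp
#' @return scalar log-density.
#' @export
log_single_detection <- function(y, s, params, detgrid, trunc_mult = Inf) {
  y <- as_point_matrix(y)
  l <- locate_window(detgrid, y, outside = "na")
  if (anyNA(l)) {
    stop(sprintf("detection location (%g, %g) lies outside every detection window",
                 y[1, 1], y[1, 2]))
  }
  b <- baseline_intensity(params, detgrid)
  Lam <- expected_detections(s, params, detgrid, trunc_mult)
  s <- as_point_matrix(s)
  log(b[l]) - sum((y[1, ] - s[1, ])^2) / (2 * params$sigma^2) - log(Lam)
}

#' Binomial point process over repeated single-detection occasions
#'
#' Independent-occasion product of [log_single_detection()] for an
#' individual detected on `nrow(ys)` occasions.
#'
#' @param ys `K x 2` matrix, one detection location per occasion.
#' @inheritParams log_detection_pp
#' @export
log_binomial_pp_occasions <- function(ys, s, params, detgrid,
                                      trunc_mult = Inf) {
  ys <- as_point_matrix(ys)
  sum(vapply(seq_len(nrow(ys)), function(k) {
    log_single_detection(ys[k, ], s, params, detgrid, trunc_mult)
  }, numeric(1)))
}

#' Discrete-detector Poisson log-likelihood
#'
#' Baseline observation model in which each detection grid cell is treated
#' as a point detector at its center: detection counts are independent
#' Poisson with rate `b_j * tau(c_j | s, sigma)` at detector center `c_j`.
#'
#' @param counts nonnegative integer vector, one count per detector.
#' @param s the individual's AC coordinate pair.
#' @param params a `detection_params`; `theta` slopes act on the detector
#'   covariates.
#' @param detectors a detection `scr_grid` (detectors at window centroids)
#'   or a list with elements `centers` (`J x 2`) and `covariates`
#'   (`J x p` matrix).
#' @return scalar log-likelihood.
#' @export
log_discrete_detector <- function(counts, s, params, detectors) {
  if (inherits(detectors, "scr_grid")) {
    centers <- window_centroids(detectors)
    covs <- detectors$covariates
  } else {
    centers <- as_point_matrix(detectors$centers)
    covs <- detectors$covariates
    if (is.null(covs)) covs <- matrix(numeric(0), nrow(centers), 0)
  }
  counts <- as.numeric(counts)
  if (length(counts) != nrow(centers)) {
    stop("counts must have one entry per detector")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  eta <- rep(params$theta0, nrow(centers))
  if (length(params$theta) > 0) eta <- eta + drop(covs %*% params$theta)
  rate <- exp(eta) * kernel_value(centers, s, params$sigma)
  sum(dpois(counts, rate, log = TRUE))
}
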