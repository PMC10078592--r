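#' Quadrature configuration for the marginal void probability
#'
#' The marginal void probability is computed by the midpoint rule over the
#' habitat. In the default `"per_window"` mode, `nodes` midpoints are placed
#' on a regular sqrt(K) x sqrt(K) sub-lattice inside every habitat window
#' (so `nodes` must be a perfect square) and each node carries weight
#' `area_h / nodes`; node weights therefore sum exactly to the habitat area.
#' In `"total"` mode, `nodes` is the approximate total budget: a single
#' global sub-lattice over the habitat extent with about that many nodes.
#'
#' @param nodes number of quadrature nodes (per window or total).
#' @param mode `"per_window"` or `"total"`.
#' @return an object of class `void_config`.
#' @export
void_config <- function(nodes = 100, mode = c("per_window", "total")) {
  mode <- match.arg(mode)
  stopifnot(nodes >= 1, nodes == round(nodes))
  if (mode == "per_window") {
    k <- sqrt(nodes)
    if (abs(k - round(k)) > 1e-8) {
      stop("nodes must be a perfect square in per_window mode")
    }
  }
  structure(list(nodes = as.integer(nodes), mode = mode),
            class = "void_config")
}

# Midpoint-rule nodes over the habitat: coordinates, per-node weight (km^2)
# and the habitat window each node falls in.
void_nodes <- function(habitat, config) {
  w <- habitat$windows
  if (config$mode == "per_window") {
    k <- as.integer(round(sqrt(config$nodes)))
    offs <- (seq_len(k) - 0.5) / k
    ux <- rep(offs, times = k)
    uy <- rep(offs, each = k)
    H <- nrow(w)
    sx <- rep(w$xmin, each = k * k) +
      rep(w$xmax - w$xmin, each = k * k) * rep(ux, H)
    sy <- rep(w$ymin, each = k * k) +
      rep(w$ymax - w$ymin, each = k * k) * rep(uy, H)
    list(points = cbind(sx, sy),
         weight = rep(w$area / (k * k), each = k * k),
         window = rep(seq_len(H), each = k * k))
  } else {
    ext <- habitat$extent
    wx <- ext[3] - ext[1]; wy <- ext[4] - ext[2]
    # choose a lattice with aspect ratio close to the extent's
    kx <- max(1L, as.integer(round(sqrt(config$nodes * wx / wy))))
    ky <- max(1L, as.integer(round(config$nodes / kx)))
    gx <- ext[1] + (seq_len(kx) - 0.5) * wx / kx
    gy <- ext[2] + (seq_len(ky) - 0.5) * wy / ky
    pts <- cbind(rep(gx, times = ky), rep(gy, each = kx))
    idx <- locate_window(habitat, pts)
    list(points = pts,
         weight = rep(wx * wy / (kx * ky), nrow(pts)),
         window = idx)
  }
}

#' Marginal void probability p*
#'
#' Probability that an individual in the population is never detected,
#' marginal over its unknown activity center:
#' `p* = (1 / Lambda_tilde) * integral over the habitat of
#' lambda_tilde(s) * exp(-Lambda(o | s, theta, sigma)) ds`.
#' Because the AC intensity is window-constant, the integral reduces to a
#' per-window sum evaluated by the midpoint rule on the configured node
#' lattice. Under the semi-complete data likelihood, p* is shared by all
#' individuals (no individual heterogeneity) and is computed once per
#' parameter value.
#'
#' @param dparams a `density_params`.
#' @param oparams a `detection_params`.
#' @param habitat habitat `scr_grid`.
#' @param detgrid detection `scr_grid`.
#' @param config a [void_config()].
#' @param trunc_mult detection-window truncation radius in units of sigma
#'   passed to the kernel integrals (`Inf` = exact).
#' @return scalar in \[0, 1\].
#' @export
void_probability <- function(dparams, oparams, habitat, detgrid,
                             config = void_config(100), trunc_mult = Inf) {
  nodes <- void_nodes(habitat, config)
  surface <- window_intensities(habitat, dparams)
  b <- baseline_intensity(oparams, detgrid)
  Lam <- cpp_lambda_integral(nodes$points, window_matrix(detgrid), b,
                             oparams$sigma, trunc_mult)
  num <- sum(surface$lambda[nodes$window] * nodes$weight * exp(-Lam))
  min(1, max(0, num / surface$Lambda_total))
}

#' Semi-complete data likelihood (SCDL) for the point process SCR model
#'
#' Log-likelihood in which the activity centers of the `N - n` undetected
#' individuals are integrated out through the marginal void probability:
#' `log C(N, n) + (N - n) log p* +
#'  sum_i [log_bernoulli_pp(s_i) + log_detection_pp(y_i | s_i)] +
#'  log prior(N)`.
#' The binomial coefficient is computed on the log-gamma scale. The N-prior
#' is pluggable: `"poisson"` (the default) uses `N ~ Poisson(Lambda_tilde)`,
#' the prior induced by the Poisson point process for ACs, which keeps the
#' density intercept `beta0` identifiable; `"uniform"` is a flat prior over
#' nonnegative integers (an improper constant).
#'
#' @param data an `scr_detections` with the `n` observed individuals.
#' @param acs `n x 2` matrix of (latent) activity centers for the observed
#'   individuals, in `data` order.
#' @param state list with elements `N` (population size, `>= n`) and
#'   optionally `p_star`; when `p_star` is missing it is computed from the
#'   parameters with `config`.
#' @param dparams,oparams,habitat,detgrid,config as in [void_probability()].
#' @param n_prior `"poisson"` or `"uniform"`.
#' @return scalar log-likelihood (including the N-prior term).
#' @export
scdl_log_likelihood <- function(data, acs, state, dparams, oparams,
                                habitat, detgrid,
                                config = void_config(100),
                                n_prior = c("poisson", "uniform")) {
  n_prior <- match.arg(n_prior)
  n <- data$n_observed
  N <- state$N
  if (is.null(N) || N != round(N)) stop("state$N must be an integer")
  if (N < n) stop(sprintf("N = %d is smaller than the observed count n = %d",
                          N, n))
  acs <- as_point_matrix(acs)
  stopifnot(nrow(acs) == n)
  surface <- window_intensities(habitat, dparams)
  p_star <- state$p_star
  if (is.null(p_star)) {
    p_star <- void_probability(dparams, oparams, habitat, detgrid, config)
  }
  u <- N - n
  void_term <- if (u == 0) 0 else if (p_star == 0) -Inf else u * log(p_star)
  choose_term <- lgamma(N + 1) - lgamma(n + 1) - lgamma(u + 1)
  obs_term <- 0
  if (n > 0) {
    obs_term <- sum(log_bernoulli_pp(acs, surface, habitat)) +
      sum(vapply(seq_len(n), function(i) {
        log_detection_pp(data$locations[[i]], acs[i, ], oparams, detgrid)
      }, numeric(1)))
  }
  prior_term <- switch(n_prior,
    poisson = dpois(N, surface$Lambda_total, log = TRUE),
    uniform = 0)
  choose_term + void_term + obs_term + prior_term
}
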