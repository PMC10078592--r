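#' Prior specification for the SCR model
#'
#' Independent Normal(0, `beta_sd`^2) priors on density coefficients
#' (including the intercept when it is estimated), Normal(0, `theta_sd`^2)
#' on detection coefficients, Uniform(0, `sigma_upper`) on the kernel scale
#' and Beta(`psi_shape`) (default Uniform(0, 1)) on the data-augmentation
#' inclusion probability.
#'
#' @param beta_sd,theta_sd prior SDs for the regression coefficients.
#' @param sigma_upper upper bound of the uniform prior on sigma (km);
#'   `NULL` defers to a model-level default of half the shorter side of the
#'   detection extent.
#' @param psi_shape length-2 Beta shape parameters for psi.
#' @return an object of class `scr_priors`.
#' @export
scr_priors <- function(beta_sd = 10, theta_sd = 10, sigma_upper = NULL,
                       psi_shape = c(1, 1)) {
  structure(list(beta_sd = beta_sd, theta_sd = theta_sd,
                 sigma_upper = sigma_upper, psi_shape = psi_shape),
            class = "scr_priors")
}

#' Assemble an SCR model
#'
#' Bundles the habitat grid, detection grid, detection data and priors into
#' a model object ready for [run_mcmc()].
#'
#' @param habitat habitat `scr_grid`.
#' @param detgrid detection `scr_grid`.
#' @param detections an `scr_detections`.
#' @param priors an [scr_priors()].
#' @return an object of class `scr_model`.
#' @export
scr_model <- function(habitat, detgrid, detections, priors = scr_priors()) {
  stopifnot(inherits(habitat, "scr_grid"), inherits(detgrid, "scr_grid"),
            inherits(detections, "scr_detections"))
  if (detections$n_observed == 0) {
    stop("model fitting requires at least one observed individual")
  }
  # validate detections against the detection grid
  detections <- detection_data(detections$ids, detections$locations, detgrid)
  if (is.null(priors$sigma_upper)) {
    priors$sigma_upper <- min(detgrid$extent[3] - detgrid$extent[1],
                              detgrid$extent[4] - detgrid$extent[2]) / 2
  }
  structure(list(habitat = habitat, detgrid = detgrid,
                 detections = detections, priors = priors),
            class = "scr_model")
}

#' MCMC configuration
#'
#' @param mode fitting strategy: `"scdl"` (semi-complete data likelihood;
#'   undetected individuals integrated out via the marginal void
#'   probability, density intercept `beta0` estimated) or `"da"` (data
#'   augmentation with inclusion indicators; `beta0` fixed, density
#'   recovered post hoc from N).
#' @param iterations total MCMC iterations per chain (> 0).
#' @param burnin iterations discarded from the front (< iterations);
#'   proposal-scale adaptation stops at the end of burn-in.
#' @param chains number of chains (>= 1).
#' @param seed integer seed; runs are bit-reproducible given config + seed.
#' @param augmentation_factor DA: augmented size M =
#'   `ceiling(augmentation_factor * n_observed)`.
#' @param nodes SCDL: midpoint-rule nodes for p*, see [void_config()].
#' @param node_mode `"per_window"` or `"total"`.
#' @param n_prior SCDL prior on population size: `"poisson"`
#'   (N ~ Poisson(Lambda_tilde), conjugate draw for the number of
#'   undetected individuals) or `"uniform"` (flat, integer random-walk).
#' @param trunc_mult kernel-integral truncation radius in sigmas (`Inf` =
#'   exact; the default 6 discards relative mass below ~1.5e-8).
#' @param estimate_N when `FALSE` under SCDL the undetected count is pinned
#'   at zero (N = n), useful for conditional-likelihood checks.
#' @param beta0_fixed value at which the density intercept is fixed under DA.
#' @param init `"default"` (data-driven: ACs at detection centroids, sigma
#'   from the within-individual detection spread) or `"prior_mean"`.
#' @param ac_model `"bernoulli"` (continuous ACs under the Bernoulli point
#'   process) or, under DA only, `"categorical"` (the baseline cell model:
#'   ACs live on habitat cells, approximated by centroids, with a
#'   categorical Gibbs update whose cost grows with the number of cells).
#' @param store_acs keep AC traces for observed individuals?
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(mode = c("scdl", "da"), iterations = 11000,
                        burnin = 1000, chains = 1, seed = 1,
                        augmentation_factor = 3, nodes = 25,
                        node_mode = "per_window",
                        n_prior = c("poisson", "uniform"),
                        trunc_mult = 6, estimate_N = TRUE,
                        beta0_fixed = 0,
                        init = c("default", "prior_mean"),
                        ac_model = c("bernoulli", "categorical"),
                        store_acs = FALSE) {
  mode <- match.arg(mode)
  n_prior <- match.arg(n_prior)
  init <- match.arg(init)
  ac_model <- match.arg(ac_model)
  if (ac_model == "categorical" && mode != "da") {
    stop("the categorical AC baseline is available under DA fitting only")
  }
  if (iterations <= 0) stop("iterations must be positive")
  if (burnin < 0 || burnin >= iterations) {
    stop("burnin must be in [0, iterations)")
  }
  if (chains < 1) stop("chains must be >= 1")
  structure(list(mode = mode, iterations = as.integer(iterations),
                 burnin = as.integer(burnin), chains = as.integer(chains),
                 seed = as.integer(seed),
                 augmentation_factor = augmentation_factor,
                 nodes = nodes, node_mode = node_mode, n_prior = n_prior,
                 trunc_mult = trunc_mult, estimate_N = estimate_N,
                 beta0_fixed = beta0_fixed, init = init,
                 ac_model = ac_model, store_acs = store_acs),
            class = "mcmc_config")
}

#' One Metropolis step of the block activity-center sampler
#'
#' Proposes a joint (x, y) update from a bivariate normal centered at the
#' current AC and accepts by the Metropolis rule. Proposals landing where
#' `log_target` is `-Inf` (e.g. outside the habitat) are rejected
#' automatically, so no boundary handling is needed in the target.
#'
#' @param current length-2 coordinate.
#' @param log_target function of a length-2 coordinate returning a log
#'   target density (finite at `current`).
#' @param proposal_cov 2x2 proposal covariance (or a scalar, interpreted as
#'   `scalar^2 * I`).
#' @return list with `value` (the new coordinate), `accepted` (logical) and
#'   `log_target_value`.
#' @export
sample_ac_block <- function(current, log_target, proposal_cov) {
  if (length(proposal_cov) == 1) {
    proposal_cov <- diag(proposal_cov^2, 2)
  }
  lt0 <- log_target(current)
  if (!is.finite(lt0)) stop("log_target must be finite at the current value")
  prop <- current + drop(rnorm(2) %*% chol(proposal_cov))
  lt1 <- log_target(prop)
  if (is.finite(lt1) && log(runif(1)) < lt1 - lt0) {
    list(value = prop, accepted = TRUE, log_target_value = lt1)
  } else {
    list(value = current, accepted = FALSE, log_target_value = lt0)
  }
}

#' Adaptive random-walk sampler for a 2-D target
#'
#' Runs [sample_ac_block()] repeatedly with Robbins-Monro adaptation of the
#' proposal scale towards a target acceptance rate (0.234, the asymptotic
#' optimum for random-walk Metropolis), freezing adaptation after `burnin`.
#'
#' @param log_target as in [sample_ac_block()].
#' @param init length-2 starting point.
#' @param n_iter iterations.
#' @param scale initial proposal scale (SD per coordinate).
#' @param burnin adaptation window.
#' @param target_rate acceptance rate targeted during adaptation.
#' @return list with `draws` (`n_iter x 2`), `acceptance_rate` (after
#'   burn-in) and final `scale`.
#' @export
rw_chain <- function(log_target, init, n_iter, scale = 1,
                     burnin = floor(n_iter / 4), target_rate = 0.234) {
  draws <- matrix(NA_real_, n_iter, 2)
  cur <- init
  log_scale <- log(scale)
  acc_post <- 0L
  for (t in seq_len(n_iter)) {
    st <- sample_ac_block(cur, log_target, exp(log_scale))
    cur <- st$value
    draws[t, ] <- cur
    if (t <= burnin) {
      log_scale <- log_scale +
        min(0.25, 1 / sqrt(t)) * ((st$accepted) - target_rate)
    } else {
      acc_post <- acc_post + st$accepted
    }
  }
  list(draws = draws,
       acceptance_rate = acc_post / max(1, n_iter - burnin),
       scale = exp(log_scale))
}

#' Data-augmentation log-posterior
#'
#' Full joint log-posterior of the data-augmented SCR model for a given
#' state. Each of the M individuals (observed and augmented) carries an AC
#' with the Bernoulli point process prior; inclusion indicators `z`
#' contribute `log psi` when 1 and `log(1 - psi)` when 0; included
#' individuals contribute their detection point process density (which for
#' an augmented individual with no detections is `-Lambda(o | s)`).
#' Observed individuals with `z = 0` give `-Inf`.
#'
#' @param state list with `M`, `z` (length M, observed individuals first),
#'   `psi`, and `s` (`M x 2` AC matrix).
#' @param dparams `density_params` (the intercept is whatever fixed value
#'   DA uses; it cancels from the Bernoulli density).
#' @param oparams `detection_params`.
#' @param data `scr_detections` with the n observed individuals.
#' @param grids list with elements `habitat` and `detgrid`.
#' @param priors an [scr_priors()].
#' @return scalar log-posterior.
#' @export
da_log_posterior <- function(state, dparams, oparams, data, grids, priors) {
  habitat <- grids$habitat; detgrid <- grids$detgrid
  n <- data$n_observed
  M <- state$M
  z <- state$z
  stopifnot(length(z) == M, nrow(state$s) == M, M >= n)
  if (any(z[seq_len(n)] == 0)) return(-Inf)
  surface <- window_intensities(habitat, dparams)
  lp_ac <- log_bernoulli_pp(state$s, surface, habitat)
  if (any(!is.finite(lp_ac))) return(-Inf)
  N <- sum(z)
  out <- sum(lp_ac) + N * log(state$psi) + (M - N) * log1p(-state$psi)
  for (i in seq_len(n)) {
    out <- out + log_detection_pp(data$locations[[i]], state$s[i, ],
                                  oparams, detgrid)
  }
  aug_in <- which(z == 1 & seq_len(M) > n)
  if (length(aug_in) > 0) {
    out <- out - sum(expected_detections(state$s[aug_in, , drop = FALSE],
                                         oparams, detgrid))
  }
  # priors
  out <- out +
    sum(dnorm_log(dparams$beta, priors$beta_sd)) +
    dnorm_log(oparams$theta0, priors$theta_sd) +
    sum(dnorm_log(oparams$theta, priors$theta_sd)) +
    stats::dbeta(state$psi, priors$psi_shape[1], priors$psi_shape[2],
                 log = TRUE) +
    ifelse(oparams$sigma < priors$sigma_upper,
           -log(priors$sigma_upper), -Inf)
  out
}

dnorm_log <- function(x, sd) {
  if (length(x) == 0) return(0)
  stats::dnorm(x, 0, sd, log = TRUE)
}
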