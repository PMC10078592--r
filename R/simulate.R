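#' Simulation scenario for the point process SCR model
#'
#' A fully specified generative setting: habitat and detection grid
#' geometry, covariate source, true parameters, and how population size is
#' drawn. Covariates are drawn Uniform(-1, 1) per window using a dedicated
#' covariate sub-seed, so data realizations and covariate surfaces can be
#' varied independently.
#'
#' @param habitat_extent,detection_extent numeric length-4
#'   `c(xmin, ymin, xmax, ymax)` (km); the detection extent must lie inside
#'   the habitat extent (the difference is the unsearched buffer).
#' @param habitat_res,detection_res window side lengths (km).
#' @param beta0,beta,theta0,theta,sigma true model parameters.
#' @param n_hab_cov,n_det_cov numbers of Uniform(-1,1) covariates to draw
#'   (lengths of `beta` and `theta`).
#' @param N_mode `"poisson"` (N ~ Poisson(Lambda_tilde)) or `"fixed"`.
#' @param N population size when `N_mode = "fixed"`.
#' @param seed data seed.
#' @param covariate_seed seed for covariate draws (default derived from
#'   `seed`).
#' @return an object of class `scr_scenario`.
#' @export
scr_scenario <- function(habitat_extent, habitat_res,
                         detection_extent, detection_res,
                         beta0 = 0, beta = numeric(0),
                         theta0 = 0, theta = numeric(0), sigma = 1,
                         n_hab_cov = length(beta), n_det_cov = length(theta),
                         N_mode = c("poisson", "fixed"), N = NULL,
                         seed = 1, covariate_seed = NULL) {
  N_mode <- match.arg(N_mode)
  if (N_mode == "fixed" && (is.null(N) || N < 0)) {
    stop("fixed N_mode requires a nonnegative N")
  }
  stopifnot(detection_extent[1] >= habitat_extent[1],
            detection_extent[2] >= habitat_extent[2],
            detection_extent[3] <= habitat_extent[3],
            detection_extent[4] <= habitat_extent[4])
  if (is.null(covariate_seed)) covariate_seed <- seed + 104729L
  structure(list(
    habitat_extent = habitat_extent, habitat_res = habitat_res,
    detection_extent = detection_extent, detection_res = detection_res,
    beta0 = beta0, beta = beta, theta0 = theta0, theta = theta,
    sigma = sigma, n_hab_cov = n_hab_cov, n_det_cov = n_det_cov,
    N_mode = N_mode, N = N, seed = as.integer(seed),
    covariate_seed = as.integer(covariate_seed)
  ), class = "scr_scenario")
}

#' @export
print.scr_scenario <- function(x, ...) {
  hx <- x$habitat_extent; dx <- x$detection_extent
  cat(sprintf(
    "<scr_scenario: habitat %gx%g km @ %g km, detection %gx%g km @ %g km,\n",
    hx[3] - hx[1], hx[4] - hx[2], x$habitat_res,
    dx[3] - dx[1], dx[4] - dx[2], x$detection_res))
  cat(sprintf("  beta0=%g beta=(%s) theta0=%g theta=(%s) sigma=%g, N %s%s>\n",
              x$beta0, paste(x$beta, collapse = ","),
              x$theta0, paste(x$theta, collapse = ","), x$sigma,
              x$N_mode,
              if (x$N_mode == "fixed") sprintf(" = %d", x$N) else ""))
  invisible(x)
}

#' Build the habitat and detection grids of a scenario
#'
#' Draws the Uniform(-1, 1) window covariates with the scenario's covariate
#' sub-seed and returns both grids.
#'
#' @param scenario an `scr_scenario`.
#' @return list with `habitat` and `detgrid`.
#' @export
scenario_grids <- function(scenario) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scenario$covariate_seed)
  mk_cov <- function(H, p, prefix) {
    if (p == 0) return(NULL)
    m <- matrix(runif(H * p, -1, 1), H, p)
    colnames(m) <- paste0(prefix, seq_len(p))
    m
  }
  hx <- scenario$habitat_extent
  nhw <- round((hx[3] - hx[1]) / scenario$habitat_res) *
    round((hx[4] - hx[2]) / scenario$habitat_res)
  habitat <- build_grid(hx, scenario$habitat_res,
                        mk_cov(nhw, scenario$n_hab_cov, "hcov"),
                        role = "habitat")
  dx <- scenario$detection_extent
  ndw <- round((dx[3] - dx[1]) / scenario$detection_res) *
    round((dx[4] - dx[2]) / scenario$detection_res)
  detgrid <- build_grid(dx, scenario$detection_res,
                        mk_cov(ndw, scenario$n_det_cov, "dcov"),
                        role = "detection")
  list(habitat = habitat, detgrid = detgrid)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

scenario_params <- function(scenario) {
  list(density = density_params(scenario$beta0, scenario$beta),
       detection = detection_params(scenario$theta0, scenario$theta,
                                    scenario$sigma))
}

#' Simulate activity centers
#'
#' Draws ACs from the generative AC point process on a habitat grid: each
#' AC falls in window h with probability `lambda_h * area_h / Lambda` and
#' is uniform within its window (the intensity is window-constant). With
#' `N_mode = "poisson"` the count is first drawn N ~ Poisson(Lambda_tilde)
#' (Poisson point process); with `"fixed"` exactly N ACs are placed
#' (Bernoulli/binomial point process).
#'
#' @param habitat habitat `scr_grid`.
#' @param dparams a `density_params`.
#' @param N_mode,N see [scr_scenario()].
#' @return `N x 2` matrix of AC coordinates.
#' @export
simulate_acs <- function(habitat, dparams, N_mode = c("poisson", "fixed"),
                         N = NULL) {
  N_mode <- match.arg(N_mode)
  surface <- window_intensities(habitat, dparams)
  if (N_mode == "poisson") {
    N <- rpois(1, surface$Lambda_total)
  }
  stopifnot(!is.null(N), N >= 0)
  w <- habitat$windows
  probs <- surface$lambda * w$area
  if (N == 0) return(matrix(numeric(0), 0, 2))
  h <- sample.int(nrow(w), N, replace = TRUE, prob = probs)
  cbind(runif(N, w$xmin[h], w$xmax[h]),
        runif(N, w$ymin[h], w$ymax[h]))
}

#' Simulate detections from the detection point process
#'
#' For each individual and detection window, the detection count is Poisson
#' with mean `b_l * integral of tau over the window`; locations within the
#' window are then drawn exactly by rejection sampling against the kernel,
#' with the envelope constant equal to the kernel value at the point of the
#' window nearest the AC. Individuals with zero total detections are
#' excluded from the observed data but retained in the truth table.
#'
#' @param acs `N x 2` matrix of activity centers.
#' @param oparams a `detection_params`.
#' @param detgrid detection `scr_grid`.
#' @return list with `detections` (an `scr_detections` of observed
#'   individuals, ids `"ind<k>"` indexing rows of `acs`) and `truth` (data
#'   frame: id, AC coordinates, detection count, observed flag).
#' @export
simulate_detections <- function(acs, oparams, detgrid) {
  acs <- as_point_matrix(acs)
  N <- nrow(acs)
  w <- detgrid$windows
  L <- nrow(w)
  b <- baseline_intensity(oparams, detgrid)
  sigma <- oparams$sigma
  counts_total <- integer(N)
  ids <- character(0)
  locs <- list()
  if (N > 0) {
    I <- cpp_kernel_integral_matrix(acs, window_matrix(detgrid), sigma, Inf)
    mu <- sweep(I, 2, b, `*`)
    cnt <- matrix(rpois(length(mu), mu), N, L)
    counts_total <- rowSums(cnt)
    for (i in which(counts_total > 0)) {
      pts <- matrix(numeric(0), 0, 2)
      for (l in which(cnt[i, ] > 0)) {
        m <- cnt[i, l]
        # envelope: kernel value at the nearest point of the window
        nx <- min(max(acs[i, 1], w$xmin[l]), w$xmax[l])
        ny <- min(max(acs[i, 2], w$ymin[l]), w$ymax[l])
        tau_max <- exp(-((nx - acs[i, 1])^2 + (ny - acs[i, 2])^2) /
                         (2 * sigma^2))
        got <- matrix(numeric(0), 0, 2)
        while (nrow(got) < m) {
          k <- max(2 * (m - nrow(got)), 8)
          cx <- runif(k, w$xmin[l], w$xmax[l])
          cy <- runif(k, w$ymin[l], w$ymax[l])
          tau <- exp(-((cx - acs[i, 1])^2 + (cy - acs[i, 2])^2) /
                       (2 * sigma^2))
          keep <- runif(k) < tau / tau_max
          got <- rbind(got, cbind(cx[keep], cy[keep]))
        }
        pts <- rbind(pts, got[seq_len(m), , drop = FALSE])
      }
      ids <- c(ids, paste0("ind", i))
      locs <- c(locs, list(pts))
    }
  }
  truth <- data.frame(
    id = if (N > 0) paste0("ind", seq_len(N)) else character(0),
    sx = acs[, 1], sy = acs[, 2],
    n_detections = counts_total,
    observed = counts_total > 0
  )
  detections <- if (length(ids) > 0) {
    detection_data(ids, locs, detgrid)
  } else {
    structure(list(ids = character(0), locations = list(), n_observed = 0L),
              class = "scr_detections")
  }
  list(detections = detections, truth = truth)
}

#' Simulate a complete SCR dataset from a scenario
#'
#' Builds the grids (covariate sub-seed), draws ACs and detections (data
#' seed), and returns everything needed to fit and to score recovery.
#'
#' @param scenario an `scr_scenario`.
#' @return list with `habitat`, `detgrid`, `acs`, `detections`, `truth`,
#'   `params` (true parameter objects) and `scenario`.
#' @export
simulate_scr <- function(scenario) {
  grids <- scenario_grids(scenario)
  pars <- scenario_params(scenario)
  set.seed(scenario$seed)
  acs <- simulate_acs(grids$habitat, pars$density, scenario$N_mode,
                      scenario$N)
  sim <- simulate_detections(acs, pars$detection, grids$detgrid)
  list(habitat = grids$habitat, detgrid = grids$detgrid, acs = acs,
       detections = sim$detections, truth = sim$truth,
       params = pars, scenario = scenario)
}

#' Preset simulation scenarios
#'
#' Ready-made generative settings matching the package's three simulation
#' designs plus a wolverine-like survey geometry:
#' \describe{
#'   \item{sim1}{model-validation design: 10 x 10 km habitat in 100 windows
#'     with a 0.6 km buffer around an 8.8 x 8.8 km detection region in 25
#'     windows; `beta0 = 1`, `theta0 = 2`, `sigma = 0.2`; slope variants
#'     `beta1`, `theta1` in \{-1, 0, 1\}; N ~ Poisson(Lambda_tilde).}
#'   \item{sim2}{density point process benchmark: N = 100 fixed, 12 x 12 km
#'     habitat (window count selectable via `habitat_res` in
#'     \{1, 2, 4, 6\} km -> 144/36/9/4 windows) with a 2 km buffer around an
#'     8 x 8 km detection region in 64 windows; `beta1 = 2`,
#'     `theta0 = theta1 = -1`, `sigma = 1`.}
#'   \item{sim3}{SCDL-versus-DA benchmark: same geometry as sim2 but with
#'     `detection_res` in \{1, 4\} km (64 or 4 detection windows),
#'     `beta0 = 1`, `theta0 = -1`, `beta1 = -1`, `theta1 = 2`, `sigma = 1`;
#'     N = 100 fixed.}
#'   \item{wolverine_like}{survey geometry of the wolverine case: 195
#'     detection windows of 20 x 20 km inside 40 habitat windows of
#'     60 x 60 km, density ~1e-3 AC/km^2 and detection parameters chosen so
#'     that roughly half of a ~140-strong population is observed
#'     (~70 individuals).}
#' }
#'
#' @param name preset name.
#' @param beta1,theta1 sim1 slope variants (each in \{-1, 0, 1\}).
#' @param habitat_res sim2/sim3 habitat resolution in km (1, 2, 4 or 6).
#' @param detection_res sim3 detection resolution in km (1 or 4).
#' @param seed data seed (covariate sub-seed derived from it).
#' @return an `scr_scenario`.
#' @export
preset <- function(name = c("sim1", "sim2", "sim3", "wolverine_like"),
                   beta1 = 0, theta1 = 0, habitat_res = 1,
                   detection_res = 1, seed = 1) {
  name <- match.arg(name)
  switch(name,
    sim1 = {
      if (!beta1 %in% c(-1, 0, 1) || !theta1 %in% c(-1, 0, 1)) {
        stop("sim1 slope variants beta1 and theta1 must be in {-1, 0, 1}")
      }
      scr_scenario(
        habitat_extent = c(0, 0, 10, 10), habitat_res = 1,
        detection_extent = c(0.6, 0.6, 9.4, 9.4), detection_res = 8.8 / 5,
        beta0 = 1, beta = beta1, theta0 = 2, theta = theta1, sigma = 0.2,
        N_mode = "poisson", seed = seed)
    },
    sim2 = {
      if (!habitat_res %in% c(1, 2, 4, 6)) {
        stop("sim2 habitat_res must be one of 1, 2, 4, 6 (km)")
      }
      scr_scenario(
        habitat_extent = c(0, 0, 12, 12), habitat_res = habitat_res,
        detection_extent = c(2, 2, 10, 10), detection_res = 1,
        beta0 = 0, beta = 2, theta0 = -1, theta = -1, sigma = 1,
        N_mode = "fixed", N = 100, seed = seed)
    },
    sim3 = {
      if (!habitat_res %in% c(1, 2, 4, 6)) {
        stop("sim3 habitat_res must be one of 1, 2, 4, 6 (km)")
      }
      if (!detection_res %in% c(1, 4)) {
        stop("sim3 detection_res must be 1 or 4 (km)")
      }
      scr_scenario(
        habitat_extent = c(0, 0, 12, 12), habitat_res = habitat_res,
        detection_extent = c(2, 2, 10, 10), detection_res = detection_res,
        beta0 = 1, beta = -1, theta0 = -1, theta = 2, sigma = 1,
        N_mode = "fixed", N = 100, seed = seed)
    },
    wolverine_like = {
      scr_scenario(
        habitat_extent = c(0, 0, 480, 300), habitat_res = 60,
        detection_extent = c(90, 20, 390, 280), detection_res = 20,
        beta0 = -6.96, beta = 0.5, theta0 = -3.85, theta = 0.5, sigma = 5,
        N_mode = "poisson", seed = seed)
    })
}
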