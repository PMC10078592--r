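test_that("AC simulation matches the intensity surface", {
  g <- build_grid(c(0, 0, 10, 10), 1, role = "habitat")
  dp <- density_params(0)
  set.seed(101)
  acs <- simulate_acs(g, dp, N_mode = "fixed", N = 10000)
  expect_equal(nrow(acs), 10000)
  counts <- tabulate(locate_window(g, acs), nbins = 100)
  gof <- chisq.test(counts, p = rep(1 / 100, 100))
  expect_gt(gof$p.value, 0.001)

  # fixed small N
  acs100 <- simulate_acs(g, dp, N_mode = "fixed", N = 100)
  expect_equal(nrow(acs100), 100)

  # all intensity mass in one window
  g2 <- build_grid(c(0, 0, 2, 1), 1,
                   covariates = data.frame(cov1 = c(0, 1)),
                   role = "habitat")
  dp2 <- density_params(0, 50)
  acs2 <- simulate_acs(g2, dp2, N_mode = "fixed", N = 500)
  expect_true(all(acs2[, 1] >= 1))

  # Poisson mode draws N ~ Poisson(Lambda)
  set.seed(7)
  ns <- replicate(200, nrow(simulate_acs(g, density_params(-1), "poisson")))
  Lt <- 100 * exp(-1)
  expect_lt(abs(mean(ns) - Lt), 4 * sqrt(Lt / 200))
})

test_that("detection counts are Poisson with mean Lambda(o | s)", {
  grids <- paired_grids(seed = 53)
  op <- detection_params(0, 0.5, sigma = 0.6)
  s <- c(4.8, 5.2)
  Lam <- expected_detections(s, op, grids$detgrid)
  set.seed(11)
  reps <- simulate_detections(matrix(rep(s, each = 10000), 10000),
                              op, grids$detgrid)
  cnt <- reps$truth$n_detections
  expect_lt(abs(mean(cnt) - Lam), 3 * sqrt(Lam / 10000))
  # chi-square GOF against the Poisson pmf
  kmax <- max(cnt)
  obs <- tabulate(cnt + 1, nbins = kmax + 1)
  p <- dpois(0:kmax, Lam)
  p[kmax + 1] <- p[kmax + 1] + ppois(kmax, Lam, lower.tail = FALSE)
  keep <- p * 10000 >= 5
  obs_b <- obs[keep]; p_b <- p[keep]
  if (any(!keep)) {
    obs_b <- c(obs_b, sum(obs[!keep])); p_b <- c(p_b, sum(p[!keep]))
  }
  gof <- suppressWarnings(chisq.test(obs_b, p = p_b / sum(p_b),
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
})

test_that("within-window locations follow the truncated kernel", {
  # single window, AC at its center: accepted x and y coordinates are
  # independent truncated normals
  det1 <- build_grid(c(0, 0, 1, 1), 1, role = "detection")
  op <- detection_params(3.2, sigma = 0.3)
  s <- c(0.5, 0.5)
  set.seed(21)
  reps <- simulate_detections(matrix(rep(s, each = 600), 600), op, det1)
  xs <- do.call(rbind, reps$detections$locations)[, 1]
  expect_gt(length(xs), 4000)
  tn_cdf <- function(x) {
    (pnorm((x - 0.5) / 0.3) - pnorm(-0.5 / 0.3)) /
      (pnorm(0.5 / 0.3) - pnorm(-0.5 / 0.3))
  }
  ks <- ks.test(xs, tn_cdf)
  expect_gt(ks$p.value, 0.001)
})

test_that("zero baseline yields no detections", {
  grids <- paired_grids(seed = 59)
  op <- detection_params(-1e9, 0, sigma = 0.6)
  set.seed(3)
  sim <- simulate_detections(cbind(runif(50, 0, 10), runif(50, 0, 10)),
                             op, grids$detgrid)
  expect_equal(sim$detections$n_observed, 0)
  expect_true(all(!sim$truth$observed))
})

test_that("observed fraction is consistent with 1 - p*", {
  sc <- preset("sim3", habitat_res = 2, detection_res = 1, seed = 71)
  grids <- scenario_grids(sc)
  pars <- list(density_params(sc$beta0, sc$beta),
               detection_params(sc$theta0, sc$theta, sc$sigma))
  ps <- void_probability(pars[[1]], pars[[2]], grids$habitat, grids$detgrid,
                         void_config(100))
  set.seed(5)
  nobs <- replicate(20, {
    acs <- simulate_acs(grids$habitat, pars[[1]], "fixed", N = 100)
    simulate_detections(acs, pars[[2]], grids$detgrid)$detections$n_observed
  })
  # binomial(100, 1 - p*) check on the mean of 20 replicates
  expect_lt(abs(mean(nobs) - 100 * (1 - ps)),
            4 * sqrt(100 * ps * (1 - ps) / 20))
})

test_that("covariates use a dedicated sub-seed", {
  sc1 <- scr_scenario(c(0, 0, 4, 4), 1, c(1, 1, 3, 3), 1,
                      beta = 0.5, theta = 0.5, seed = 1,
                      covariate_seed = 99)
  sc2 <- scr_scenario(c(0, 0, 4, 4), 1, c(1, 1, 3, 3), 1,
                      beta = 0.5, theta = 0.5, seed = 2,
                      covariate_seed = 99)
  g1 <- scenario_grids(sc1); g2 <- scenario_grids(sc2)
  expect_equal(g1$habitat$covariates, g2$habitat$covariates)
  s1 <- simulate_scr(sc1); s2 <- simulate_scr(sc2)
  expect_false(isTRUE(all.equal(s1$acs, s2$acs)))
})

test_that("presets reproduce the printed designs", {
  g1 <- scenario_grids(preset("sim1", beta1 = 1, theta1 = -1))
  expect_equal(n_windows(g1$habitat), 100)
  expect_equal(n_windows(g1$detgrid), 25)
  expect_equal(preset("sim1")$sigma, 0.2)
  expect_equal(preset("sim1")$beta0, 1)
  expect_equal(preset("sim1")$theta0, 2)

  g3 <- scenario_grids(preset("sim3", habitat_res = 6, detection_res = 4))
  expect_equal(n_windows(g3$habitat), 4)
  expect_equal(n_windows(g3$detgrid), 4)
  expect_equal(preset("sim3")$N, 100)

  g2 <- scenario_grids(preset("sim2", habitat_res = 1))
  expect_equal(n_windows(g2$habitat), 144)
  expect_equal(n_windows(g2$detgrid), 64)

  gw <- scenario_grids(preset("wolverine_like"))
  expect_equal(n_windows(gw$habitat), 40)
  expect_equal(n_windows(gw$detgrid), 195)
  # around 72 observed individuals out of a larger population
  set.seed(13)
  sims <- lapply(1:4, function(k) simulate_scr(preset("wolverine_like",
                                                      seed = 100 + k)))
  nobs <- vapply(sims, function(s) s$detections$n_observed, numeric(1))
  ntot <- vapply(sims, function(s) nrow(s$acs), numeric(1))
  expect_gt(mean(nobs), 50); expect_lt(mean(nobs), 90)
  expect_gt(mean(ntot), mean(nobs))

  expect_error(preset("sim1", beta1 = 2), "-1, 0, 1")
  expect_error(preset("sim3", habitat_res = 3), "1, 2, 4, 6")
  expect_error(preset("nope"), "arg")
})
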