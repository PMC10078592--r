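test_that("the block AC sampler behaves as a Metropolis step", {
  # proposals where the target is -Inf are always rejected
  target <- function(p) if (any(p < 0)) -Inf else -sum(p^2) / 2
  set.seed(1)
  cur <- c(0.01, 0.01)
  stuck <- replicate(200, {
    st <- sample_ac_block(cur, function(p) if (any(p < 0)) -Inf else 0,
                          proposal_cov = 25)
    all(st$value == cur) || all(st$value >= 0)
  })
  expect_true(all(stuck))
  expect_error(sample_ac_block(c(-1, -1), target, 1), "finite")
})

test_that("adaptive RW sampling recovers a known 2-D Gaussian target", {
  mu <- c(1, -2)
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  Sinv <- solve(S)
  lt <- function(p) -0.5 * drop(t(p - mu) %*% Sinv %*% (p - mu))
  set.seed(42)
  out <- rw_chain(lt, init = c(0, 0), n_iter = 20000, scale = 1,
                  burnin = 4000)
  keep <- out$draws[4001:20000, ]
  expect_gt(out$acceptance_rate, 0.15)
  expect_lt(out$acceptance_rate, 0.35)
  expect_equal(colMeans(keep), mu, tolerance = 0.15)
  expect_equal(unname(cov(keep)), unname(S), tolerance = 0.25)
})

test_that("ESS matches sampling-error and AR(1) oracles", {
  set.seed(7)
  e <- ess(rnorm(1000))
  expect_gt(e, 600); expect_lt(e, 1400)

  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), 20000))
  target <- 20000 * (1 - rho) / (1 + rho)
  expect_lt(abs(ess(x) - target) / target, 0.3)

  expect_warning(expect_true(is.na(ess(rep(1, 100)))), "constant")
  expect_error(ess(1:5), "short")
})

test_that("split R-hat is ~1 for identical chains and >1 for shifted ones", {
  set.seed(9)
  x <- rnorm(2000)
  expect_equal(rhat(list(x, x)), 1, tolerance = 0.01)
  expect_gt(rhat(list(x, x + 3)), 1.5)
  expect_error(rhat(list(x)), "2 chains")
})

test_that("DA log-posterior encodes inclusion and conjugacy structure", {
  grids <- paired_grids(seed = 61)
  dat <- detection_data(c("a", "b"),
                        list(rbind(c(4, 5), c(4.2, 5.1)), rbind(c(6, 6))))
  dp <- density_params(0, 0.4)
  op <- detection_params(0, 0.3, sigma = 0.5)
  priors <- scr_priors(sigma_upper = 4)
  s <- rbind(c(4.1, 5), c(6, 6), c(2, 2), c(8, 8))
  mk <- function(z, psi) list(M = 4L, z = z, psi = psi, s = s)

  # observed individual with z = 0 is impossible
  expect_identical(
    da_log_posterior(mk(c(1L, 0L, 0L, 0L), 0.5), dp, op, dat, grids,
                     priors), -Inf)

  # flipping an augmented z from 0 to 1 adds log(psi/(1-psi)) - Lambda(s)
  lp0 <- da_log_posterior(mk(c(1L, 1L, 0L, 0L), 0.4), dp, op, dat, grids,
                          priors)
  lp1 <- da_log_posterior(mk(c(1L, 1L, 1L, 0L), 0.4), dp, op, dat, grids,
                          priors)
  expect_equal(lp1 - lp0,
               log(0.4 / 0.6) - expected_detections(s[3, ], op,
                                                    grids$detgrid),
               tolerance = 1e-10)

  # psi enters exactly through the Beta(1 + N, 1 + M - N) kernel
  z <- c(1L, 1L, 1L, 0L); N <- 3
  d_lp <- da_log_posterior(mk(z, 0.7), dp, op, dat, grids, priors) -
    da_log_posterior(mk(z, 0.3), dp, op, dat, grids, priors)
  d_beta <- dbeta(0.7, 1 + N, 1 + 4 - N, log = TRUE) -
    dbeta(0.3, 1 + N, 1 + 4 - N, log = TRUE)
  expect_equal(d_lp, d_beta, tolerance = 1e-10)
})

test_that("run_mcmc validates configuration and is seed-reproducible", {
  expect_error(mcmc_config(iterations = 0), "positive")
  expect_error(mcmc_config(iterations = 100, burnin = 100), "burnin")
  expect_error(mcmc_config("scdl", ac_model = "categorical"), "DA")

  sim <- simulate_scr(preset("sim3", habitat_res = 6, detection_res = 4,
                             seed = 8))
  model <- scr_model(sim$habitat, sim$detgrid, sim$detections)
  cfg <- mcmc_config("scdl", iterations = 300, burnin = 100, seed = 31,
                     nodes = 9)
  ch1 <- run_mcmc(model, cfg)
  ch2 <- run_mcmc(model, cfg)
  expect_identical(ch1$chains, ch2$chains)

  cfg_da <- mcmc_config("da", iterations = 300, burnin = 100, seed = 31)
  chd <- run_mcmc(model, cfg_da)
  expect_identical(chd$chains, run_mcmc(model, cfg_da)$chains)
  expect_true(all(c("N", "psi", "sigma") %in%
                    colnames(chd$chains[[1]])))
})

test_that("DA with M = n and all z fixed matches SCDL with N fixed at n", {
  sim <- simulate_scr(preset("sim3", habitat_res = 4, detection_res = 4,
                             seed = 14))
  model <- scr_model(sim$habitat, sim$detgrid, sim$detections)
  chS <- run_mcmc(model, mcmc_config("scdl", iterations = 4000,
                                     burnin = 1000, seed = 41, nodes = 9,
                                     estimate_N = FALSE))
  chD <- run_mcmc(model, mcmc_config("da", iterations = 4000,
                                     burnin = 1000, seed = 42,
                                     augmentation_factor = 1))
  sS <- summary(chS); sD <- summary(chD)
  expect_true(all(chD$chains[[1]][, "N"] == sim$detections$n_observed))
  expect_true(all(chS$chains[[1]][, "N"] == sim$detections$n_observed))
  for (p in c("theta0", "sigma")) {
    mS <- sS$mean[sS$parameter == p]; mD <- sD$mean[sD$parameter == p]
    se <- sqrt(sS$sd[sS$parameter == p]^2 / sS$ess[sS$parameter == p] +
                 sD$sd[sD$parameter == p]^2 / sD$ess[sD$parameter == p])
    expect_lt(abs(mS - mD), 4 * se)
  }
})

test_that("a model-validation style fit recovers sigma and theta0", {
  sim <- simulate_scr(preset("sim1", beta1 = 1, theta1 = -1, seed = 9))
  model <- scr_model(sim$habitat, sim$detgrid, sim$detections)
  ch <- run_mcmc(model, mcmc_config("scdl", iterations = 1500,
                                    burnin = 500, seed = 11, nodes = 9))
  s <- summary(ch)
  for (p in c("sigma", "theta0")) {
    truth <- if (p == "sigma") 0.2 else 2
    expect_lt(abs(s$mean[s$parameter == p] - truth),
              3 * s$sd[s$parameter == p])
  }
  # acceptance rates settled near the adaptation target
  acc <- ch$meta$acceptance[[1]]
  expect_gt(acc["ac"], 0.1); expect_lt(acc["ac"], 0.45)
})

test_that("categorical-AC baseline agrees with the Bernoulli PP on a fine grid
           and costs more per iteration as cells grow", {
  # agreement needs cells small relative to sigma (1 km cells, sigma = 1);
  # on coarse cells the centroid approximation visibly biases N, which is
  # exactly why the point process model exists
  sim <- simulate_scr(preset("sim3", habitat_res = 1, detection_res = 4,
                             seed = 3))
  model <- scr_model(sim$habitat, sim$detgrid, sim$detections)
  chB <- run_mcmc(model, mcmc_config("da", iterations = 2500, burnin = 750,
                                     seed = 5))
  chC <- run_mcmc(model, mcmc_config("da", iterations = 2500, burnin = 750,
                                     seed = 6, ac_model = "categorical"))
  sB <- summary(chB); sC <- summary(chC)
  mB <- sB$mean[sB$parameter == "N"]; mC <- sC$mean[sC$parameter == "N"]
  se <- sqrt(sB$sd[sB$parameter == "N"]^2 / sB$ess[sB$parameter == "N"] +
               sC$sd[sC$parameter == "N"]^2 / sC$ess[sC$parameter == "N"])
  expect_lt(abs(mB - mC), max(4 * se, 0.05 * mB))

  # categorical cost scales with the number of habitat cells; the point
  # process cost does not
  M <- ceiling(3 * sim$detections$n_observed)
  expect_equal(chC$meta$ac_ops_per_iter[1], M * n_windows(sim$habitat))
  expect_equal(chB$meta$ac_ops_per_iter[1], M)
  simc <- simulate_scr(preset("sim3", habitat_res = 2, detection_res = 4,
                              seed = 3))
  modelc <- scr_model(simc$habitat, simc$detgrid, simc$detections)
  chCc <- run_mcmc(modelc, mcmc_config("da", iterations = 60, burnin = 10,
                                       seed = 6, ac_model = "categorical"))
  chBc <- run_mcmc(modelc, mcmc_config("da", iterations = 60, burnin = 10,
                                       seed = 6))
  expect_gt(chC$meta$ac_ops_per_iter[1] / chCc$meta$ac_ops_per_iter[1], 2)
  expect_lt(chB$meta$ac_ops_per_iter[1] / chBc$meta$ac_ops_per_iter[1], 2)
})
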