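# MCMC engine for the point process SCR model.
#
# Control flow lives in R; the numerical hot spots (Gaussian window
# integrals over detection windows, per-individual squared-distance sums)
# are compiled. Caching follows the structure of the model: the per-window
# AC intensity is evaluated once per density-parameter update, the node
# exponentials exp(-Lambda(o | node)) once per detection-parameter update,
# and p* is recombined from those caches at negligible cost.

prep_fit_data <- function(model, config) {
  habitat <- model$habitat
  detgrid <- model$detgrid
  det <- model$detections
  n <- det$n_observed
  m_i <- vapply(det$locations, nrow, integer(1))
  y_all <- do.call(rbind, det$locations)
  y_ind <- rep(seq_len(n), m_i)
  y_l <- locate_window(detgrid, y_all)
  list(
    habitat = habitat, detgrid = detgrid, det = det,
    X = habitat$covariates, areas = window_areas(habitat),
    W = window_matrix(detgrid), Z = detgrid$covariates,
    H = n_windows(habitat), L = n_windows(detgrid),
    pd = ncol(habitat$covariates), pe = ncol(detgrid$covariates),
    n = n, m_i = m_i, y_all = y_all, y_ind = y_ind, y_l = y_l,
    D = nrow(y_all), ext = habitat$extent,
    hab_area = sum(window_areas(habitat)),
    trunc = config$trunc_mult
  )
}

init_params <- function(prep, priors, config) {
  if (config$init == "prior_mean") {
    sigma <- priors$sigma_upper / 2
    beta0 <- 0; theta0 <- 0
  } else {
    # data-driven: sigma from the within-individual spread of detections,
    # intercepts from crude method-of-moments counts
    multi <- which(prep$m_i >= 2)
    if (length(multi) > 0) {
      d2 <- 0; cnt <- 0
      for (i in multi) {
        y <- prep$det$locations[[i]]
        cen <- colMeans(y)
        d2 <- d2 + sum((y[, 1] - cen[1])^2 + (y[, 2] - cen[2])^2)
        cnt <- cnt + nrow(y)
      }
      sigma <- sqrt(d2 / (2 * cnt))
    } else {
      w <- prep$detgrid$windows
      sigma <- mean(w$xmax - w$xmin) / 2
    }
    sigma <- min(max(sigma, 1e-2), 0.9 * priors$sigma_upper)
    beta0 <- log(max(prep$n, 1) / prep$hab_area)
    theta0 <- log(prep$D / (max(prep$n, 1) * 2 * pi * sigma^2))
    theta0 <- min(max(theta0, -20), 20)
  }
  list(beta0 = beta0, beta = rep(0, prep$pd),
       theta0 = theta0, theta = rep(0, prep$pe), sigma = sigma)
}

init_acs <- function(prep, extra = 0) {
  ext <- prep$ext
  eps <- 1e-9 * max(ext[3] - ext[1], ext[4] - ext[2])
  cen <- t(vapply(prep$det$locations, colMeans, numeric(2)))
  cen[, 1] <- pmin(pmax(cen[, 1], ext[1] + eps), ext[3] - eps)
  cen[, 2] <- pmin(pmax(cen[, 2], ext[2] + eps), ext[4] - eps)
  if (extra > 0) {
    cen <- rbind(cen, cbind(runif(extra, ext[1], ext[3]),
                            runif(extra, ext[2], ext[4])))
  }
  cen
}

node_void_weights <- function(nodes, Lam_nodes, H) {
  val <- nodes$weight * exp(-Lam_nodes)
  q <- numeric(H)
  tmp <- rowsum(val, nodes$window)
  q[as.integer(rownames(tmp))] <- tmp
  q
}

rm_gain <- function(t) min(0.25, 1 / sqrt(t))

fit_chain_scdl <- function(prep, priors, config, chain_seed) {
  set.seed(chain_seed)
  H <- prep$H; L <- prep$L; n <- prep$n
  pd <- prep$pd; pe <- prep$pe
  trunc <- prep$trunc
  par <- init_params(prep, priors, config)
  beta0 <- par$beta0; beta <- par$beta
  theta0 <- par$theta0; theta <- par$theta; sigma <- par$sigma
  s <- init_acs(prep)

  nodes <- void_nodes(prep$habitat,
                      void_config(config$nodes, config$node_mode))
  pstar_evals <- 0L

  # caches
  loglam <- beta0 + if (pd > 0) drop(prep$X %*% beta) else 0
  loglam <- rep(loglam, length.out = H)
  lam <- exp(loglam)
  Lambda_tilde <- sum(lam * prep$areas)
  logb <- theta0 + if (pe > 0) drop(prep$Z %*% theta) else 0
  logb <- rep(logb, length.out = L)
  b <- exp(logb)
  node_Lam <- drop(cpp_lambda_integral(nodes$points, prep$W, b, sigma, trunc))
  pstar_evals <- pstar_evals + 1L
  q <- node_void_weights(nodes, node_Lam, H)
  s_win <- locate_window(prep$habitat, s)
  Lam_s <- drop(cpp_lambda_integral(s, prep$W, b, sigma, trunc))
  ssd <- drop(cpp_ssd_by_individual(prep$y_all, prep$y_ind, s, n))
  logb_det_sum <- sum(logb[prep$y_l])

  pstar <- function() min(1, sum(lam * q) / Lambda_tilde)
  p_star <- pstar()
  u <- if (config$estimate_N) rpois(1, Lambda_tilde * p_star) else 0L

  init_bits <- c(Lambda_tilde = Lambda_tilde, p_star = p_star,
                 min_loglam_s = min(loglam[s_win]),
                 detection_loglik = sum(-Lam_s) + logb_det_sum -
                   sum(ssd) / (2 * sigma^2))
  if (any(!is.finite(init_bits))) {
    stop("non-finite initial posterior; offending components: ",
         paste(names(init_bits)[!is.finite(init_bits)], collapse = ", "))
  }

  # adaptive proposal scales
  ls_ac <- rep(log(max(sigma, 1e-2)), n)
  ls_beta <- log(0.1); ls_ts <- log(0.1)
  ls_u <- log(max(2, sqrt(n)))
  acc_ac <- 0; acc_beta <- 0L; acc_ts <- 0L; n_post <- 0L

  kept <- config$iterations - config$burnin
  par_names <- c("N", "beta0",
                 if (pd > 0) paste0("beta", seq_len(pd)),
                 "theta0", if (pe > 0) paste0("theta", seq_len(pe)),
                 "sigma", "p_star")
  draws <- matrix(NA_real_, kept, length(par_names),
                  dimnames = list(NULL, par_names))
  ac_trace <- if (config$store_acs)
    array(NA_real_, c(kept, n, 2)) else NULL

  for (t in seq_len(config$iterations)) {
    adapting <- t <= config$burnin

    ## --- activity centers (joint (x, y) random-walk, all individuals) ---
    prop <- s + matrix(rnorm(2 * n), n, 2) * exp(ls_ac)
    idx_p <- locate_window(prep$habitat, prop, outside = "na")
    valid <- !is.na(idx_p)
    Lam_p <- drop(cpp_lambda_integral(prop, prep$W, b, sigma, trunc))
    ssd_p <- drop(cpp_ssd_by_individual(prep$y_all, prep$y_ind, prop, n))
    logr <- rep(-Inf, n)
    logr[valid] <- (loglam[idx_p[valid]] - Lam_p[valid] -
                      ssd_p[valid] / (2 * sigma^2)) -
      (loglam[s_win[valid]] - Lam_s[valid] - ssd[valid] / (2 * sigma^2))
    acc <- log(runif(n)) < logr
    if (any(acc)) {
      s[acc, ] <- prop[acc, ]
      s_win[acc] <- idx_p[acc]
      Lam_s[acc] <- Lam_p[acc]
      ssd[acc] <- ssd_p[acc]
    }
    if (adapting) {
      ls_ac <- ls_ac + rm_gain(t) * (acc - 0.234)
    } else {
      acc_ac <- acc_ac + mean(acc); n_post <- n_post + 1L
    }

    ## --- density coefficients (beta0 + slopes, joint block) ---
    prop_b0 <- beta0 + rnorm(1) * exp(ls_beta)
    prop_b <- beta + if (pd > 0) rnorm(pd) * exp(ls_beta) else numeric(0)
    loglam_p <- rep(prop_b0 + if (pd > 0) drop(prep$X %*% prop_b) else 0,
                    length.out = H)
    lam_p <- exp(loglam_p)
    Lt_p <- sum(lam_p * prep$areas)
    lamq_p <- sum(lam_p * q); lamq <- sum(lam * q)
    # Under the Poisson population prior the beta target carries the
    # Poisson-process normalizer -Lambda_tilde + u log(Lambda_tilde p*);
    # under the flat prior it is the pure Bernoulli-PP form
    # sum_i log lambda(s_i) - N log Lambda_tilde + u log p* (beta0 then
    # cancels and follows its prior, as under data augmentation).
    if (config$n_prior == "poisson") {
      core_p <- -Lt_p + (if (u > 0) u * log(lamq_p) else 0) +
        sum(loglam_p[s_win])
      core_c <- -Lambda_tilde + (if (u > 0) u * log(lamq) else 0) +
        sum(loglam[s_win])
    } else {
      core_p <- sum(loglam_p[s_win]) - (n + u) * log(Lt_p) +
        (if (u > 0) u * log(lamq_p) else 0)
      core_c <- sum(loglam[s_win]) - (n + u) * log(Lambda_tilde) +
        (if (u > 0) u * log(lamq) else 0)
    }
    logr <- (core_p + dnorm_log(prop_b0, priors$beta_sd) +
               sum(dnorm_log(prop_b, priors$beta_sd))) -
      (core_c + dnorm_log(beta0, priors$beta_sd) +
         sum(dnorm_log(beta, priors$beta_sd)))
    if (is.finite(logr) && log(runif(1)) < logr) {
      beta0 <- prop_b0; beta <- prop_b
      loglam <- loglam_p; lam <- lam_p; Lambda_tilde <- Lt_p
      if (!adapting) acc_beta <- acc_beta + 1L
      if (adapting) ls_beta <- ls_beta + rm_gain(t) * (1 - 0.234)
    } else if (adapting) {
      ls_beta <- ls_beta - rm_gain(t) * 0.234
    }

    ## --- detection coefficients + sigma (joint block) ---
    prop_t0 <- theta0 + rnorm(1) * exp(ls_ts)
    prop_t <- theta + if (pe > 0) rnorm(pe) * exp(ls_ts) else numeric(0)
    prop_sig <- sigma + rnorm(1) * exp(ls_ts) * max(sigma, 0.05)
    if (prop_sig > 0 && prop_sig < priors$sigma_upper) {
      logb_p <- rep(prop_t0 + if (pe > 0) drop(prep$Z %*% prop_t) else 0,
                    length.out = L)
      b_p <- exp(logb_p)
      node_Lam_p <- drop(cpp_lambda_integral(nodes$points, prep$W, b_p,
                                             prop_sig, trunc))
      pstar_evals <- pstar_evals + 1L
      q_p <- node_void_weights(nodes, node_Lam_p, H)
      Lam_s_p <- drop(cpp_lambda_integral(s, prep$W, b_p, prop_sig, trunc))
      logb_det_p <- sum(logb_p[prep$y_l])
      lamq_p <- sum(lam * q_p); lamq <- sum(lam * q)
      logr <- (sum(-Lam_s_p) + logb_det_p - sum(ssd) / (2 * prop_sig^2) +
                 (if (u > 0) u * (log(lamq_p) - log(Lambda_tilde)) else 0) +
                 dnorm_log(prop_t0, priors$theta_sd) +
                 sum(dnorm_log(prop_t, priors$theta_sd))) -
        (sum(-Lam_s) + logb_det_sum - sum(ssd) / (2 * sigma^2) +
           (if (u > 0) u * (log(lamq) - log(Lambda_tilde)) else 0) +
           dnorm_log(theta0, priors$theta_sd) +
           sum(dnorm_log(theta, priors$theta_sd)))
      accepted <- is.finite(logr) && log(runif(1)) < logr
    } else {
      accepted <- FALSE
    }
    if (accepted) {
      theta0 <- prop_t0; theta <- prop_t; sigma <- prop_sig
      logb <- logb_p; b <- b_p
      node_Lam <- node_Lam_p; q <- q_p
      Lam_s <- Lam_s_p; logb_det_sum <- logb_det_p
      if (!adapting) acc_ts <- acc_ts + 1L
    }
    if (adapting) ls_ts <- ls_ts + rm_gain(t) * (accepted - 0.234)

    ## --- number of undetected individuals ---
    p_star <- pstar()
    if (config$estimate_N) {
      if (config$n_prior == "poisson") {
        u <- rpois(1, Lambda_tilde * p_star)
      } else {
        # integer random walk on u with adaptive step scale
        step <- as.integer(round(rnorm(1) * exp(ls_u)))
        u_acc <- FALSE
        if (step != 0L) {
          u_p <- u + step
          if (u_p >= 0 && p_star > 0) {
            logr <- (lgamma(n + u_p + 1) - lgamma(u_p + 1) +
                       u_p * log(p_star)) -
              (lgamma(n + u + 1) - lgamma(u + 1) + u * log(p_star))
            if (log(runif(1)) < logr) {
              u <- u_p
              u_acc <- TRUE
            }
          }
        }
        if (adapting) ls_u <- ls_u + rm_gain(t) * (u_acc - 0.4)
      }
    }

    if (t > config$burnin) {
      k <- t - config$burnin
      draws[k, ] <- c(n + u, beta0, beta, theta0, theta, sigma, p_star)
      if (config$store_acs) ac_trace[k, , ] <- s
    }
  }

  list(draws = draws, ac_trace = ac_trace,
       acceptance = c(ac = acc_ac / max(1, n_post),
                      beta = acc_beta / max(1, n_post),
                      theta_sigma = acc_ts / max(1, n_post)),
       p_star_evals = pstar_evals,
       ac_ops_per_iter = n)
}

fit_chain_da <- function(prep, priors, config, chain_seed) {
  set.seed(chain_seed)
  H <- prep$H; L <- prep$L; n <- prep$n
  pd <- prep$pd; pe <- prep$pe
  trunc <- prep$trunc
  M <- as.integer(ceiling(config$augmentation_factor * n))
  par <- init_params(prep, priors, config)
  beta0 <- config$beta0_fixed
  beta <- par$beta
  theta0 <- par$theta0; theta <- par$theta; sigma <- par$sigma
  s <- init_acs(prep, extra = M - n)
  z <- c(rep(1L, n), rbinom(M - n, 1, 0.5))
  psi <- 0.5

  loglam <- rep(beta0 + if (pd > 0) drop(prep$X %*% beta) else 0,
                length.out = H)
  lam <- exp(loglam)
  Lambda_tilde <- sum(lam * prep$areas)
  logb <- rep(theta0 + if (pe > 0) drop(prep$Z %*% theta) else 0,
              length.out = L)
  b <- exp(logb)
  s_win <- locate_window(prep$habitat, s)
  Lam_s <- drop(cpp_lambda_integral(s, prep$W, b, sigma, trunc))
  ssd <- drop(cpp_ssd_by_individual(prep$y_all, prep$y_ind,
                                    s[seq_len(n), , drop = FALSE], n))
  logb_det_sum <- sum(logb[prep$y_l])

  init_bits <- c(Lambda_tilde = Lambda_tilde,
                 min_loglam_s = min(loglam[s_win]),
                 detection_loglik = sum(-Lam_s[seq_len(n)]) + logb_det_sum -
                   sum(ssd) / (2 * sigma^2))
  if (any(!is.finite(init_bits))) {
    stop("non-finite initial posterior; offending components: ",
         paste(names(init_bits)[!is.finite(init_bits)], collapse = ", "))
  }

  ls_ac <- rep(log(max(sigma, 1e-2)), M)
  ls_beta <- log(0.1); ls_ts <- log(0.1)
  acc_ac <- 0; acc_beta <- 0L; acc_ts <- 0L; n_post <- 0L
  obs <- seq_len(n)

  kept <- config$iterations - config$burnin
  par_names <- c("N", "psi",
                 if (pd > 0) paste0("beta", seq_len(pd)),
                 "theta0", if (pe > 0) paste0("theta", seq_len(pe)),
                 "sigma")
  draws <- matrix(NA_real_, kept, length(par_names),
                  dimnames = list(NULL, par_names))
  ac_trace <- if (config$store_acs) array(NA_real_, c(kept, n, 2)) else NULL

  for (t in seq_len(config$iterations)) {
    adapting <- t <= config$burnin

    ## --- activity centers (all M individuals) ---
    prop <- s + matrix(rnorm(2 * M), M, 2) * exp(ls_ac)
    idx_p <- locate_window(prep$habitat, prop, outside = "na")
    valid <- !is.na(idx_p)
    Lam_p <- drop(cpp_lambda_integral(prop, prep$W, b, sigma, trunc))
    ssd_p <- drop(cpp_ssd_by_individual(prep$y_all, prep$y_ind,
                                        prop[obs, , drop = FALSE], n))
    det_cur <- numeric(M); det_prop <- numeric(M)
    det_cur[obs] <- -Lam_s[obs] - ssd / (2 * sigma^2)
    det_prop[obs] <- -Lam_p[obs] - ssd_p / (2 * sigma^2)
    aug <- which(seq_len(M) > n & z == 1L)
    det_cur[aug] <- -Lam_s[aug]
    det_prop[aug] <- -Lam_p[aug]
    logr <- rep(-Inf, M)
    logr[valid] <- (loglam[idx_p[valid]] + det_prop[valid]) -
      (loglam[s_win[valid]] + det_cur[valid])
    acc <- log(runif(M)) < logr
    if (any(acc)) {
      s[acc, ] <- prop[acc, ]
      s_win[acc] <- idx_p[acc]
      Lam_s[acc] <- Lam_p[acc]
      oacc <- acc[obs]
      ssd[oacc] <- ssd_p[oacc]
    }
    if (adapting) {
      ls_ac <- ls_ac + rm_gain(t) * (acc - 0.234)
    } else {
      acc_ac <- acc_ac + mean(acc); n_post <- n_post + 1L
    }

    ## --- inclusion indicators (augmented individuals) and psi ---
    idx_aug <- if (M > n) (n + 1):M else integer(0)
    if (M > n) {
      p1 <- psi * exp(-Lam_s[idx_aug])
      z[idx_aug] <- rbinom(M - n, 1, p1 / (p1 + (1 - psi)))
    }
    N <- n + sum(z[idx_aug])
    psi <- rbeta(1, priors$psi_shape[1] + N, priors$psi_shape[2] + M - N)

    ## --- density slopes (beta0 fixed under DA) ---
    if (pd > 0) {
      prop_b <- beta + rnorm(pd) * exp(ls_beta)
      loglam_p <- rep(beta0 + drop(prep$X %*% prop_b), length.out = H)
      Lt_p <- sum(exp(loglam_p) * prep$areas)
      logr <- (sum(loglam_p[s_win]) - M * log(Lt_p) +
                 sum(dnorm_log(prop_b, priors$beta_sd))) -
        (sum(loglam[s_win]) - M * log(Lambda_tilde) +
           sum(dnorm_log(beta, priors$beta_sd)))
      if (is.finite(logr) && log(runif(1)) < logr) {
        beta <- prop_b; loglam <- loglam_p; lam <- exp(loglam)
        Lambda_tilde <- Lt_p
        if (!adapting) acc_beta <- acc_beta + 1L
        if (adapting) ls_beta <- ls_beta + rm_gain(t) * (1 - 0.234)
      } else if (adapting) {
        ls_beta <- ls_beta - rm_gain(t) * 0.234
      }
    }

    ## --- detection coefficients + sigma ---
    prop_t0 <- theta0 + rnorm(1) * exp(ls_ts)
    prop_t <- theta + if (pe > 0) rnorm(pe) * exp(ls_ts) else numeric(0)
    prop_sig <- sigma + rnorm(1) * exp(ls_ts) * max(sigma, 0.05)
    aug_in <- which(z == 1L & seq_len(M) > n)
    if (prop_sig > 0 && prop_sig < priors$sigma_upper) {
      logb_p <- rep(prop_t0 + if (pe > 0) drop(prep$Z %*% prop_t) else 0,
                    length.out = L)
      b_p <- exp(logb_p)
      Lam_s_p <- drop(cpp_lambda_integral(s, prep$W, b_p, prop_sig, trunc))
      logb_det_p <- sum(logb_p[prep$y_l])
      logr <- (-sum(Lam_s_p[obs]) - sum(Lam_s_p[aug_in]) + logb_det_p -
                 sum(ssd) / (2 * prop_sig^2) +
                 dnorm_log(prop_t0, priors$theta_sd) +
                 sum(dnorm_log(prop_t, priors$theta_sd))) -
        (-sum(Lam_s[obs]) - sum(Lam_s[aug_in]) + logb_det_sum -
           sum(ssd) / (2 * sigma^2) +
           dnorm_log(theta0, priors$theta_sd) +
           sum(dnorm_log(theta, priors$theta_sd)))
      accepted <- is.finite(logr) && log(runif(1)) < logr
    } else {
      accepted <- FALSE
    }
    if (accepted) {
      theta0 <- prop_t0; theta <- prop_t; sigma <- prop_sig
      logb <- logb_p; b <- b_p
      Lam_s <- Lam_s_p; logb_det_sum <- logb_det_p
      if (!adapting) acc_ts <- acc_ts + 1L
    }
    if (adapting) ls_ts <- ls_ts + rm_gain(t) * (accepted - 0.234)

    if (t > config$burnin) {
      k <- t - config$burnin
      draws[k, ] <- c(sum(z), psi, beta, theta0, theta, sigma)
      if (config$store_acs) ac_trace[k, , ] <- s[obs, ]
    }
  }

  list(draws = draws, ac_trace = ac_trace,
       acceptance = c(ac = acc_ac / max(1, n_post),
                      beta = acc_beta / max(1, n_post),
                      theta_sigma = acc_ts / max(1, n_post)),
       p_star_evals = 0L,
       ac_ops_per_iter = M)
}

fit_chain_da_categorical <- function(prep, priors, config, chain_seed) {
  # Baseline AC model: the activity center lives on the habitat cells, with
  # the cell centroid used as the approximate location. The cell index has
  # a categorical full conditional evaluated over all H cells for every
  # individual in every iteration, which is exactly the per-iteration cost
  # the window-constant Bernoulli point process avoids.
  set.seed(chain_seed)
  H <- prep$H; L <- prep$L; n <- prep$n
  pd <- prep$pd; pe <- prep$pe
  trunc <- prep$trunc
  M <- as.integer(ceiling(config$augmentation_factor * n))
  par <- init_params(prep, priors, config)
  beta0 <- config$beta0_fixed
  beta <- par$beta
  theta0 <- par$theta0; theta <- par$theta; sigma <- par$sigma
  cent <- window_centroids(prep$habitat)
  log_area <- log(prep$areas)
  z <- c(rep(1L, n), rbinom(M - n, 1, 0.5))
  psi <- 0.5
  obs <- seq_len(n)

  # per-individual squared-distance sums to every cell centroid: constant
  # in the parameters, computed once
  y_sum <- rowsum(prep$y_all, prep$y_ind)
  y_sq <- rowsum(prep$y_all[, 1]^2 + prep$y_all[, 2]^2, prep$y_ind)
  m_i <- prep$m_i
  ssd_cells <- matrix(y_sq, n, H) -
    2 * (y_sum %*% t(cent)) +
    outer(m_i, cent[, 1]^2 + cent[, 2]^2)

  loglam <- rep(beta0 + if (pd > 0) drop(prep$X %*% beta) else 0,
                length.out = H)
  Lambda_tilde <- sum(exp(loglam) * prep$areas)
  logb <- rep(theta0 + if (pe > 0) drop(prep$Z %*% theta) else 0,
              length.out = L)
  b <- exp(logb)
  Lam_cent <- drop(cpp_lambda_integral(cent, prep$W, b, sigma, trunc))
  logb_det_sum <- sum(logb[prep$y_l])
  cell <- integer(M)

  gibbs_cells <- function() {
    lw <- matrix(loglam + log_area, M, H, byrow = TRUE)
    lw[obs, ] <- lw[obs, , drop = FALSE] +
      matrix(-Lam_cent, n, H, byrow = TRUE) - ssd_cells / (2 * sigma^2)
    aug_in <- which(z == 1L & seq_len(M) > n)
    if (length(aug_in) > 0) {
      lw[aug_in, ] <- lw[aug_in, , drop = FALSE] +
        matrix(-Lam_cent, length(aug_in), H, byrow = TRUE)
    }
    mx <- apply(lw, 1, max)
    wgt <- exp(lw - mx)
    cs <- wgt / rowSums(wgt)
    un <- runif(M)
    max.col(-(t(apply(cs, 1, cumsum)) < un), ties.method = "first")
  }
  cell <- gibbs_cells()
  ac_ops <- 0

  ls_ts <- log(0.1); ls_beta <- log(0.1)
  acc_beta <- 0L; acc_ts <- 0L; n_post <- 0L
  kept <- config$iterations - config$burnin
  par_names <- c("N", "psi",
                 if (pd > 0) paste0("beta", seq_len(pd)),
                 "theta0", if (pe > 0) paste0("theta", seq_len(pe)),
                 "sigma")
  draws <- matrix(NA_real_, kept, length(par_names),
                  dimnames = list(NULL, par_names))

  for (t in seq_len(config$iterations)) {
    adapting <- t <= config$burnin

    cell <- gibbs_cells()
    ac_ops <- ac_ops + M * H
    ssd <- ssd_cells[cbind(obs, cell[obs])]

    idx_aug <- if (M > n) (n + 1):M else integer(0)
    if (M > n) {
      p1 <- psi * exp(-Lam_cent[cell[idx_aug]])
      z[idx_aug] <- rbinom(M - n, 1, p1 / (p1 + (1 - psi)))
    }
    N <- n + sum(z[idx_aug])
    psi <- rbeta(1, priors$psi_shape[1] + N, priors$psi_shape[2] + M - N)

    if (pd > 0) {
      prop_b <- beta + rnorm(pd) * exp(ls_beta)
      loglam_p <- rep(beta0 + drop(prep$X %*% prop_b), length.out = H)
      Lt_p <- sum(exp(loglam_p) * prep$areas)
      logr <- (sum(loglam_p[cell]) - M * log(Lt_p) +
                 sum(dnorm_log(prop_b, priors$beta_sd))) -
        (sum(loglam[cell]) - M * log(Lambda_tilde) +
           sum(dnorm_log(beta, priors$beta_sd)))
      if (is.finite(logr) && log(runif(1)) < logr) {
        beta <- prop_b; loglam <- loglam_p; Lambda_tilde <- Lt_p
        if (!adapting) acc_beta <- acc_beta + 1L
        if (adapting) ls_beta <- ls_beta + rm_gain(t) * (1 - 0.234)
      } else if (adapting) {
        ls_beta <- ls_beta - rm_gain(t) * 0.234
      }
    }

    prop_t0 <- theta0 + rnorm(1) * exp(ls_ts)
    prop_t <- theta + if (pe > 0) rnorm(pe) * exp(ls_ts) else numeric(0)
    prop_sig <- sigma + rnorm(1) * exp(ls_ts) * max(sigma, 0.05)
    aug_in <- which(z == 1L & seq_len(M) > n)
    if (prop_sig > 0 && prop_sig < priors$sigma_upper) {
      logb_p <- rep(prop_t0 + if (pe > 0) drop(prep$Z %*% prop_t) else 0,
                    length.out = L)
      b_p <- exp(logb_p)
      Lam_cent_p <- drop(cpp_lambda_integral(cent, prep$W, b_p, prop_sig,
                                             trunc))
      logb_det_p <- sum(logb_p[prep$y_l])
      logr <- (-sum(Lam_cent_p[cell[obs]]) - sum(Lam_cent_p[cell[aug_in]]) +
                 logb_det_p - sum(ssd) / (2 * prop_sig^2) +
                 dnorm_log(prop_t0, priors$theta_sd) +
                 sum(dnorm_log(prop_t, priors$theta_sd))) -
        (-sum(Lam_cent[cell[obs]]) - sum(Lam_cent[cell[aug_in]]) +
           logb_det_sum - sum(ssd) / (2 * sigma^2) +
           dnorm_log(theta0, priors$theta_sd) +
           sum(dnorm_log(theta, priors$theta_sd)))
      accepted <- is.finite(logr) && log(runif(1)) < logr
    } else {
      accepted <- FALSE
    }
    if (accepted) {
      theta0 <- prop_t0; theta <- prop_t; sigma <- prop_sig
      logb <- logb_p; b <- b_p
      Lam_cent <- Lam_cent_p; logb_det_sum <- logb_det_p
      if (!adapting) acc_ts <- acc_ts + 1L
    }
    if (adapting) ls_ts <- ls_ts + rm_gain(t) * (accepted - 0.234)
    if (!adapting) n_post <- n_post + 1L

    if (t > config$burnin) {
      draws[t - config$burnin, ] <- c(sum(z), psi, beta, theta0, theta,
                                      sigma)
    }
  }

  list(draws = draws, ac_trace = NULL,
       acceptance = c(ac = 1, beta = acc_beta / max(1, n_post),
                      theta_sigma = acc_ts / max(1, n_post)),
       p_star_evals = 0L,
       ac_ops_per_iter = ac_ops / config$iterations)
}

#' Fit the point process SCR model by MCMC
#'
#' Runs adaptive Metropolis-within-Gibbs MCMC under the fitting strategy
#' named in `config`. Activity centers are updated with a joint (x, y)
#' block random-walk per individual; regression coefficient blocks and
#' (theta, sigma) use adaptive random-walk Metropolis; the
#' data-augmentation inclusion indicators and psi are Gibbs steps; under
#' SCDL with the Poisson population prior, the number of undetected
#' individuals is a conjugate Poisson draw with mean
#' `Lambda_tilde * p_star`. Proposal scales adapt by Robbins-Monro towards
#' 0.234 acceptance during burn-in and are frozen afterwards. Runs are
#' bit-reproducible given the same configuration and seed.
#'
#' @param model an [scr_model()].
#' @param config an [mcmc_config()].
#' @return an object of class `scr_chains`: `chains` is a list (one matrix
#'   of post-burn-in draws per chain, columns named `N`, `beta*`, `theta*`,
#'   `sigma`, and `p_star`/`psi` depending on mode), `meta` records seeds,
#'   acceptance rates and the number of full p* quadrature evaluations.
#' @export
run_mcmc <- function(model, config) {
  stopifnot(inherits(model, "scr_model"), inherits(config, "mcmc_config"))
  prep <- prep_fit_data(model, config)
  fitter <- if (config$mode == "scdl") {
    fit_chain_scdl
  } else if (config$ac_model == "categorical") {
    fit_chain_da_categorical
  } else {
    fit_chain_da
  }
  chain_seeds <- config$seed + 1000L * (seq_len(config$chains) - 1L)
  res <- lapply(chain_seeds, function(cs)
    fitter(prep, model$priors, config, cs))
  structure(list(
    chains = lapply(res, `[[`, "draws"),
    ac_traces = if (config$store_acs) lapply(res, `[[`, "ac_trace") else NULL,
    meta = list(
      mode = config$mode, iterations = config$iterations,
      burnin = config$burnin, seed = config$seed,
      chain_seeds = chain_seeds,
      n_observed = prep$n,
      acceptance = lapply(res, `[[`, "acceptance"),
      p_star_evals = vapply(res, `[[`, numeric(1), "p_star_evals"),
      ac_ops_per_iter = vapply(res, `[[`, numeric(1), "ac_ops_per_iter"),
      config = unclass(config)
    )
  ), class = "scr_chains")
}
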