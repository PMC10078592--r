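test_that("Gaussian kernel has SCR half-normal properties", {
  expect_equal(kernel_value(c(1, 1), c(1, 1), 0.5), 1)
  expect_equal(kernel_value(c(1, 0), c(0, 0), 1), exp(-1 / 2))
  # radial symmetry at fixed distance
  ang <- seq(0, 2 * pi, length.out = 13)
  pts <- cbind(0.7 * cos(ang), 0.7 * sin(ang))
  vals <- kernel_value(pts, c(0, 0), 0.3)
  expect_equal(vals, rep(vals[1], length(vals)))
  expect_error(detection_params(0, sigma = -1), "positive")
})

test_that("window kernel integral matches closed-form limits and quadrature", {
  expect_equal(window_kernel_integral(c(0, 0), 1, c(-8, -8, 8, 8)), 2 * pi,
               tolerance = 1e-9)
  expect_equal(window_kernel_integral(c(0, 0), 1, c(0, 0, 8, 8)), 2 * pi / 4,
               tolerance = 1e-9)
  # independent 2-D quadrature oracle on random windows
  skip_if_not_installed("pracma")
  set.seed(7)
  for (rep in 1:8) {
    s <- runif(2, -2, 2)
    sigma <- runif(1, 0.2, 2)
    win <- c(sort(runif(2, -3, 3)), sort(runif(2, -3, 3)))[c(1, 3, 2, 4)]
    f <- function(x, y) exp(-((x - s[1])^2 + (y - s[2])^2) / (2 * sigma^2))
    q <- pracma::integral2(f, win[1], win[3], win[2], win[4],
                           reltol = 1e-12)$Q
    expect_equal(window_kernel_integral(s, sigma, win), q,
                 tolerance = 1e-8)
  }
  expect_warning(window_kernel_integral(c(0, 0), 1, c(0, 0, 0, 1)),
                 "degenerate")
})

test_that("expected detections sum baseline-weighted window integrals", {
  det <- build_grid(c(-50, -50, 50, 50), 100, role = "detection")
  # b = 1 on one huge window, s central: whole-plane Gaussian mass
  expect_equal(expected_detections(c(0, 0), detection_params(0, sigma = 1),
                                   det), 2 * pi, tolerance = 1e-9)
  # vanishing baseline
  expect_equal(expected_detections(c(0, 0),
                                   detection_params(-1e9, sigma = 1), det), 0)

  # midpoint-quadrature oracle over a covariate-varying detection grid
  grids <- paired_grids(seed = 13)
  op <- detection_params(0.3, 0.8, sigma = 0.7)
  b <- exp(0.3 + 0.8 * grids$detgrid$covariates[, 1])
  w <- grids$detgrid$windows
  s <- c(2.7, 6.1)
  # per-window adaptive quadrature of b(y) tau(y | s)
  skip_if_not_installed("pracma")
  quad <- 0
  for (l in seq_len(nrow(w))) {
    quad <- quad + b[l] * pracma::integral2(
      function(x, y) exp(-((x - s[1])^2 + (y - s[2])^2) / (2 * 0.7^2)),
      w$xmin[l], w$xmax[l], w$ymin[l], w$ymax[l], reltol = 1e-10)$Q
  }
  expect_equal(expected_detections(s, op, grids$detgrid), quad,
               tolerance = 1e-6)

  # strictly increasing in theta0
  lam <- vapply(c(-1, 0, 1), function(t0)
    expected_detections(s, detection_params(t0, 0.8, sigma = 0.7),
                        grids$detgrid), numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("kernel truncation approximates the exact integral sum", {
  grids <- paired_grids(seed = 17)
  op <- detection_params(0.5, -0.4, sigma = 0.3)
  set.seed(5)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  exact <- expected_detections(pts, op, grids$detgrid, trunc_mult = Inf)
  trunc <- expected_detections(pts, op, grids$detgrid, trunc_mult = 6)
  expect_lt(max(abs(exact - trunc)), 1e-6 * max(exact))
  expect_equal(expected_detections(pts, op, grids$detgrid,
                                   trunc_mult = Inf), exact)
})

test_that("Lambda decreases as the AC moves away from the detection region", {
  grids <- paired_grids(seed = 19)
  op <- detection_params(0, 0, sigma = 0.5)  # flat baseline: pure kernel decay
  # ray from the center of the detection region out into the buffer
  ts <- seq(0, 1, length.out = 12)
  ray <- cbind(5 + ts * 4.9, 5 + ts * 4.9)
  lam <- expected_detections(ray, op, grids$detgrid)
  expect_true(all(diff(lam) < 0))
})

test_that("detection point process log-density matches its pieces", {
  grids <- paired_grids(seed = 23)
  op <- detection_params(0.2, 0.5, sigma = 0.6)
  s <- c(4.2, 5.5)
  Lam <- expected_detections(s, op, grids$detgrid)
  # zero detections: conditional void probability
  expect_equal(log_detection_pp(NULL, s, op, grids$detgrid), -Lam)
  expect_equal(log_detection_pp(matrix(numeric(0), 0, 2), s, op,
                                grids$detgrid), -Lam)
  # one detection exactly at s with homogeneous b = 1
  det1 <- build_grid(c(1, 1, 9, 9), 2, role = "detection")
  op1 <- detection_params(0, sigma = 0.6)
  expect_equal(log_detection_pp(matrix(s, 1), s, op1, det1),
               -expected_detections(s, op1, det1))

  # independent reimplementation for several detections in mixed windows
  ys <- rbind(c(4.0, 5.2), c(6.6, 3.1), c(2.2, 7.7))
  b <- exp(0.2 + 0.5 * grids$detgrid$covariates[, 1])
  l <- locate_window(grids$detgrid, ys)
  oracle <- -Lam + sum(log(b[l]) -
                         rowSums(sweep(ys, 2, s)^2) / (2 * 0.6^2))
  expect_equal(log_detection_pp(ys, s, op, grids$detgrid), oracle,
               tolerance = 1e-12)
  expect_error(log_detection_pp(rbind(c(0.1, 0.1)), s, op, grids$detgrid),
               "outside")
})

test_that("single-detection density is proper over the detection region", {
  det1 <- build_grid(c(-20, -20, 20, 20), 40, role = "detection")
  op <- detection_params(0, sigma = 1)
  s <- c(0, 0)
  expect_equal(log_single_detection(c(0, 0), s, op, det1), -log(2 * pi),
               tolerance = 1e-9)

  grids <- paired_grids(seed = 29)
  op2 <- detection_params(0.4, 0.6, sigma = 0.8)
  s <- c(5.1, 4.3)
  # quadrature of exp(log-density) over the detection region
  w <- grids$detgrid$windows
  total <- 0
  for (l in seq_len(nrow(w))) {
    gx <- seq(w$xmin[l], w$xmax[l], length.out = 41)
    gx <- (gx[-1] + gx[-41]) / 2
    gy <- seq(w$ymin[l], w$ymax[l], length.out = 41)
    gy <- (gy[-1] + gy[-41]) / 2
    cell <- (w$xmax[l] - w$xmin[l]) * (w$ymax[l] - w$ymin[l]) / 40^2
    for (x in gx) {
      total <- total + sum(exp(vapply(gy, function(y)
        log_single_detection(c(x, y), s, op2, grids$detgrid),
        numeric(1)))) * cell
    }
  }
  expect_equal(total, 1, tolerance = 1e-4)

  # invariant to rescaling the baseline by a constant
  op3 <- detection_params(0.4 + 2, 0.6, sigma = 0.8)
  y <- c(5.5, 4.1)
  expect_equal(log_single_detection(y, s, op2, grids$detgrid),
               log_single_detection(y, s, op3, grids$detgrid),
               tolerance = 1e-12)

  # occasion products
  ys <- rbind(c(5.5, 4.1), c(4.9, 4.6))
  expect_equal(log_binomial_pp_occasions(ys, s, op2, grids$detgrid),
               log_single_detection(ys[1, ], s, op2, grids$detgrid) +
                 log_single_detection(ys[2, ], s, op2, grids$detgrid))
})

test_that("discrete-detector likelihood matches the Poisson pmf oracle", {
  det <- build_grid(c(0, 0, 4, 4), 1,
                    covariates = data.frame(eff = runif(16, -1, 1)),
                    role = "detection")
  op <- detection_params(-0.5, 0.7, sigma = 1.2)
  s <- c(1.7, 2.4)
  centers <- window_centroids(det)
  rate <- exp(-0.5 + 0.7 * det$covariates[, 1]) *
    exp(-rowSums(sweep(centers, 2, s)^2) / (2 * 1.2^2))
  set.seed(3)
  counts <- rpois(16, rate)
  expect_equal(log_discrete_detector(counts, s, op, det),
               sum(dpois(counts, rate, log = TRUE)), tolerance = 1e-12)
  expect_equal(log_discrete_detector(rep(0, 16), s, op, det), -sum(rate))
  # single detector at s with b = 1 and one count
  det1 <- build_grid(c(1.2, 1.9, 2.2, 2.9), 1, role = "detection")
  # detector center is exactly s
  expect_equal(log_discrete_detector(1, s, detection_params(0, sigma = 1),
                                     det1), -1)
  expect_error(log_discrete_detector(c(-1, rep(0, 15)), s, op, det),
               "nonnegative")
})
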