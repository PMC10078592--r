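# Shared fixtures, built in code at test time.

# 4-window habitat grid on [0,2]^2 with one covariate, fixed values.
tiny_grid <- function(role = "habitat") {
  build_grid(c(0, 0, 2, 2), 1,
             covariates = data.frame(cov1 = c(-0.5, 0.25, 0.75, -1)),
             role = role)
}

# sim-style paired grids: habitat with buffer around a centered detection
# region, Uniform(-1,1) covariates drawn under `seed`.
paired_grids <- function(seed = 1) {
  sc <- scr_scenario(
    habitat_extent = c(0, 0, 10, 10), habitat_res = 1,
    detection_extent = c(1, 1, 9, 9), detection_res = 2,
    beta0 = 0.5, beta = 1, theta0 = 0, theta = 0.5, sigma = 0.5,
    seed = seed)
  scenario_grids(sc)
}

# Brute-force point-in-window scan, independent of locate_window().
scan_window <- function(grid, p) {
  w <- grid$windows
  ext <- grid$extent
  for (h in seq_len(nrow(w))) {
    in_x <- p[1] >= w$xmin[h] &&
      (p[1] < w$xmax[h] || (w$xmax[h] == ext[3] && p[1] == w$xmax[h]))
    in_y <- p[2] >= w$ymin[h] &&
      (p[2] < w$ymax[h] || (w$ymax[h] == ext[4] && p[2] == w$ymax[h]))
    if (in_x && in_y) return(h)
  }
  NA_integer_
}

# Closed-form Gaussian rectangle integral written independently of the
# package (pnorm-based), for cross-checking compiled code.
oracle_rect_integral <- function(s, sigma, win) {
  2 * pi * sigma^2 *
    (pnorm((win[3] - s[1]) / sigma) - pnorm((win[1] - s[1]) / sigma)) *
    (pnorm((win[4] - s[2]) / sigma) - pnorm((win[2] - s[2]) / sigma))
}
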