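# Independent oracles and shared fixtures for the test suite.

# brute-force kernel-sum KDE: double loop over knots and points,
# independent of the separable-matrix implementation
brute_force_kde <- function(coords, grid, h) {
  n <- nrow(coords)
  vals <- matrix(NA_real_, grid$nx, grid$ny)
  for (i in seq_len(grid$nx)) {
    for (j in seq_len(grid$ny)) {
      s <- 0
      for (k in seq_len(n)) {
        dx <- grid$x[i] - coords[k, 1]
        dy <- grid$y[j] - coords[k, 2]
        s <- s + exp(-(dx^2 + dy^2) / (2 * h^2)) / (2 * pi * h^2)
      }
      vals[i, j] <- s / n
    }
  }
  vals[!grid$inside] <- NA_real_
  vals
}

# direct evaluation of the maximal-smoothing bandwidth formula,
# spelled out independently of os_bandwidth()
oracle_os_bandwidth <- function(coords) {
  n <- nrow(coords)
  sx2 <- sum((coords[, 1] - mean(coords[, 1]))^2) / (n - 1)
  sy2 <- sum((coords[, 2] - mean(coords[, 2]))^2) / (n - 1)
  sigma <- sqrt((sx2 + sy2) / 2)
  # d = 2: ((8 * 6 * (2 sqrt(pi))^2) / (4 n))^(1/6) = (48 pi / n)^(1/6)
  sigma * (48 * pi / n)^(1 / 6)
}

# a small non-convex test polygon (L-shape) used across geometry tests
l_shape_window <- function() {
  polygon_window(cbind(c(0, 4, 4, 2, 2, 0), c(0, 0, 2, 2, 4, 4)))
}

# standard fixtures for the study scenario
fort_dodge_window <- function() disc_window(c(0, 0), 10)

fort_dodge_scenario <- function(n_case = 8L, n_control = 428L) {
  scenario_spec(fort_dodge_window(),
                mvn_model(c(0, 0), 0.83),
                mvn_model(c(0, 0), 1.67),
                n_case, n_control)
}

knot_radius <- function(grid) {
  outer(grid$x, grid$y, function(a, b) sqrt(a^2 + b^2))
}
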