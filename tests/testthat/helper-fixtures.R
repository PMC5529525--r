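# Shared fixtures, generated in code.

# Short grid for fast unit tests
short_grid <- function() seq(600, 800, by = 1)

# Two well-separated synthetic components on the short grid
small_library <- function(grid = short_grid()) {
  a <- make_component_profile("alpha",
                              list(peak_spec(650, 20, 1.0),
                                   peak_spec(740, 15, 0.6)),
                              grid, unit_concentration = 100)
  b <- make_component_profile("beta",
                              list(peak_spec(700, 18, 0.9),
                                   peak_spec(770, 25, 0.8)),
                              grid, unit_concentration = 20)
  component_library(list(a, b))
}

random_spectrum <- function(seed, n = 64, meta = list()) {
  set.seed(seed)
  wn <- sort(stats::runif(n, 600, 1800))
  while (anyDuplicated(wn)) wn <- sort(stats::runif(n, 600, 1800))
  raman_spectrum(wn, stats::rexp(n, 1 / 50), meta)
}

# Brute-force grid search over (c1, c2[, delta]) for the two-component
# least-squares objective; the independent oracle for fit_lcm.
grid_search_lcm <- function(y, lib, c1_grid, c2_grid, delta_grid = 0) {
  nu <- lib$grid
  R <- vapply(lib$components, function(cp) cp$reference$intensities,
              numeric(length(nu)))
  best <- list(obj = Inf)
  for (d in delta_grid) {
    Rd <- vapply(1:2, function(i) {
      stats::approx(nu, R[, i], xout = nu - d, rule = 2)$y
    }, numeric(length(nu)))
    G <- crossprod(Rd)
    bv <- crossprod(Rd, y)
    yy <- sum(y^2)
    # objective(c) = c'Gc - 2 b'c + yy over the whole (c1, c2) grid
    obj <- outer(c1_grid^2 * G[1, 1], rep(1, length(c2_grid))) +
      outer(rep(1, length(c1_grid)), c2_grid^2 * G[2, 2]) +
      2 * G[1, 2] * outer(c1_grid, c2_grid) -
      2 * outer(c1_grid * bv[1], rep(1, length(c2_grid))) -
      2 * outer(rep(1, length(c1_grid)), c2_grid * bv[2]) + yy
    ix <- arrayInd(which.min(obj), dim(obj))
    if (min(obj) < best$obj) {
      best <- list(obj = min(obj), c1 = c1_grid[ix[1]], c2 = c2_grid[ix[2]],
                   delta = d)
    }
  }
  best
}

# Independent event-count oracle: plain enumeration of significant interior
# extrema, written without reference to the package implementation.
count_events_oracle <- function(values, sigma, k = 1) {
  n <- length(values)
  cnt <- 0L
  where <- integer(0)
  if (n < 3) return(list(n = 0L, idx = where))
  for (i in 2:(n - 1)) {
    left <- values[i] - values[i - 1]
    right <- values[i + 1] - values[i]
    is_max <- left > 0 && right < 0
    is_min <- left < 0 && right > 0
    big <- abs(left) > k * sigma[i] && abs(right) > k * sigma[i]
    if ((is_max || is_min) && big) {
      cnt <- cnt + 1L
      where <- c(where, i)
    }
  }
  list(n = cnt, idx = where)
}
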