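# Shared fixtures built in code.

# axis-aligned square polygon with given corner and side
square_poly <- function(id = "sq", x0 = 0, y0 = 0, side = 10) {
  simple_polygon(id, rbind(c(x0, y0), c(x0 + side, y0),
                           c(x0 + side, y0 + side), c(x0, y0 + side)))
}

flat_dsm <- function(n = 20, cell = 1, z = 0)
  raster_grid(matrix(z, n, n), cell_size = cell)

# small random-terrain DSM for oracle comparisons
random_dsm <- function(n, seed, cell = 1, relief = 6) {
  with_seed <- function(s, code) { set.seed(s); force(code) }
  with_seed(seed, {
    base <- matrix(stats::runif(n * n, 0, relief), n, n)
    # mild smoothing so sight lines interact with structure, not pure noise
    k <- (base[-1, -1] + base[-n, -1] + base[-1, -n] + base[-n, -n]) / 4
    m <- matrix(0, n, n)
    m[1:(n - 1), 1:(n - 1)] <- k
    raster_grid(m, cell_size = cell)
  })
}

random_observers <- function(dsm, n_obs, seed, eye = 1.5) {
  set.seed(seed)
  ext <- raster_extent(dsm)
  x <- stats::runif(n_obs, ext["xmin"] + 0.5, ext["xmax"] - 0.5)
  y <- stats::runif(n_obs, ext["ymin"] + 0.5, ext["ymax"] - 0.5)
  data.frame(x = x, y = y, eye_z = surface_at(dsm, x, y) + eye)
}

# small labelled dataset with one strong numeric signal
signal_dataset <- function(n, seed, noise = 0.1, tau_q = 0.6) {
  set.seed(seed)
  X <- data.frame(a = stats::runif(n), b = stats::runif(n),
                  g = factor(sample(c("u", "v", "w"), n, replace = TRUE)))
  tau <- stats::quantile(X$a, tau_q, names = FALSE)
  y <- as.integer(X$a >= tau)
  flip <- stats::runif(n) < noise
  list(X = X, y = as.integer(xor(y, flip)), tau = tau)
}
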