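#' Fluctuation magnitude of a set of supply vectors
#'
#' The fluctuation magnitude sigma_RS is the root-mean-square deviation
#' of supply fractions from the equal-supply point: the square root of
#' the mean, over samples and components, of `(s_i - 1/N)^2`.  For a
#' uniform-random supply on three resources it equals `sqrt(1/18)`
#' (about 0.236); for a single randomly chosen resource it equals
#' `sqrt(2/9)` (about 0.471).
#'
#' @param samples matrix with one supply vector per row (rows sum to 1),
#'   or a single numeric vector.
#' @return scalar sigma_RS estimate.
#' @export
fluctuation_magnitude <- function(samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  n <- ncol(samples)
  sqrt(mean((samples - 1 / n)^2))
}

#' Reference sigma_RS values
#'
#' `sigma_rs_uniform(n)` is the fluctuation magnitude of the uniform
#' (flat-Dirichlet) distribution on the n-simplex;
#' `sigma_rs_single_resource(n)` that of a single uniformly chosen
#' resource.
#' @param n_resources number of resources.
#' @return scalar.
#' @export
sigma_rs_uniform <- function(n_resources = 3) {
  n <- n_resources
  sqrt((n - 1) / (n^2 * (n + 1)))
}

#' @rdname sigma_rs_uniform
#' @export
sigma_rs_single_resource <- function(n_resources = 3) {
  sqrt((n_resources - 1)) / n_resources
}

#' Elementary supply schedules
#'
#' `constant_supply()` supplies all resources equally on every cycle;
#' `sample_uniform_simplex()` draws supplies uniformly from the simplex
#' (flat Dirichlet); `single_resource_supply()` supplies one uniformly
#' chosen resource per cycle.
#'
#' @param n_resources number of resources.
#' @param n number of cycles / draws.
#' @return `n` x `n_resources` matrix; every row is nonnegative and sums
#'   to 1.
#' @export
constant_supply <- function(n_resources, n = 1) {
  matrix(1 / n_resources, n, n_resources)
}

#' @rdname constant_supply
#' @export
sample_uniform_simplex <- function(n_resources, n = 1) {
  if (n_resources < 2) stop("n_resources must be >= 2")
  e <- matrix(-log(1 - runif(n * n_resources)), n, n_resources)
  e / rowSums(e)
}

#' @rdname constant_supply
#' @export
single_resource_supply <- function(n_resources, n = 1) {
  if (n_resources < 1) stop("n_resources must be >= 1")
  s <- matrix(0, n, n_resources)
  s[cbind(seq_len(n), sample.int(n_resources, n, replace = TRUE))] <- 1
  s
}

#' Seasonal (periodic sinusoidal) resource supply
#'
#' Supplies trace a circle on the simplex: resource i on growth cycle k
#' receives `1/3 + A * cos(2*pi*((k-1)/period - (i-1)/3))`.  The default
#' amplitude `A = 0.2969` (about 0.297, the peak supply 0.630 minus
#' 1/3) is the least-squares fit to the canonical three/six/twelve-
#' season supply tables shipped in `extdata/seasonal_supply_table.csv`;
#' with it the generator reproduces every printed table cell to three
#' decimals, supplies stay nonnegative, and each cycle sums to 1.
#'
#' @param period integer length of the seasonal cycle (3, 6 and 12 are
#'   the canonical choices).
#' @param cycles integer vector of 1-based growth-cycle indices.
#' @param amplitude radius of the circle in supply-fraction units; must
#'   lie in [0, 1/3].
#' @return `length(cycles)` x 3 supply matrix.
#' @examples
#' round(seasonal_supply(3, 1), 3)  # 0.630 0.185 0.185
#' @export
seasonal_supply <- function(period, cycles = seq_len(period),
                            amplitude = 0.2969) {
  if (period < 1) stop("period must be a positive integer")
  if (amplitude < 0 || amplitude > 1 / 3)
    stop("amplitude must lie in [0, 1/3]")
  k <- as.numeric(cycles) - 1
  s <- sapply(0:2, function(i) {
    1 / 3 + amplitude * cos(2 * pi * (k / period - i / 3))
  })
  s <- matrix(s, length(k), 3)
  colnames(s) <- paste0("R", 1:3)
  s
}

# --- stochastic fluctuation family (three resources) ------------------

# Centroid-rule quadrature grid on the simplex face (s1, s2 coordinates,
# s3 = 1 - s1 - s2): M^2 congruent subtriangles, equal weights.
simplex_quad_grid <- function(M = 700) {
  h <- 1 / M
  ij <- expand.grid(i = 0:(M - 1), j = 0:(M - 1))
  up <- ij[ij$i + ij$j <= M - 1, ]
  dn <- ij[ij$i + ij$j <= M - 2, ]
  s1 <- c((up$i + 1 / 3) * h, (dn$i + 2 / 3) * h)
  s2 <- c((up$j + 1 / 3) * h, (dn$j + 2 / 3) * h)
  d2 <- (s1 - 1 / 3)^2 + (s2 - 1 / 3)^2 + (1 - s1 - s2 - 1 / 3)^2
  list(d2 = d2)
}

#' Realized fluctuation magnitude of the clipped-normal family
#'
#' The stochastic supply family for three resources has density on the
#' simplex proportional to `exp(-|s - (1/3,1/3,1/3)|^2 / (2 v))` with a
#' signed shape parameter `v`: small positive `v` concentrates supplies
#' near equal supply, `v -> +/- Inf` is the uniform distribution
#' (sigma_RS about 0.236), and small negative `v` concentrates mass in
#' the corners (sigma_RS -> 0.471).  `sigma_rs_for_shape()` computes the
#' realized sigma_RS for a given `v` by deterministic quadrature over
#' the simplex.
#'
#' @param v signed shape parameter (nonzero).
#' @param grid optional quadrature grid (internal).
#' @return realized sigma_RS.
#' @export
sigma_rs_for_shape <- function(v, grid = NULL) {
  if (!is.finite(v)) return(sigma_rs_uniform(3))
  if (v == 0) stop("shape parameter must be nonzero")
  if (is.null(grid)) grid <- get_quad_grid()
  ref <- if (v > 0) 0 else 2 / 3  # density maximum: center vs corner
  w <- exp(-(grid$d2 - ref) / (2 * v))
  sqrt(sum(w * grid$d2) / (3 * sum(w)))
}

get_quad_grid <- function() {
  if (is.null(.diauxie_env$quad_grid))
    .diauxie_env$quad_grid <- simplex_quad_grid()
  .diauxie_env$quad_grid
}

#' Calibration table for the fluctuation family
#'
#' Maps the signed shape parameter `v` to the realized fluctuation
#' magnitude on a log-spaced grid of both signs, by quadrature (see
#' [sigma_rs_for_shape()]).  The table is monotone within each sign and
#' is inverted by [fluctuation_shape()] to find the `v` that realizes a
#' target sigma_RS after accounting for clipping at the simplex
#' boundary.
#'
#' @param n_grid grid points per sign.
#' @param v_min,v_max magnitude range of the shape parameter.
#' @return data.frame with columns `v` and `sigma_rs`.
#' @export
calibrate_fluctuation_family <- function(n_grid = 61, v_min = 2e-4,
                                         v_max = 60) {
  grid <- get_quad_grid()
  vs <- 10^seq(log10(v_min), log10(v_max), length.out = n_grid)
  data.frame(
    v = c(vs, -vs),
    sigma_rs = c(vapply(vs, sigma_rs_for_shape, 0, grid = grid),
                 vapply(-vs, sigma_rs_for_shape, 0, grid = grid)))
}

fluctuation_table <- function() {
  if (is.null(.diauxie_env$fluct_table))
    .diauxie_env$fluct_table <- calibrate_fluctuation_family()
  .diauxie_env$fluct_table
}

#' Shape parameter realizing a target fluctuation magnitude
#'
#' Inverts the calibration table of [calibrate_fluctuation_family()].
#' For very small targets, where clipping at the simplex boundary is
#' negligible, the analytic small-fluctuation relation `v = 3 sigma^2 / 2`
#' is used directly.
#'
#' @param sigma_rs target magnitude in (0, 0.471), excluding the uniform
#'   point `sqrt(1/18)` (where the family is flat and `v` diverges).
#' @return signed shape parameter `v`.
#' @export
fluctuation_shape <- function(sigma_rs) {
  su <- sigma_rs_uniform(3)
  if (sigma_rs <= 0 || sigma_rs >= sigma_rs_single_resource(3))
    stop("sigma_rs must lie strictly between 0 and 0.471")
  tab <- fluctuation_table()
  if (sigma_rs < su) {
    pos <- tab[tab$v > 0, ]
    if (sigma_rs <= min(pos$sigma_rs)) return(3 * sigma_rs^2 / 2)
    if (sigma_rs >= max(pos$sigma_rs))
      stop("sigma_rs too close to the uniform point ", signif(su, 4),
           "; use the uniform sampler")
    exp(approx(pos$sigma_rs, log(pos$v), xout = sigma_rs)$y)
  } else {
    neg <- tab[tab$v < 0, ]
    neg <- neg[order(neg$sigma_rs), ]
    if (sigma_rs >= max(neg$sigma_rs))
      stop("sigma_rs too close to 0.471; use single_resource_supply()")
    if (sigma_rs <= min(neg$sigma_rs))
      stop("sigma_rs too close to the uniform point ", signif(su, 4),
           "; use the uniform sampler")
    -exp(approx(neg$sigma_rs, log(-neg$v), xout = sigma_rs)$y)
  }
}

#' Stochastic resource-supply sampler with target fluctuation magnitude
#'
#' Builds a per-cycle supply sampler for three resources whose draws
#' have root-mean-square deviation from equal supply equal to
#' `sigma_rs`.  The sampling density on the simplex is a normal centred
#' on equal supply, clipped at the boundary `s_i > 0`, whose (signed)
#' variance is read from a calibration lookup table so that the realized
#' magnitude matches the target after clipping.  Draws use a normal
#' proposal with boundary rejection at small magnitudes, and a uniform
#' proposal with rejection probability
#' `1 - p(s) / max(p(center), p(corner))` for `sigma_rs >= 0.21`.
#' The degenerate endpoints are handled exactly: `sigma_rs = 0` returns
#' constant equal supply, `sigma_rs = sqrt(1/18)` the uniform simplex
#' distribution, and `sigma_rs = sqrt(2/9)` a single random resource.
#'
#' @param sigma_rs target magnitude in [0, 0.471].
#' @param n_resources must be 3 for intermediate magnitudes (the family
#'   is defined on the three-simplex); the three exact endpoints are
#'   available for any number of resources.
#' @return function of `n` returning an `n` x `n_resources` supply
#'   matrix.
#' @examples
#' set.seed(1)
#' s <- supply_sampler(0.09)(1000)
#' round(fluctuation_magnitude(s), 2)
#' @export
supply_sampler <- function(sigma_rs, n_resources = 3) {
  smax <- sigma_rs_single_resource(n_resources)
  if (sigma_rs < 0 || sigma_rs > smax + 1e-9)
    stop("sigma_rs must lie in [0, ", signif(smax, 4), "]")
  if (sigma_rs == 0)
    return(function(n) constant_supply(n_resources, n))
  if (abs(sigma_rs - smax) < 1e-4)
    return(function(n) single_resource_supply(n_resources, n))
  su <- sigma_rs_uniform(n_resources)
  if (abs(sigma_rs - su) < 1e-4)
    return(function(n) sample_uniform_simplex(n_resources, n))
  if (n_resources != 3)
    stop("intermediate fluctuation magnitudes are defined for 3 resources; ",
         "use uniform, single-resource, or constant supply for other counts")
  v <- fluctuation_shape(sigma_rs)
  if (sigma_rs >= 0.21) sampler_rejection(v) else sampler_normal(v)
}

# uniform proposal on the simplex, thinned by the target density
sampler_rejection <- function(v) {
  ref <- if (v > 0) 0 else 2 / 3
  function(n) {
    out <- matrix(NA_real_, n, 3)
    got <- 0
    while (got < n) {
      m <- max(2L * (n - got), 256L)
      s <- sample_uniform_simplex(3, m)
      d2 <- rowSums((s - 1 / 3)^2)
      keep <- runif(m) < exp(-(d2 - ref) / (2 * v))
      k <- which(keep)
      if (length(k) > 0) {
        k <- k[seq_len(min(length(k), n - got))]
        out[(got + 1):(got + length(k)), ] <- s[k, , drop = FALSE]
        got <- got + length(k)
      }
    }
    out
  }
}

# isotropic normal in the simplex plane, rejecting draws outside s_i >= 0
sampler_normal <- function(v) {
  stopifnot(v > 0)
  e1 <- c(1, -1, 0) / sqrt(2)
  e2 <- c(1, 1, -2) / sqrt(6)
  sdv <- sqrt(v)
  function(n) {
    out <- matrix(NA_real_, n, 3)
    got <- 0
    while (got < n) {
      m <- max(2L * (n - got), 256L)
      x1 <- rnorm(m, sd = sdv)
      x2 <- rnorm(m, sd = sdv)
      s <- cbind(1 / 3 + x1 * e1[1] + x2 * e2[1],
                 1 / 3 + x1 * e1[2] + x2 * e2[2],
                 1 / 3 + x1 * e1[3] + x2 * e2[3])
      k <- which(s[, 1] >= 0 & s[, 2] >= 0 & s[, 3] >= 0)
      if (length(k) > 0) {
        k <- k[seq_len(min(length(k), n - got))]
        out[(got + 1):(got + length(k)), ] <- s[k, , drop = FALSE]
        got <- got + length(k)
      }
    }
    out
  }
}

#' Resolve a supply specification to a per-cycle schedule matrix
#'
#' Accepts a matrix (used as-is), a single supply vector (recycled), or
#' a sampler function of `n` (as returned by [supply_sampler()]).
#'
#' @param supply matrix, vector, or function.
#' @param n_cycles number of cycles.
#' @param n_resources number of resources (checked).
#' @return `n_cycles` x `n_resources` matrix.
#' @export
resolve_supply <- function(supply, n_cycles, n_resources) {
  s <- if (is.function(supply)) supply(n_cycles)
       else if (is.matrix(supply)) supply
       else matrix(supply, n_cycles, length(supply), byrow = TRUE)
  if (ncol(s) != n_resources)
    stop("supply has ", ncol(s), " resources; pool has ", n_resources)
  if (nrow(s) < n_cycles)
    stop("supply schedule shorter than n_cycles")
  s <- s[seq_len(n_cycles), , drop = FALSE]
  if (any(s < 0)) stop("negative supply")
  bad <- abs(rowSums(s) - 1) > 1e-9
  if (any(bad)) stop("supply rows must sum to 1")
  s
}
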