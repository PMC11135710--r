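# Independent oracle for one growth cycle: phase-by-phase numerical ODE
# integration (lsodar with root finding on the concentrations) instead of
# the analytic sum-of-exponentials event solver.
ode_depletion_oracle <- function(pool, n0, supply, tmax = 1e4) {
  g <- pool$growth_rates
  S <- nrow(g); N <- ncol(g)
  conc <- as.numeric(supply)
  dep <- ifelse(conc > 0, NA_real_, 0)
  t <- 0
  n <- as.numeric(n0)
  while (any(conc > 0)) {
    avail <- which(conc > 0)
    eater <- rep(NA_integer_, S)
    for (mu in which(n > 0))
      eater[mu] <- active_resource(pool$preferences[mu, ], avail)
    deriv <- function(tt, y, parms) {
      nn <- y[1:S]
      dn <- numeric(S); dc <- numeric(N)
      for (mu in which(!is.na(eater))) {
        i <- eater[mu]
        dn[mu] <- g[mu, i] * nn[mu]
        dc[i] <- dc[i] - g[mu, i] * nn[mu]
      }
      list(c(dn, dc))
    }
    root <- function(tt, y, parms) y[S + avail]
    sol <- deSolve::lsodar(c(n, conc), times = c(0, tmax), func = deriv,
                           rootfunc = root, rtol = 1e-11, atol = 1e-14)
    troot <- attr(sol, "troot")
    if (is.null(troot) || length(troot) == 0)
      stop("oracle: no depletion event found")
    fin <- unname(sol[nrow(sol), -1])
    n <- pmax(fin[1:S], 0)
    conc <- fin[S + 1:N]
    t <- t + troot[1]
    conc[abs(conc) < 1e-9] <- 0
    conc[conc < 0] <- 0
    dep[is.na(dep) & conc == 0] <- t
  }
  list(depletion_times = dep, end_populations = n, cycle_length = t)
}

# random small test instance: pool plus feasible initial state
random_small_instance <- function(n_resources = sample(2:4, 1),
                                  n_species = sample(2:5, 1)) {
  pool <- sample_pool(n_resources, n_species)
  supply <- as.numeric(sample_uniform_simplex(n_resources, 1))
  n0 <- runif(n_species, 0.01, 0.1)
  list(pool = pool, supply = supply, n0 = n0)
}
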