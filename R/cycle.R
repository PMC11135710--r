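#' Resource a species eats given the available set
#'
#' Under diauxie a species always consumes the highest-ranked resource,
#' by its own preference order, among those still available.
#'
#' @param preference_order integer permutation (rank 1 first), or a
#'   `species_traits` object.
#' @param available integer vector of available resource indices (may be
#'   empty).
#' @return resource index, or `NA_integer_` if nothing is available.
#' @examples
#' active_resource(c(3, 1, 2), c(2))       # 2: only option
#' active_resource(c(1, 2, 3), c(2, 3))    # 2: highest remaining rank
#' @export
active_resource <- function(preference_order, available) {
  if (inherits(preference_order, "species_traits"))
    preference_order <- preference_order$preference_order
  hit <- preference_order[preference_order %in% available]
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

#' Solve one growth phase for the next depletion event
#'
#' Within a phase every species eats one fixed resource, so each
#' concentration decays as
#' `c_i(t) = c_i(0) - sum_{mu eating i} n_mu (exp(g_mu_i t) - 1)`,
#' a strictly decreasing curve wherever the resource has consumers.  The
#' next event is the earliest time at which some available resource hits
#' zero, located by bracketed root-finding; resources with no consumers
#' produce no event.
#'
#' @param populations numeric vector of biomasses.
#' @param growth_rates S x N rate matrix.
#' @param eater integer vector: resource index each species is eating.
#' @param concentrations numeric vector of current concentrations; only
#'   entries with `concentrations > 0` are considered available.
#' @param tol absolute time tolerance of the root (hours).
#' @return list with `dt` (time to the event), `depleted` (resource
#'   indices hitting zero at the event, possibly several), and
#'   `event_times` (per-resource depletion time, `Inf` where no event).
#' @export
solve_phase <- function(populations, growth_rates, eater, concentrations,
                        tol = 1e-12) {
  N <- length(concentrations)
  avail <- which(concentrations > 0)
  if (length(avail) == 0) stop("no available resources")
  times <- rep(Inf, N)
  for (i in avail) {
    mu <- which(eater == i & populations > 0)
    if (length(mu) == 0) next
    n <- populations[mu]
    g <- growth_rates[cbind(mu, rep(i, length(mu)))]
    ci <- concentrations[i]
    if (length(mu) == 1) {
      times[i] <- log1p(ci / n) / g
    } else {
      # bracket: all biomass at the fastest rate depletes no later than
      # the truth; any single consumer alone no earlier
      lo <- log1p(ci / sum(n)) / max(g)
      hi <- min(log1p(ci / n) / g)
      f <- function(t) sum(n * expm1(g * t)) - ci
      times[i] <- if (hi - lo < tol) lo else
        uniroot(f, c(lo, hi), tol = tol, extendInt = "no")$root
    }
  }
  if (all(!is.finite(times[avail])))
    stop("dynamics stalled: no available resource has a consumer")
  dt <- min(times[avail])
  list(dt = dt,
       depleted = avail[times[avail] <= dt + 1e-10],
       event_times = times)
}

#' Run one complete growth cycle (reference R engine)
#'
#' Iterates [solve_phase()] between depletion events, reassigning every
#' species to its top remaining preference after each event, until all
#' supplied resources are depleted.  Resources supplied at zero are
#' treated as depleted at time zero.  Total biomass gained over the
#' cycle equals the total supply (all yields are 1).
#'
#' @param pool a `species_pool`.
#' @param populations starting biomasses (one per species; zeros mark
#'   absent species).
#' @param supply supply vector `s_i` (nonnegative, summing to 1).
#' @return A `cycle_record`: list with `depletion_times` (hours; 0 for
#'   zero-supply resources), `depletion_order`, `phase_boundaries`,
#'   `niches` (available-resource set per phase), `eater_map` (per
#'   phase, the resource each extant species ate), `tau` (S x N matrix
#'   of time spent on each preference rank), `start_populations`,
#'   `end_populations`, and `cycle_length`.
#' @examples
#' pool <- pool_from_traits(species_traits(c(0.5, 0.5), c(1, 2), "A"))
#' rec <- run_growth_cycle(pool, c(1 / 9), c(0.5, 0.5))
#' rec$cycle_length  # log(10) / 0.5
#' @export
run_growth_cycle <- function(pool, populations, supply) {
  g <- pool$growth_rates
  S <- nrow(g); N <- ncol(g)
  supply <- as.numeric(supply)
  if (length(supply) != N) stop("supply length mismatch")
  if (any(supply < 0)) stop("negative supply")
  if (abs(sum(supply) - 1) > 1e-9) stop("supply must sum to 1")
  populations <- as.numeric(populations)
  if (length(populations) != S) stop("populations length mismatch")
  if (all(populations <= 0)) stop("no species present")

  conc <- supply
  dep_time <- ifelse(supply > 0, NA_real_, 0)
  t <- 0
  n <- populations
  tau <- matrix(0, S, N)
  boundaries <- 0
  niches <- list()
  eater_map <- list()
  extant <- which(n > 0)
  rank_of <- t(apply(pool$preferences, 1, order)) # rank_of[mu, i]

  while (any(conc > 0)) {
    avail <- which(conc > 0)
    eater <- rep(NA_integer_, S)
    for (mu in extant) eater[mu] <- active_resource(pool$preferences[mu, ], avail)
    ev <- solve_phase(n, g, eater, conc)
    niches[[length(niches) + 1]] <- avail
    eater_map[[length(eater_map) + 1]] <- eater
    # consumption during the phase
    for (i in avail) {
      mu <- which(eater == i)
      if (length(mu) > 0)
        conc[i] <- conc[i] -
          sum(n[mu] * expm1(g[cbind(mu, rep(i, length(mu)))] * ev$dt))
    }
    for (mu in extant) {
      tau[mu, rank_of[mu, eater[mu]]] <- tau[mu, rank_of[mu, eater[mu]]] + ev$dt
      n[mu] <- n[mu] * exp(g[mu, eater[mu]] * ev$dt)
    }
    t <- t + ev$dt
    conc[ev$depleted] <- 0
    conc[conc < 1e-10 & conc > 0] <- 0  # simultaneous depletion within tolerance
    if (any(conc < -1e-8)) stop("concentration went negative beyond tolerance")
    dep_time[is.na(dep_time) & conc == 0] <- t
    boundaries <- c(boundaries, t)
  }
  gained <- sum(n) - sum(populations)
  if (abs(gained - sum(supply)) > 1e-6) stop("mass balance violated")
  structure(list(depletion_times = dep_time,
                 depletion_order = order(dep_time, seq_len(N)),
                 phase_boundaries = boundaries,
                 niches = niches,
                 eater_map = eater_map,
                 tau = tau,
                 start_populations = populations,
                 end_populations = n,
                 cycle_length = t,
                 supply = supply),
            class = "cycle_record")
}

#' Mortality and resupply between growth cycles
#'
#' After all resources are depleted, every population is divided by the
#' mortality factor (10 by default) and concentrations are reset to the
#' next cycle's supply.
#'
#' @param populations biomasses at the end of a cycle.
#' @param supply next cycle's supply vector.
#' @param mortality mortality factor (> 1).
#' @return list with `populations` and `concentrations`.
#' @export
apply_mortality_and_resupply <- function(populations, supply,
                                         mortality = 10) {
  if (mortality <= 1) stop("mortality factor must exceed 1")
  list(populations = populations / mortality,
       concentrations = as.numeric(supply))
}

#' End-of-cycle population fractions
#'
#' Fractions are biomasses normalised by total biomass.  At the
#' steady-state total of 10/9 (total supply 1 plus the carryover 1/9)
#' this equals `(9/10) * n`.
#'
#' @param populations biomass vector.
#' @return fractions summing to 1.
#' @export
population_fractions <- function(populations) {
  tot <- sum(populations)
  if (tot <= 0) stop("total biomass must be positive")
  populations / tot
}
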