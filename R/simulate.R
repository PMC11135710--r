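#' Default trajectory thinning schedule
#'
#' Long serial-dilution runs are recorded on a progressively coarser
#' grid: every cycle up to 10, every 2nd to 50, every 5th to 200, every
#' 10th to 1,000, every 20th to 2,000, every 50th to 4,000, every 100th
#' to 7,000, every 200th to 10,000, and every 500th to 1,000,000.
#'
#' @return data.frame with columns `upto` and `stride`.
#' @export
default_thin_schedule <- function() {
  data.frame(upto = c(10, 50, 200, 1000, 2000, 4000, 7000, 1e4, 1e6),
             stride = c(1, 2, 5, 10, 20, 50, 100, 200, 500))
}

#' Cycles retained by a thinning schedule
#'
#' @param n_cycles run length.
#' @param schedule data.frame as in [default_thin_schedule()].
#' @return sorted integer vector of retained 1-based cycle indices.
#' @examples
#' head(thin_cycles(100), 15)  # 1..10, 12, 14, ...
#' @export
thin_cycles <- function(n_cycles, schedule = default_thin_schedule()) {
  lower <- c(0, head(schedule$upto, -1))
  out <- unlist(lapply(seq_len(nrow(schedule)), function(r) {
    if (lower[r] >= n_cycles) return(integer())
    seq(lower[r] + schedule$stride[r],
        min(schedule$upto[r], n_cycles), by = schedule$stride[r])
  }))
  sort(unique(c(as.integer(out), as.integer(n_cycles))))
}

default_inoculum <- function(n_species, total = 1 / 9) {
  rep(total / n_species, n_species)
}

#' Simulate serial-dilution growth cycles
#'
#' Runs `n_cycles` boom-and-bust cycles for a species pool: on each
#' cycle resources are supplied, species grow by exact event-driven
#' piecewise-exponential dynamics until all supplied resources are
#' depleted, end-of-cycle population fractions are recorded, populations
#' are divided by the mortality factor, and species whose population
#' fraction has fallen below the extinction threshold are removed.
#'
#' @param pool a `species_pool`.
#' @param supply per-cycle supply: a matrix (`n_cycles` x N), a single
#'   vector (recycled), or a sampler function of `n` such as
#'   [supply_sampler()] returns.  Sampler draws consume the R random
#'   number stream, so runs are reproducible under `set.seed()`.
#' @param n_cycles number of growth cycles (>= 1).
#' @param init initial biomasses; default is equal biomass per species
#'   with total 1/9 (the steady-state carryover, since total supply is 1
#'   and mortality divides by 10).
#' @param mortality mortality factor applied between cycles.
#' @param extinction_threshold species are removed when their population
#'   fraction `n / sum(n)` drops below this value (default 1e-12).
#' @param record which end-of-cycle fraction vectors to keep:
#'   `"thinned"` (default, see [default_thin_schedule()]), `"all"`,
#'   `"none"`, or an integer vector of cycles.
#' @param detail_window fraction of final cycles over which
#'   time-on-preference statistics are accumulated (default 0.2).
#' @param engine `"compiled"` (default) or `"R"` (reference
#'   implementation; also keeps full per-cycle records when
#'   `keep_records = TRUE`).
#' @param keep_records R engine only: keep every [run_growth_cycle()]
#'   record (memory-heavy; for small runs and tests).
#' @return An object of class `"diauxie_sim"`; see Details.
#' @details The returned object contains `fractions` (recorded cycles x
#'   species), `recorded_cycles`, `depletion_times` (cycles x resources,
#'   in hours within each cycle; 0 for zero-supply resources),
#'   `cycle_lengths`, `extinction_cycle` (NA for survivors),
#'   `survivors` (indices of extant species), `populations` (after the
#'   final mortality), `tau_rank` (species x preference-rank mean hours
#'   per cycle over the detail window), and the run settings.
#' @examples
#' pool <- sample_pool(3, 20, seed = 1)
#' set.seed(2)
#' sim <- run_serial_dilution(pool, sample_uniform_simplex(3, 200), 200)
#' length(sim$survivors)
#' @export
run_serial_dilution <- function(pool, supply, n_cycles = NULL, init = NULL,
                                mortality = 10, extinction_threshold = 1e-12,
                                record = "thinned", detail_window = 0.2,
                                engine = c("compiled", "R"),
                                keep_records = FALSE) {
  engine <- match.arg(engine)
  if (!inherits(pool, "species_pool")) stop("pool must be a species_pool")
  if (mortality <= 1) stop("mortality factor must exceed 1")
  if (extinction_threshold <= 0 || extinction_threshold >= 1)
    stop("extinction threshold must lie in (0, 1)")
  S <- nrow(pool$growth_rates); N <- ncol(pool$growth_rates)
  if (is.null(n_cycles)) {
    if (!is.matrix(supply)) stop("n_cycles required unless supply is a matrix")
    n_cycles <- nrow(supply)
  }
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  supply <- resolve_supply(supply, n_cycles, N)
  if (is.null(init)) init <- default_inoculum(S)
  if (length(init) != S || any(init < 0) || sum(init) <= 0)
    stop("invalid initial biomasses")

  rec_cycles <-
    if (is.numeric(record)) sort(unique(as.integer(record)))
    else switch(record,
                thinned = thin_cycles(n_cycles),
                all = seq_len(n_cycles),
                none = integer(),
                stop("unknown record option"))
  rec_cycles <- rec_cycles[rec_cycles >= 1 & rec_cycles <= n_cycles]
  detail_from <- n_cycles - floor(detail_window * n_cycles) + 1L

  if (engine == "compiled") {
    res <- .sim_serial_dilution_cpp(pool$growth_rates, pool$preferences,
                                    init, supply, mortality,
                                    extinction_threshold,
                                    as.integer(rec_cycles),
                                    as.integer(detail_from),
                                    1e-13, 1e-10)
    records <- NULL
  } else {
    res <- sim_serial_dilution_r(pool, init, supply, mortality,
                                 extinction_threshold, rec_cycles,
                                 detail_from, keep_records)
    records <- res$records
  }
  tau_cycles <- res$tau_cycles
  out <- list(pool = pool, n_resources = N, n_cycles = n_cycles,
              supply = supply,
              fractions = res$fractions, recorded_cycles = rec_cycles,
              depletion_times = res$depletion_times,
              cycle_lengths = as.numeric(res$cycle_lengths),
              extinction_cycle = res$extinction_cycle,
              populations = as.numeric(res$populations),
              survivors = which(is.na(res$extinction_cycle)),
              tau_rank = if (tau_cycles > 0) res$tau / tau_cycles else res$tau,
              tau_cycles = tau_cycles, detail_from = detail_from,
              mortality = mortality,
              extinction_threshold = extinction_threshold,
              records = records, engine = engine)
  colnames(out$fractions) <- pool$species_id
  rownames(out$fractions) <- rec_cycles
  class(out) <- "diauxie_sim"
  out
}

# reference pure-R serial-dilution loop
sim_serial_dilution_r <- function(pool, init, supply, mortality,
                                  extinct_frac, rec_cycles, detail_from,
                                  keep_records) {
  S <- nrow(pool$growth_rates); N <- ncol(pool$growth_rates)
  n_cycles <- nrow(supply)
  n <- init
  fractions <- matrix(NA_real_, length(rec_cycles), S)
  dep_times <- matrix(NA_real_, n_cycles, N)
  cycle_lengths <- numeric(n_cycles)
  extinction_cycle <- rep(NA_integer_, S)
  tau <- matrix(0, S, N)
  tau_cycles <- 0L
  records <- if (keep_records) vector("list", n_cycles) else NULL
  for (k in seq_len(n_cycles)) {
    rec <- run_growth_cycle(pool, n, supply[k, ])
    if (keep_records) records[[k]] <- rec
    dep_times[k, ] <- rec$depletion_times
    cycle_lengths[k] <- rec$cycle_length
    if (k >= detail_from) {
      tau <- tau + rec$tau
      tau_cycles <- tau_cycles + 1L
    }
    n <- rec$end_populations
    f <- n / sum(n)
    if (k %in% rec_cycles) fractions[match(k, rec_cycles), ] <- f
    n <- n / mortality
    dead <- which(f < extinct_frac & n > 0)
    if (length(dead) > 0) {
      n[dead] <- 0
      extinction_cycle[dead] <- k
    }
    if (all(n == 0)) stop("all species went extinct on cycle ", k)
  }
  list(fractions = fractions, depletion_times = dep_times,
       cycle_lengths = cycle_lengths, extinction_cycle = extinction_cycle,
       populations = n, tau = tau, tau_cycles = tau_cycles,
       records = records)
}

#' Thin the recorded trajectory of a simulation
#'
#' @param sim a `diauxie_sim`.
#' @param schedule thinning schedule (see [default_thin_schedule()]).
#' @return the simulation with `fractions` restricted to the scheduled
#'   cycles (intersected with what was recorded).
#' @export
thin_trajectory <- function(sim, schedule = default_thin_schedule()) {
  keep <- intersect(thin_cycles(sim$n_cycles, schedule),
                    sim$recorded_cycles)
  idx <- match(keep, sim$recorded_cycles)
  sim$fractions <- sim$fractions[idx, , drop = FALSE]
  sim$recorded_cycles <- keep
  sim
}

#' @export
print.diauxie_sim <- function(x, ...) {
  cat("Diauxie serial-dilution simulation\n")
  cat("  ", length(x$pool$species_id), "species,", x$n_resources,
      "resources,", x$n_cycles, "cycles (", x$engine, "engine )\n")
  cat("  survivors:", length(x$survivors), "of",
      length(x$pool$species_id), "\n")
  invisible(x)
}

#' @export
summary.diauxie_sim <- function(object, ...) {
  surv <- object$survivors
  tal <- tally_niches(object)
  out <- list(n_species = length(object$pool$species_id),
              n_resources = object$n_resources,
              n_cycles = object$n_cycles,
              n_survivors = length(surv),
              survivor_ids = object$pool$species_id[surv],
              ce_violation = length(surv) > object$n_resources,
              mean_cycle_length = mean(object$cycle_lengths),
              n_niches = nrow(tal$niches),
              final_fractions =
                population_fractions(object$populations)[surv])
  class(out) <- "summary.diauxie_sim"
  out
}

#' @export
print.summary.diauxie_sim <- function(x, ...) {
  cat(x$n_survivors, "of", x$n_species, "species survive on",
      x$n_resources, "resources after", x$n_cycles, "cycles\n")
  cat("  competitive exclusion violated:", x$ce_violation, "\n")
  cat("  distinct temporal niches observed:", x$n_niches,
      "(max", max_niche_count(x$n_resources), ")\n")
  cat("  mean cycle length:", signif(x$mean_cycle_length, 4), "hr\n")
  if (x$n_survivors <= 12) {
    cat("  survivor fractions:\n")
    print(round(stats::setNames(x$final_fractions, x$survivor_ids), 4))
  }
  invisible(x)
}

#' Plot end-of-cycle population fractions
#'
#' @param x a `diauxie_sim` with recorded fractions.
#' @param log use a log10 y-axis (default TRUE).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.diauxie_sim <- function(x, log = TRUE, ...) {
  if (length(x$recorded_cycles) == 0) stop("no recorded cycles")
  f <- x$fractions
  f[f <= 0] <- NA
  graphics::matplot(x$recorded_cycles, f, type = "l", lty = 1,
                    log = if (log) "y" else "",
                    xlab = "growth cycle",
                    ylab = "population fraction", ...)
  invisible(x)
}
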