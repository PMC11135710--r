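#' Maximum number of temporal niches / coexisting species
#'
#' A temporal niche is a period of a growth cycle during which a given
#' nonempty subset of resources remains available.  There are `2^n - 1`
#' such subsets (the all-depleted state is not a niche), which bounds
#' the number of stably coexisting species under diauxic competition
#' with fluctuating depletion orders.
#'
#' @param n_resources number of resources.
#' @return integer `2^n_resources - 1`.
#' @examples
#' max_niche_count(3)  # 7
#' @export
max_niche_count <- function(n_resources) {
  if (n_resources < 1) stop("n_resources must be >= 1")
  as.integer(2^n_resources - 1)
}

# canonical label for a resource subset, e.g. "1+2+3"
niche_label <- function(resources) paste(sort(resources), collapse = "+")

#' Temporal niches realized on one growth cycle
#'
#' Given the within-cycle depletion times, the cycle decomposes into
#' phases separated by depletion events; the niche of each phase is the
#' set of resources still available.  Resources supplied at zero are
#' depleted at time 0 and never appear in any niche.
#'
#' @param record a `cycle_record` from [run_growth_cycle()], or a
#'   numeric vector of per-resource depletion times (hours; 0 or
#'   negative marks an unsupplied resource).
#' @param tol times closer than this are one simultaneous event.
#' @return data.frame with columns `niche` (label such as `"1+2"`),
#'   `duration` (hours), and `n_available`, one row per phase in
#'   temporal order.
#' @examples
#' niches_of_cycle(c(2.5, 4.0, 1.0))  # 1+2+3, then 1+2, then 2
#' @export
niches_of_cycle <- function(record, tol = 1e-9) {
  dep <- if (inherits(record, "cycle_record")) record$depletion_times
         else as.numeric(record)
  supplied <- which(dep > tol)
  if (length(supplied) == 0)
    stop("no supplied resources: no niches on this cycle")
  events <- sort(unique(dep[supplied]))
  # merge events closer than tol
  keep <- c(TRUE, diff(events) > tol)
  events <- events[keep]
  bounds <- c(0, events)
  out <- lapply(seq_along(events), function(p) {
    avail <- supplied[dep[supplied] > bounds[p] + tol]
    data.frame(niche = niche_label(avail),
               duration = bounds[p + 1] - bounds[p],
               n_available = length(avail),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tally distinct temporal niches across a run
#'
#' Unions the per-cycle niche sequences over a window of cycles,
#' counting occurrences and mean durations.  Niche identity is the set
#' of available resources (durations are ignored when deciding
#' distinctness).
#'
#' @param sim a `diauxie_sim`, or a matrix of per-cycle depletion times
#'   (cycles x resources).
#' @param window fraction of final cycles to include (default 0.2), or
#'   an integer vector of cycle indices.
#' @return An object of class `"niche_tally"`: list with `niches`
#'   (data.frame: `niche`, `count`, `mean_duration`), `n_cycles`,
#'   `n_resources`, `max_niches`.
#' @export
tally_niches <- function(sim, window = 0.2) {
  dep <- if (inherits(sim, "diauxie_sim")) sim$depletion_times
         else as.matrix(sim)
  n_cycles <- nrow(dep)
  idx <- if (length(window) == 1 && window <= 1)
    seq(n_cycles - floor(window * n_cycles) + 1, n_cycles)
  else as.integer(window)
  idx <- idx[idx >= 1 & idx <= n_cycles]
  if (length(idx) == 0) stop("empty cycle window")
  per <- lapply(idx, function(k) niches_of_cycle(dep[k, ]))
  all <- do.call(rbind, per)
  agg <- aggregate(all$duration, by = list(niche = all$niche),
                   FUN = function(d) c(n = length(d), mean = mean(d)))
  niches <- data.frame(niche = agg$niche,
                       count = as.integer(agg$x[, "n"]),
                       mean_duration = agg$x[, "mean"],
                       stringsAsFactors = FALSE)
  niches <- niches[order(-niches$count), ]
  rownames(niches) <- NULL
  structure(list(niches = niches, n_cycles = length(idx),
                 n_resources = ncol(dep),
                 max_niches = max_niche_count(ncol(dep))),
            class = "niche_tally")
}

#' @export
print.niche_tally <- function(x, ...) {
  cat("Temporal niches over", x$n_cycles, "cycles:",
      nrow(x$niches), "distinct (max", x$max_niches, ")\n")
  print(x$niches, digits = 4)
  invisible(x)
}

#' @importFrom stats aggregate setNames
NULL

#' Mean time spent growing on each preference rank
#'
#' For each preference rank k, the average time per growth cycle that a
#' species spends consuming its k-th preferred resource, averaged over
#' cycles in the simulation's detail window and then (unweighted) over
#' the requested species.
#'
#' @param sim a `diauxie_sim`.
#' @param species indices to average over; default the survivors.
#' @return numeric vector `tau` of length `n_resources` (hours per
#'   cycle), with attribute `"per_species"` holding the species x rank
#'   matrix.
#' @export
time_on_preferences <- function(sim, species = sim$survivors) {
  if (sim$tau_cycles == 0)
    stop("no time-on-preference statistics were recorded")
  m <- sim$tau_rank[species, , drop = FALSE]
  tau <- colMeans(m)
  names(tau) <- paste0("rank", seq_along(tau))
  attr(tau, "per_species") <- m
  tau
}

#' Optimal growth-rate allocation across preference ranks
#'
#' With the metabolic constraint `sum(g_k^2) = 1` and mean time `tau_k`
#' spent on the k-th preference, a species' log-growth per cycle is
#' `sum_k g_k tau_k`; the allocation maximising it on the unit sphere
#' is `g* = tau / |tau|_2`.
#'
#' @param tau nonnegative per-rank mean times (hours), not all zero.
#' @return unit-norm allocation vector (rate on rank-1 preference
#'   first).
#' @examples
#' optimal_allocation(c(0.5, 0.3, 0.2))
#' @export
optimal_allocation <- function(tau) {
  tau <- as.numeric(tau)
  if (any(tau < 0)) stop("tau must be nonnegative")
  nrm <- sqrt(sum(tau^2))
  if (nrm == 0) stop("tau must not be all zero")
  tau / nrm
}

# all permutations of 1..n, rows
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub), n - 1))
  }))
}

#' Predicted optimal strategies for every preference order
#'
#' Applies the [optimal_allocation()] of a given time-on-preference
#' profile to each of the `n!` resource preference orders, yielding a
#' set of strategies that together would form an uninvadable
#' "supersaturated" community (6 strategies for three resources).
#'
#' @param tau per-rank mean times.
#' @param n_resources number of resources (default `length(tau)`).
#' @return An object of class `"strategy_set"`: list with
#'   `growth_rates` (n! x N matrix: rate on each resource),
#'   `preferences` (n! x N preference orders), `allocation` (the shared
#'   per-rank allocation).
#' @export
optimal_strategy_set <- function(tau, n_resources = length(tau)) {
  alloc <- optimal_allocation(tau)
  if (length(alloc) != n_resources) stop("tau length must match n_resources")
  perms <- permutations_of(n_resources)
  g <- matrix(0, nrow(perms), n_resources)
  for (r in seq_len(nrow(perms)))
    g[r, perms[r, ]] <- alloc  # rank-k preference gets allocation k
  structure(list(growth_rates = g, preferences = perms,
                 allocation = alloc),
            class = "strategy_set")
}

#' @export
print.strategy_set <- function(x, ...) {
  cat("Optimal strategy set:", nrow(x$growth_rates), "preference orders\n")
  cat("  allocation by rank:", paste(signif(x$allocation, 4),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' 2-D simplex (barycentric) coordinates for three-component vectors
#'
#' Maps a nonnegative 3-vector to the triangle with corners at (0,0),
#' (1,0) and (1/2, sqrt(3)/2).  In `"supply"` mode the vector is
#' normalised to sum 1; in `"squared-growth"` mode the squared,
#' normalised growth rates `g_i^2 / sum(g^2)` are embedded, a nonlinear
#' map under which complete specialisation on one resource still maps
#' to a corner and equal investment to the centroid.
#'
#' @param x 3-vector or matrix with 3 columns.
#' @param mode `"supply"` or `"squared-growth"`.
#' @return matrix with columns `x`, `y`.
#' @export
simplex_coordinates <- function(x, mode = c("supply", "squared-growth")) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 3) stop("simplex coordinates require 3 components")
  if (any(x < 0)) stop("components must be nonnegative")
  w <- if (mode == "squared-growth") x^2 else x
  w <- w / rowSums(w)
  corners <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  out <- w %*% corners
  colnames(out) <- c("x", "y")
  out
}

#' Distance from survivors to the nearest optimal strategy
#'
#' Euclidean distance in growth-rate space from each survivor's rate
#' vector to the nearest strategy of a [optimal_strategy_set()].
#'
#' @param survivor_rates matrix of survivor growth-rate vectors (rows).
#' @param strategies a `strategy_set` or a matrix of strategy rate
#'   vectors (rows).
#' @return numeric vector of per-survivor distances, with attributes
#'   `"mean"` and `"max"`.
#' @export
survivor_strategy_distance <- function(survivor_rates, strategies) {
  if (inherits(strategies, "strategy_set"))
    strategies <- strategies$growth_rates
  survivor_rates <- as.matrix(survivor_rates)
  if (nrow(survivor_rates) == 0) stop("no survivors supplied")
  if (ncol(survivor_rates) != ncol(strategies)) stop("dimension mismatch")
  d <- apply(survivor_rates, 1, function(g) {
    sqrt(min(rowSums(sweep(strategies, 2, g)^2)))
  })
  attr(d, "mean") <- mean(d)
  attr(d, "max") <- max(d)
  d
}
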