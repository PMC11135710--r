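#' Construct a single species definition
#'
#' A species is defined by its per-resource exponential growth rates
#' (hr^-1) and a preference permutation giving the order in which it
#' consumes resources (rank 1 = most preferred).  A species is
#' "anomalous" when its preference order does not sort its growth rates
#' in descending order (ties broken by resource index).
#'
#' @param growth_rates numeric vector of strictly positive rates (hr^-1).
#' @param preference_order permutation of `seq_along(growth_rates)`;
#'   defaults to the descending growth-rate order.
#' @param species_id identifier (any scalar); defaults to `"sp1"`.
#' @return An object of class `"species_traits"`: a list with elements
#'   `species_id`, `growth_rates`, `preference_order`, `anomalous`.
#' @examples
#' sp <- species_traits(c(0.2, 0.9, 0.38), c(1, 2, 3))
#' sp$anomalous  # TRUE: rates would order preferences (2, 3, 1)
#' @export
species_traits <- function(growth_rates, preference_order = NULL,
                           species_id = "sp1") {
  growth_rates <- as.numeric(growth_rates)
  n <- length(growth_rates)
  if (n < 1 || any(!is.finite(growth_rates)) || any(growth_rates <= 0))
    stop("growth rates must be strictly positive and finite")
  if (is.null(preference_order)) preference_order <- rate_order(growth_rates)
  preference_order <- as.integer(preference_order)
  if (!identical(sort(preference_order), seq_len(n)))
    stop("preference_order must be a permutation of 1..", n)
  structure(list(species_id = species_id,
                 growth_rates = growth_rates,
                 preference_order = preference_order,
                 anomalous = is_anomalous(growth_rates, preference_order)),
            class = "species_traits")
}

#' Descending growth-rate order (ties broken by resource index)
#' @param growth_rates numeric vector.
#' @return integer permutation: resource indices from fastest to slowest.
#' @export
rate_order <- function(growth_rates) {
  order(-growth_rates, seq_along(growth_rates))
}

#' Is a preference order anomalous for the given rates?
#'
#' @inheritParams species_traits
#' @return `TRUE` iff `preference_order` differs from [rate_order()].
#' @export
is_anomalous <- function(growth_rates, preference_order) {
  !identical(as.integer(preference_order), as.integer(rate_order(growth_rates)))
}

#' Sample random growth-rate vectors
#'
#' Under the L2 metabolic constraint, rate vectors are drawn uniformly
#' from the positive orthant of the unit sphere: each component is a
#' standard normal deviate, absolute values are taken, and the vector is
#' normalised to unit L2 norm (so that `sum(g^2) == 1` hr^-2 exactly).
#' The unconstrained mode draws each component from Uniform(0, 1]
#' without normalisation.
#'
#' @param n_resources number of resources.
#' @param n number of vectors to draw.
#' @param constraint `"L2"` (default) or `"unconstrained"`.
#' @return `n` x `n_resources` matrix of rates (hr^-1).
#' @export
sample_growth_rates <- function(n_resources, n = 1,
                                constraint = c("L2", "unconstrained")) {
  constraint <- match.arg(constraint)
  if (n_resources < 1) stop("n_resources must be >= 1")
  if (constraint == "L2") {
    g <- abs(matrix(rnorm(n * n_resources), n, n_resources))
    # guard against the measure-zero all-zero draw
    zero <- rowSums(g) == 0
    if (any(zero)) g[zero, 1] <- 1
    g / sqrt(rowSums(g^2))
  } else {
    matrix(1 - runif(n * n_resources), n, n_resources) # in (0, 1]
  }
}

#' Assign a resource-preference permutation
#'
#' @param growth_rates numeric vector of rates.
#' @param mode `"independent"` draws a uniform random permutation
#'   (allowing anomalous species); `"rate-ordered"` uses the descending
#'   growth-rate order (never anomalous).
#' @return integer permutation (rank 1 first).
#' @export
assign_preferences <- function(growth_rates,
                               mode = c("independent", "rate-ordered")) {
  mode <- match.arg(mode)
  n <- length(growth_rates)
  if (mode == "rate-ordered") rate_order(growth_rates) else sample.int(n)
}

#' Pool size from the sampling-density rule
#'
#' Pool sizes scale with the dimension of the constraint surface species
#' are sampled from: with the species density rho held constant across
#' resource numbers, `n_species = round(rho^dim)` with
#' `dim = n_resources - 1` and rho calibrated so that the three-resource
#' case uses `base_size` species.  The literal rule explodes for many
#' resources (about 1.2e8 species at 7 resources), so a hard cap is
#' applied with a warning; pool sizes are also directly overridable in
#' every driver that uses this rule.
#'
#' @param n_resources number of resources (>= 2).
#' @param base_size pool size at three resources (default 500).
#' @param max_size cap on the returned size (default 5000).
#' @return integer number of species.
#' @examples
#' pool_size(3)  # 500
#' pool_size(2)  # 22
#' @export
pool_size <- function(n_resources, base_size = 500, max_size = 5000) {
  if (n_resources < 2) stop("n_resources must be >= 2")
  rho <- base_size^(1 / 2)
  n <- round(rho^(n_resources - 1))
  if (n > max_size) {
    warning("pool size ", n, " capped at ", max_size)
    n <- max_size
  }
  as.integer(n)
}

#' Sample a random species pool
#'
#' @param n_resources number of resources.
#' @param n_species number of species.
#' @param constraint passed to [sample_growth_rates()].
#' @param preference_mode passed to [assign_preferences()].
#' @param seed optional integer; when given, sampling is wrapped in a
#'   local RNG state so the same seed always yields the same pool.
#' @return An object of class `"species_pool"`: a list with
#'   `growth_rates` (S x N matrix), `preferences` (S x N matrix, row =
#'   preference order of one species), `anomalous` (logical S),
#'   `species_id` (character S), plus the sampling settings.
#' @examples
#' pool <- sample_pool(3, 10, seed = 1)
#' all(abs(rowSums(pool$growth_rates^2) - 1) < 1e-12)
#' @export
sample_pool <- function(n_resources, n_species,
                        constraint = c("L2", "unconstrained"),
                        preference_mode = c("independent", "rate-ordered"),
                        seed = NULL) {
  constraint <- match.arg(constraint)
  preference_mode <- match.arg(preference_mode)
  if (n_species < 1) stop("n_species must be >= 1")
  draw <- function() {
    g <- sample_growth_rates(n_resources, n_species, constraint)
    pref <- t(vapply(seq_len(n_species),
                     function(s) assign_preferences(g[s, ], preference_mode),
                     integer(n_resources)))
    list(g = g, pref = pref)
  }
  d <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  new_species_pool(d$g, d$pref,
                   species_id = sprintf("sp%d", seq_len(n_species)),
                   constraint = constraint, preference_mode = preference_mode)
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @rdname sample_pool
#' @param growth_rates S x N matrix of rates.
#' @param preferences S x N matrix of preference permutations (rows).
#' @param species_id character vector of identifiers.
#' @export
new_species_pool <- function(growth_rates, preferences, species_id = NULL,
                             constraint = NA_character_,
                             preference_mode = NA_character_) {
  growth_rates <- as.matrix(growth_rates)
  preferences <- matrix(as.integer(as.matrix(preferences)),
                        nrow(preferences), ncol(preferences))
  S <- nrow(growth_rates); N <- ncol(growth_rates)
  if (!all(dim(preferences) == c(S, N))) stop("shape mismatch")
  if (any(!is.finite(growth_rates)) || any(growth_rates <= 0))
    stop("growth rates must be strictly positive and finite")
  for (s in seq_len(S))
    if (!identical(sort(preferences[s, ]), seq_len(N)))
      stop("row ", s, " of preferences is not a permutation")
  if (is.null(species_id)) species_id <- sprintf("sp%d", seq_len(S))
  anomalous <- vapply(seq_len(S),
                      function(s) is_anomalous(growth_rates[s, ],
                                               preferences[s, ]),
                      logical(1))
  structure(list(growth_rates = growth_rates, preferences = preferences,
                 species_id = as.character(species_id),
                 anomalous = anomalous, constraint = constraint,
                 preference_mode = preference_mode),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", nrow(x$growth_rates), "species on",
      ncol(x$growth_rates), "resources\n")
  cat("  constraint:", x$constraint,
      " preferences:", x$preference_mode, "\n")
  cat("  anomalous species:", sum(x$anomalous), "\n")
  invisible(x)
}

#' @export
length.species_pool <- function(x) nrow(x$growth_rates)

#' Subset a species pool
#' @param x a `species_pool`.
#' @param i index vector (integer, logical, or species ids).
#' @param ... unused.
#' @return a `species_pool` containing the selected species.
#' @export
`[.species_pool` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$species_id)
  new_species_pool(x$growth_rates[i, , drop = FALSE],
                   x$preferences[i, , drop = FALSE],
                   species_id = x$species_id[i],
                   constraint = x$constraint,
                   preference_mode = x$preference_mode)
}

#' Combine species_traits into a pool
#' @param ... `species_traits` objects.
#' @return a `species_pool`.
#' @export
pool_from_traits <- function(...) {
  sp <- list(...)
  if (length(sp) == 1 && is.list(sp[[1]]) && !inherits(sp[[1]], "species_traits"))
    sp <- sp[[1]]
  g <- do.call(rbind, lapply(sp, `[[`, "growth_rates"))
  pref <- do.call(rbind, lapply(sp, `[[`, "preference_order"))
  ids <- vapply(sp, function(s) as.character(s$species_id), character(1))
  new_species_pool(g, pref, species_id = ids)
}
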