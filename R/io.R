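#' Read and write species pools
#'
#' CSV layout: columns `species_id`, `g_1..g_N` (growth rates, hr^-1)
#' and `pref_1..pref_N` (preference order, most preferred first).  JSON
#' holds the same fields per species.
#'
#' @param pool a `species_pool`.
#' @param path file path.
#' @return `read_pool_*` return a `species_pool`; writers return the
#'   path invisibly.
#' @export
write_pool_csv <- function(pool, path) {
  N <- ncol(pool$growth_rates)
  df <- data.frame(species_id = pool$species_id,
                   pool$growth_rates, pool$preferences)
  names(df) <- c("species_id", paste0("g_", 1:N), paste0("pref_", 1:N))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_csv
#' @export
read_pool_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  gcols <- grep("^g_", names(df))
  pcols <- grep("^pref_", names(df))
  if (length(gcols) == 0 || length(gcols) != length(pcols))
    stop("malformed pool file: expected g_* and pref_* columns")
  new_species_pool(as.matrix(df[, gcols]), as.matrix(df[, pcols]),
                   species_id = df$species_id)
}

#' @rdname write_pool_csv
#' @export
write_pool_json <- function(pool, path) {
  N <- ncol(pool$growth_rates)
  species <- lapply(seq_along(pool$species_id), function(s) {
    list(species_id = pool$species_id[s],
         growth_rates = as.numeric(pool$growth_rates[s, ]),
         preference_order = as.integer(pool$preferences[s, ]))
  })
  jsonlite::write_json(list(n_resources = N, species = species), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pool_csv
#' @export
read_pool_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$species
  new_species_pool(do.call(rbind, sp$growth_rates),
                   do.call(rbind, sp$preference_order),
                   species_id = sp$species_id)
}

#' Write a recorded trajectory as tidy CSV
#'
#' One row per (cycle, species): columns `cycle`, `species_id`,
#' `fraction`.
#'
#' @param sim a `diauxie_sim` with recorded fractions.
#' @param path file path.
#' @export
write_trajectory_csv <- function(sim, path) {
  f <- sim$fractions
  df <- data.frame(cycle = rep(sim$recorded_cycles, ncol(f)),
                   species_id = rep(colnames(f), each = nrow(f)),
                   fraction = as.numeric(f))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return a data.frame with columns `cycle`, `species_id`, `fraction`.
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write per-cycle records as JSON lines
#'
#' One JSON object per cycle: `cycle`, `cycle_length`, and
#' `depletion_times`.
#'
#' @param sim a `diauxie_sim`.
#' @param path file path.
#' @param cycles which cycles to write (default all).
#' @export
write_cycle_records_json <- function(sim, path,
                                     cycles = seq_len(sim$n_cycles)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in cycles) {
    writeLines(jsonlite::toJSON(list(
      cycle = k, cycle_length = sim$cycle_lengths[k],
      depletion_times = as.numeric(sim$depletion_times[k, ])),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Run configuration
#'
#' Bundles and validates the serial-dilution run settings; readable
#' from YAML or JSON.
#'
#' @param seed integer master seed.
#' @param n_cycles number of growth cycles.
#' @param mortality_factor mortality divisor between cycles (> 1).
#' @param extinction_threshold population-fraction cutoff in (0, 1).
#' @param inoculation `"equal"` (equal biomass, total 1/9).
#' @return a validated list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_cycles = 10000, mortality_factor = 10,
                       extinction_threshold = 1e-12,
                       inoculation = "equal") {
  if (mortality_factor <= 1) stop("mortality_factor must exceed 1")
  if (extinction_threshold <= 0 || extinction_threshold >= 1)
    stop("extinction_threshold must lie in (0, 1)")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(seed = as.integer(seed), n_cycles = as.integer(n_cycles),
                 mortality_factor = mortality_factor,
                 extinction_threshold = extinction_threshold,
                 inoculation = inoculation),
            class = "run_config")
}

#' @rdname run_config
#' @param path a `.yaml`/`.yml` or `.json` file with the fields above.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj[intersect(names(obj), names(formals(run_config)))])
}

#' Constructed small communities for tests and demos
#'
#' Deterministic fixtures with documented expected outcomes:
#' \describe{
#'   \item{`mirror-pair`}{two species on two symmetrically supplied
#'     resources with rates swapped; by symmetry both survive at equal
#'     fractions.}
#'   \item{`two-species-coexistence`}{an asymmetric pair, each fastest
#'     on its own preferred resource; both coexist at unequal
#'     fractions.}
#'   \item{`three-specialists`}{three rate-ordered specialists, one per
#'     top resource preference; on three equally supplied resources all
#'     three survive.}
#'   \item{`random-small`}{a 6-species random pool on 3 resources drawn
#'     under a fixed internal seed (identical on every call).}
#' }
#'
#' @param kind fixture name.
#' @return a `species_pool`.
#' @export
generate_fixtures <- function(kind = c("mirror-pair",
                                       "two-species-coexistence",
                                       "three-specialists",
                                       "random-small")) {
  kind <- match.arg(kind)
  switch(kind,
    "mirror-pair" = pool_from_traits(
      species_traits(c(1.0, 0.5), c(1, 2), "A"),
      species_traits(c(0.5, 1.0), c(2, 1), "B")),
    "two-species-coexistence" = pool_from_traits(
      species_traits(c(1.0, 0.30), c(1, 2), "A"),
      species_traits(c(0.55, 0.85), c(2, 1), "B")),
    "three-specialists" = pool_from_traits(
      species_traits(c(0.95, 0.2, 0.2) / sqrt(sum(c(0.95, 0.2, 0.2)^2)),
                     c(1, 2, 3), "X1"),
      species_traits(c(0.2, 0.95, 0.2) / sqrt(sum(c(0.95, 0.2, 0.2)^2)),
                     c(2, 3, 1), "X2"),
      species_traits(c(0.2, 0.2, 0.95) / sqrt(sum(c(0.95, 0.2, 0.2)^2)),
                     c(3, 1, 2), "X3")),
    "random-small" = sample_pool(3, 6, seed = 20240513))
}
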