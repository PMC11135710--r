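#' Survivor-determination protocol
#'
#' Repeated-simulation protocol for declaring which species of a pool
#' stably coexist under a (possibly stochastic) supply schedule:
#' \enumerate{
#'   \item `n_primary` independent runs (fresh supply draws each) from a
#'     standard equal inoculum; the union of their survivors is
#'     collected (a species may drop out of one run through an early
#'     stochastic extinction yet belong in the final community);
#'   \item `n_headstart` further runs in which every species in that
#'     union starts with a ~`headstart_factor` (default 1000-fold)
#'     larger inoculum, renormalised to the standard total;
#'   \item species surviving at least `min_survivals` of the head-start
#'     runs are reported;
#'   \item a trend filter removes species that are clearly trending
#'     toward, but have not yet reached, the extinction threshold.
#'     "Clearly trending" means the log10 population fraction over the
#'     final fifth of cycles declines steadily: the decline is
#'     near-monotone (Spearman correlation with time below
#'     `trend_monotone`, so that supply-driven fluctuations of genuine
#'     survivors are not mistaken for decline), its fitted slope is
#'     below `trend_slope`, and extrapolating the decline forward would
#'     carry the fraction below the extinction threshold by
#'     `trend_horizon` total cycles (default 1e6, the longest
#'     equilibration horizon used in practice).  This is an automated,
#'     scale-aware surrogate for visual inspection of the time traces.
#' }
#'
#' @param pool a `species_pool`.
#' @param supply sampler function of `n`, matrix, or vector (see
#'   [resolve_supply()]).  Deterministic schedules make the repetitions
#'   identical; reduce `n_primary`/`n_headstart` to 1 in that case.
#' @param n_cycles cycles per repetition.
#' @param n_primary,n_headstart repetition counts (defaults 5 and 3).
#' @param headstart_factor inoculum advantage of prior survivors.
#' @param min_survivals head-start runs a species must survive (default
#'   2 of 3).
#' @param trend_filter apply the declining-trend filter (default TRUE).
#' @param trend_slope upper bound on the fitted slope (log10 fraction
#'   per cycle) for a species to count as declining (default 0).
#' @param trend_monotone Spearman-correlation threshold for a steady
#'   decline (default -0.9).
#' @param trend_horizon total-cycle horizon for the extrapolated
#'   extinction (default 1e6 cycles).
#' @param mortality,extinction_threshold passed to
#'   [run_serial_dilution()].
#' @param community_id optional label.
#' @return An object of class `"survivor_report"`: list with
#'   `survivors` (ids), `survivor_idx`, `n_survivors`, `ce_violation`
#'   (more survivors than resources), `headstart_counts`,
#'   `per_primary`/`per_headstart` survivor index lists, and
#'   `removed_by_trend`.
#' @export
survivor_protocol <- function(pool, supply, n_cycles = 10000,
                              n_primary = 5, n_headstart = 3,
                              headstart_factor = 1000, min_survivals = 2,
                              trend_filter = TRUE, trend_slope = 0,
                              trend_monotone = -0.9, trend_horizon = 1e6,
                              mortality = 10, extinction_threshold = 1e-12,
                              community_id = NULL) {
  S <- length(pool$species_id)
  N <- ncol(pool$growth_rates)
  if (min_survivals > n_headstart)
    stop("min_survivals cannot exceed n_headstart")
  win <- sort(unique(round(seq(n_cycles - floor(0.2 * n_cycles) + 1,
                               n_cycles, length.out = min(50, n_cycles)))))
  run1 <- function(init) {
    run_serial_dilution(pool, supply, n_cycles, init = init,
                        mortality = mortality,
                        extinction_threshold = extinction_threshold,
                        record = win)
  }
  per_primary <- vector("list", n_primary)
  for (r in seq_len(n_primary))
    per_primary[[r]] <- run1(NULL)$survivors
  union_idx <- sort(unique(unlist(per_primary)))

  init <- default_inoculum(S, total = 1)
  init[union_idx] <- init[union_idx] * headstart_factor
  init <- init / sum(init) / 9

  per_headstart <- vector("list", n_headstart)
  slopes <- finals <- rhos <- matrix(NA_real_, n_headstart, S)
  for (r in seq_len(n_headstart)) {
    sim <- run1(init)
    per_headstart[[r]] <- sim$survivors
    f <- sim$fractions
    for (mu in sim$survivors) {
      y <- log10(pmax(f[, mu], 1e-300))
      slopes[r, mu] <- unname(coef(lm(y ~ win))[2])
      rhos[r, mu] <- if (sd(y) == 0) 0 else
        suppressWarnings(cor(y, win, method = "spearman"))
      finals[r, mu] <- f[nrow(f), mu]
    }
  }
  counts <- tabulate(unlist(per_headstart), nbins = S)
  reported <- which(counts >= min_survivals)
  removed <- integer()
  if (trend_filter && length(reported) > 0) {
    for (mu in reported) {
      sl <- median(slopes[, mu], na.rm = TRUE)
      rho <- median(rhos[, mu], na.rm = TRUE)
      fin <- median(finals[, mu], na.rm = TRUE)
      if (is.finite(sl) && is.finite(fin) && is.finite(rho) &&
          sl < trend_slope && rho < trend_monotone &&
          log10(fin) + sl * max(trend_horizon - n_cycles, 0) <
            log10(extinction_threshold))
        removed <- c(removed, mu)
    }
    reported <- setdiff(reported, removed)
  }
  structure(list(community_id = community_id,
                 survivors = pool$species_id[reported],
                 survivor_idx = reported,
                 n_survivors = length(reported),
                 n_resources = N,
                 ce_violation = length(reported) > N,
                 headstart_counts = counts,
                 per_primary = per_primary,
                 per_headstart = per_headstart,
                 removed_by_trend = removed),
            class = "survivor_report")
}

#' @export
print.survivor_report <- function(x, ...) {
  cat("Survivor report", if (!is.null(x$community_id))
    paste0("(", x$community_id, ")"), "\n")
  cat("  ", x$n_survivors, "survivors on", x$n_resources, "resources;",
      "competitive exclusion violated:", x$ce_violation, "\n")
  if (x$n_survivors <= 20) cat("  ", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}

#' Competitive-exclusion-violation sweep over fluctuation magnitudes
#'
#' Applies [survivor_protocol()] to each pool at each fluctuation
#' magnitude (the same pools are reused across magnitudes) and
#' summarises the fraction of communities with more survivors than
#' resources and the mean number of survivors.
#'
#' @param pools list of `species_pool` objects (same resource count).
#' @param sigma_grid fluctuation magnitudes (see [supply_sampler()]).
#' @param n_cycles cycles per repetition.
#' @param ... further arguments to [survivor_protocol()].
#' @return An object of class `"ce_sweep"`: list with `summary`
#'   (data.frame: `sigma_rs`, `violation_fraction`, `mean_survivors`,
#'   `sem_survivors`), `counts` (pools x magnitudes survivor matrix),
#'   and `reports`.
#' @export
ce_violation_sweep <- function(pools, sigma_grid, n_cycles = 10000, ...) {
  N <- ncol(pools[[1]]$growth_rates)
  counts <- matrix(NA_integer_, length(pools), length(sigma_grid),
                   dimnames = list(NULL, signif(sigma_grid, 4)))
  reports <- vector("list", length(sigma_grid))
  for (j in seq_along(sigma_grid)) {
    sampler <- supply_sampler(sigma_grid[j], N)
    reports[[j]] <- lapply(seq_along(pools), function(p) {
      survivor_protocol(pools[[p]], sampler, n_cycles,
                        community_id = p, ...)
    })
    counts[, j] <- vapply(reports[[j]], `[[`, 0L, "n_survivors")
  }
  summary <- data.frame(
    sigma_rs = sigma_grid,
    violation_fraction = colMeans(counts > N),
    mean_survivors = colMeans(counts),
    sem_survivors = apply(counts, 2, sd) / sqrt(nrow(counts)))
  structure(list(summary = summary, counts = counts, reports = reports,
                 n_resources = N),
            class = "ce_sweep")
}

#' @export
print.ce_sweep <- function(x, ...) {
  cat("Competitive-exclusion sweep:", nrow(x$counts), "communities,",
      ncol(x$counts), "fluctuation magnitudes\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Diversity versus number of resources
#'
#' Simulates replicate random pools (rate-ordered preferences, L2
#' constraint) for each resource count under a uniform-random resource
#' supply and records the number of survivors per community.
#'
#' @param n_resources_list resource counts (e.g. `2:7`).
#' @param n_pools replicate pools per resource count.
#' @param n_species pool size; default follows [pool_size()].
#' @param n_cycles cycles per repetition.
#' @param pool_base,pool_cap base size (at three resources) and cap
#'   passed to [pool_size()] when `n_species` is NULL.  Scaled-down
#'   batches should reduce `pool_base` (keeping the species density
#'   constant across resource counts, as the sizing rule intends)
#'   rather than rely on the cap, which truncates only the
#'   high-resource pools and distorts the shape of the diversity
#'   curve.
#' @param ... further arguments to [survivor_protocol()].
#' @return data.frame with columns `n_resources`, `pool`,
#'   `n_survivors`.
#' @export
diversity_scaling <- function(n_resources_list, n_pools = 25,
                              n_species = NULL, n_cycles = 10000,
                              pool_base = 500, pool_cap = 5000, ...) {
  out <- list()
  for (N in n_resources_list) {
    S <- if (is.null(n_species))
      suppressWarnings(pool_size(N, base_size = pool_base,
                                 max_size = pool_cap)) else n_species
    for (p in seq_len(n_pools)) {
      pool <- sample_pool(N, S, preference_mode = "rate-ordered")
      rep <- survivor_protocol(pool, function(n) sample_uniform_simplex(N, n),
                               n_cycles, community_id = sprintf("N%d_p%d", N, p),
                               ...)
      out[[length(out) + 1]] <- data.frame(n_resources = N, pool = p,
                                           n_survivors = rep$n_survivors)
    }
  }
  do.call(rbind, out)
}

# two-parameter least-squares fit of y ~ f(x; b1, b2) with analytic
# jacobian; family is "monomial" (b1 * x^b2) or "exponential"
# (b1 * exp(b2 * x)).  Started from the log-scale linear fit, refined by
# quasi-Newton on the sum of squared residuals.
fit_two_param <- function(x, y, family) {
  f <- switch(family,
              monomial = function(b) b[1] * x^b[2],
              exponential = function(b) b[1] * exp(b[2] * x))
  jac <- switch(family,
                monomial = function(b) cbind(x^b[2],
                                             b[1] * x^b[2] * log(x)),
                exponential = function(b) cbind(exp(b[2] * x),
                                                b[1] * x * exp(b[2] * x)))
  lx <- if (family == "monomial") log(x) else x
  start_lm <- lm(log(y) ~ lx)
  b0 <- c(exp(coef(start_lm)[1]), coef(start_lm)[2])
  sse <- function(b) sum((y - f(b))^2)
  grad <- function(b) -2 * colSums((y - f(b)) * jac(b))
  opt <- optim(b0, sse, gr = grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  b <- opt$par
  res <- y - f(b)
  n <- length(y)
  s2 <- sum(res^2) / max(n - 2, 1)
  J <- jac(b)
  cov <- tryCatch(s2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, 2, 2))
  list(coefficients = setNames(as.numeric(b), c("b1", "b2")),
       se = sqrt(pmax(diag(cov), 0)),
       residuals = res, fitted = f(b), sse = sum(res^2))
}

#' Fit diversity-scaling laws
#'
#' Fits two-parameter linear (`b1 + b2*N`), monomial (`b1 * N^b2`) and
#' exponential (`b1 * exp(b2*N)`) models of the number of survivors
#' versus the number of resources by least squares on the original
#' scale, reporting coefficients with standard errors, R-squared, and
#' root-mean-square error per family, plus pairwise variance-ratio
#' F-tests on the residuals (equal parameter counts; a conventional
#' comparison for these non-nested families, not a recommended
#' statistic).
#'
#' @param data data.frame with columns `n_resources` and `n_survivors`
#'   (as from [diversity_scaling()]), or a numeric vector of resource
#'   counts.
#' @param n_survivors survivor counts when `data` is a vector.
#' @return An object of class `"diversity_fit"`: list of per-family
#'   fits (`coefficients`, `se`, `r_squared`, `rms_error`), `f_tests`
#'   (pairwise p-value matrix), and `best` (family with highest
#'   R-squared, equivalently lowest RMS error).
#' @examples
#' x <- rep(2:7, each = 3)
#' fit <- fit_diversity_law(data.frame(n_resources = x,
#'                                     n_survivors = 0.44 * x^2.14))
#' coef(fit)  # recovers (0.44, 2.14)
#' @export
fit_diversity_law <- function(data, n_survivors = NULL) {
  if (is.data.frame(data)) {
    x <- data$n_resources; y <- data$n_survivors
  } else {
    x <- as.numeric(data); y <- as.numeric(n_survivors)
  }
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct resource counts")
  n <- length(y)
  sst <- sum((y - mean(y))^2)

  lin <- lm(y ~ x)
  fits <- list(
    linear = list(coefficients = setNames(as.numeric(coef(lin)),
                                          c("b1", "b2")),
                  se = as.numeric(summary(lin)$coefficients[, 2]),
                  residuals = as.numeric(lin$residuals),
                  fitted = as.numeric(lin$fitted.values),
                  sse = sum(lin$residuals^2)),
    monomial = fit_two_param(x, y, "monomial"),
    exponential = fit_two_param(x, y, "exponential"))
  for (fam in names(fits)) {
    fits[[fam]]$r_squared <- 1 - fits[[fam]]$sse / sst
    fits[[fam]]$rms_error <- sqrt(fits[[fam]]$sse / n)
  }
  fams <- names(fits)
  pmat <- matrix(NA_real_, 3, 3, dimnames = list(fams, fams))
  df <- n - 2
  for (a in fams) for (b in fams) if (a != b) {
    f <- fits[[a]]$sse / fits[[b]]$sse
    pmat[a, b] <- pf(max(f, 1 / f), df, df, lower.tail = FALSE)
  }
  best <- fams[which.max(vapply(fits, `[[`, 0, "r_squared"))]
  structure(list(fits = fits, f_tests = pmat, best = best,
                 data = data.frame(n_resources = x, n_survivors = y)),
            class = "diversity_fit")
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Diversity scaling fits (n =", nrow(x$data), "):\n")
  for (fam in names(x$fits)) {
    f <- x$fits[[fam]]
    cat(sprintf("  %-12s b1 = %8.3g +/- %.2g  b2 = %8.3g +/- %.2g  R2 = %.3f  RMS = %.3g\n",
                fam, f$coefficients[1], f$se[1],
                f$coefficients[2], f$se[2], f$r_squared, f$rms_error))
  }
  cat("  best family:", x$best, "\n")
  invisible(x)
}

#' @export
coef.diversity_fit <- function(object, family = object$best, ...) {
  object$fits[[family]]$coefficients
}

#' @export
predict.diversity_fit <- function(object, n_resources,
                                  family = object$best, ...) {
  b <- object$fits[[family]]$coefficients
  switch(family,
         linear = b[1] + b[2] * n_resources,
         monomial = b[1] * n_resources^b[2],
         exponential = b[1] * exp(b[2] * n_resources),
         stop("unknown family"))
}

#' Community assembly under seasonal supply oscillations
#'
#' Runs the survivor protocol with a deterministic periodic supply (see
#' [seasonal_supply()]).  Because the schedule is deterministic the
#' repetitions are redundant, so a single primary and a single
#' head-start run are used by default.
#'
#' @param period seasonal period (3, 6 or 12 are canonical).
#' @param pools list of `species_pool` objects on three resources.
#' @param n_cycles cycles per run.
#' @param ... further arguments to [survivor_protocol()].
#' @return list with `n_survivors` (per pool), `mean_survivors`, and
#'   `reports`.
#' @export
seasonal_assembly <- function(period, pools, n_cycles = 10000, ...) {
  sched <- seasonal_supply(period, seq_len(n_cycles))
  reports <- lapply(seq_along(pools), function(p) {
    survivor_protocol(pools[[p]], sched, n_cycles,
                      n_primary = 1, n_headstart = 1, min_survivals = 1,
                      community_id = p, ...)
  })
  ns <- vapply(reports, `[[`, 0L, "n_survivors")
  list(period = period, n_survivors = ns, mean_survivors = mean(ns),
       reports = reports)
}

#' Classify long-run dynamics of a trajectory
#'
#' Inspects end-of-cycle population fractions over the final `window`
#' cycles (which must have been recorded contiguously): a run is a
#' `fixed_point` when no species' fraction changes by more than
#' `fp_tol` across the window; otherwise it is `periodic(L)` when the
#' pooled fraction series has autocorrelation above `ac_threshold` at
#' some integer lag `L` (the smallest such lag is reported); otherwise
#' it is `aperiodic` (a candidate for chaos, not a claim of it).
#'
#' @param sim a `diauxie_sim` recorded with `record = "all"` (or at
#'   least the final window contiguously).
#' @param window number of final cycles to inspect (default 2000,
#'   capped at what was recorded).
#' @param fp_tol fixed-point tolerance on fractions.
#' @param ac_threshold autocorrelation threshold for periodicity.
#' @return list with `type` (`"fixed_point"`, `"periodic"`,
#'   `"aperiodic"`), `period` (NA unless periodic), and `statistic`.
#' @export
classify_dynamics <- function(sim, window = 2000, fp_tol = 1e-10,
                              ac_threshold = 0.99) {
  rc <- sim$recorded_cycles
  window <- min(window, length(rc))
  idx <- seq(length(rc) - window + 1, length(rc))
  if (any(diff(rc[idx]) != 1))
    stop("final window must be contiguously recorded (record = \"all\")")
  X <- sim$fractions[idx, sim$survivors, drop = FALSE]
  if (max(apply(X, 2, function(col) diff(range(col)))) < fp_tol)
    return(list(type = "fixed_point", period = NA_integer_,
                statistic = max(apply(X, 2, function(c) diff(range(c))))))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  W <- nrow(Xc)
  for (L in seq_len(floor(W / 2))) {
    a <- as.numeric(Xc[seq_len(W - L), , drop = FALSE])
    b <- as.numeric(Xc[seq(L + 1, W), , drop = FALSE])
    r <- suppressWarnings(cor(a, b))
    if (is.finite(r) && r > ac_threshold)
      return(list(type = "periodic", period = L, statistic = r))
  }
  list(type = "aperiodic", period = NA_integer_, statistic = NA_real_)
}
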