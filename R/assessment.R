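## Site x realization sweeps: run the foraging + exposure chain for many
## hive sites and treatment realizations, aggregate dilution-factor
## distributions into percentiles, and compare scenarios on an area base.

#' Derive a reproducible child seed from a master seed
#'
#' Stable integer hashing (multiply-add chain modulo a Mersenne-adjacent
#' prime) so that per-(site, realization, grid-point) random draws are
#' independent of loop order but fully determined by the master seed.
#'
#' @param master Master seed (integer).
#' @param ... Further integer indices to mix in.
#' @return A positive integer seed `< 2^31`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629
  x <- as.numeric(master) %% m
  for (k in c(...)) {
    x <- (x * 48271 + (as.numeric(k) %% m) * 16807 + 1013904223) %% m
  }
  as.integer(x) + 1L
}

#' Empirical percentiles of a dilution distribution
#'
#' Quantiles with linear interpolation (`type = 7`) of the pooled per-site
#' values, `NA`s (no-exposure days) removed.
#'
#' @param x Numeric vector of dilution factors.
#' @param probs Probabilities; default the 10-, 50- and 90-percentiles.
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return Named numeric vector.
#' @export
dilution_percentiles <- function(x, probs = c(0.1, 0.5, 0.9), type = 7) {
  quantile(x, probs = probs, type = type, na.rm = TRUE, names = TRUE)
}

#' Run one hive site against one scenario realization
#'
#' Computes per-patch distances for the site (flooring at half a grid
#' cell), forces the site's adjacent target field to be treated at the
#' reference concentration, discards patches beyond `D_max`, runs the
#' configured foraging model and derives the dilution factor.
#'
#' @param site One row of [enumerate_hive_sites()].
#' @param real A realization from one of the `scenario_*()` generators.
#' @param bee [bee_parameters()].
#' @param cfg [sim_config()].
#' @param ecfg [exposure_config()].
#' @param dist_cache Optional environment caching site-to-patch distances
#'   across realizations (keyed by site and patch id).
#' @return List with `site_id`, `phi` (`NA` marks a no-exposure day),
#'   `sugar` (mg), `n_exploited` (distinct patches with positive delivery),
#'   `n_exploited90` (patches covering 90% of the sugar) and `day` (the
#'   full `foraging_day`, only when `keep_day = TRUE`).
#' @param keep_day Keep the full simulation result (default `FALSE`).
#' @export
run_site <- function(site, real, bee, cfg = sim_config(),
                     ecfg = exposure_config(), dist_cache = NULL,
                     keep_day = FALSE) {
  pt <- real$patches
  if (!is.null(dist_cache)) {
    key <- as.character(site$site_id)
    known <- dist_cache[[key]]
    need <- if (is.null(known)) pt$id else setdiff(pt$id, names(known))
    if (length(need)) {
      idx <- match(need, pt$id)
      d_new <- site_distances(site, pt[idx, , drop = FALSE], real$resolution)
      names(d_new) <- need
      known <- c(known, d_new)
      dist_cache[[key]] <- known
    }
    D <- unname(known[pt$id])
  } else {
    D <- site_distances(site, pt, real$resolution)
  }
  pt$D <- D
  pt <- pt[pt$D <= bee$D_max, , drop = FALSE]
  adj <- pt$id == site$adj_patch
  pt$treated[adj] <- TRUE
  pt$C <- ifelse(pt$treated, ecfg$C_P, pt$C)
  pt$F <- pt$F0
  day <- simulate_day(pt, bee, cfg)
  phi <- dilution_factor(day, ecfg)
  out <- list(site_id = site$site_id, phi = phi, sugar = sugar_influx(day),
              n_exploited = length(day$exploited),
              n_exploited90 = patches_for_sugar_fraction(day, 0.9))
  if (keep_day) out$day <- day
  out
}

.scenario_fn <- function(scenario) {
  switch(scenario,
    alternative_fields = function(ls, p, variant, seed)
      scenario_alternative_fields(ls, p, sugar_mult = variant, seed = seed),
    flower_strips = function(ls, p, variant, seed)
      scenario_flower_strips(ls, p, w = variant, seed = seed),
    off_field = function(ls, p, variant, seed)
      scenario_off_field(ls, p, quality_mult = variant, seed = seed),
    stop("unknown scenario: ", scenario))
}

## area (ha) of the untreated resource patches a realization adds
.managed_area_ha <- function(real) {
  add <- real$patches$category %in% c("flower-strip", "off-field", "alternative-field")
  sum(real$patches$A[add]) / 1e4
}

#' Sweep a mitigation scenario over hive sites and realizations
#'
#' For every grid point (`p`, variant) the scenario is realized
#' `realizations` times with paired seeds (the same realization index uses
#' the same seed at every `p`, so treatment draws are coupled across the
#' grid and Monte-Carlo noise cancels in comparisons). Each realization is
#' run for every sampled hive site; per-site mean dilution factors over
#' realizations are summarised by percentiles.
#'
#' @param ls A [landscape()].
#' @param scenario `"alternative_fields"`, `"flower_strips"` or
#'   `"off_field"`.
#' @param p_grid Probabilities to sweep (default 0 to 1 by 0.1).
#' @param variants Scenario variant values: sugar multiplier, strip width
#'   or quality multiplier. Default 1.
#' @param bee,cfg,ecfg Model configuration.
#' @param realizations Random realizations per grid point (default 100).
#' @param sample_fraction Fraction of candidate hive sites used
#'   (default 0.1); the identical seeded site subset is used for every
#'   scenario at the same `master_seed`.
#' @param master_seed Master seed; all site sampling and treatment draws
#'   derive from it via [derive_seed()].
#' @param sites Optional pre-enumerated site table (overrides
#'   `sample_fraction`).
#' @return Object of class `assessment`: list with `summary` (one row per
#'   grid point: percentiles of per-site mean phi, fractions of sites with
#'   no exposure / no dilution, mean managed area in ha, mean exploited
#'   patch counts), `site_means` (per site x grid point), `scenario`,
#'   `model`, `sites`.
#' @export
run_assessment <- function(ls, scenario, p_grid = seq(0, 1, by = 0.1),
                           variants = 1, bee = bee_parameters(),
                           cfg = sim_config(), ecfg = exposure_config(),
                           realizations = 100, sample_fraction = 0.1,
                           master_seed = 1L, sites = NULL) {
  fn <- .scenario_fn(scenario)
  if (is.null(sites))
    sites <- enumerate_hive_sites(ls, sample_fraction,
                                  seed = derive_seed(master_seed, 0L))
  if (!nrow(sites)) stop("no hive sites to assess")
  summ <- list()
  site_rows <- list()
  for (vi in seq_along(variants)) {
    v <- variants[vi]
    dist_cache <- new.env(parent = emptyenv())
    for (pi in seq_along(p_grid)) {
      p <- p_grid[pi]
      phi <- matrix(NA_real_, nrow(sites), realizations)
      nexp <- nexp90 <- matrix(NA_real_, nrow(sites), realizations)
      area <- numeric(realizations)
      for (k in seq_len(realizations)) {
        real <- fn(ls, p, v, derive_seed(master_seed, vi, k))
        area[k] <- .managed_area_ha(real)
        for (si in seq_len(nrow(sites))) {
          r <- run_site(sites[si, ], real, bee, cfg, ecfg, dist_cache)
          phi[si, k] <- r$phi
          nexp[si, k] <- r$n_exploited
          nexp90[si, k] <- r$n_exploited90
        }
      }
      site_mean <- rowMeans(phi, na.rm = TRUE)
      site_mean[is.nan(site_mean)] <- NA_real_
      pc <- dilution_percentiles(site_mean)
      summ[[length(summ) + 1L]] <- data.frame(
        scenario = scenario, variant = v, p = p, n_sites = nrow(sites),
        realizations = realizations,
        phi_mean = mean(site_mean, na.rm = TRUE),
        p10 = pc[[1]], p50 = pc[[2]], p90 = pc[[3]],
        frac_no_exposure = mean(site_mean == 0, na.rm = TRUE),
        frac_no_dilution = mean(abs(site_mean - 1) < 1e-12, na.rm = TRUE),
        frac_undefined = mean(is.na(site_mean)),
        managed_area_ha = mean(area),
        mean_exploited = mean(nexp, na.rm = TRUE),
        mean_exploited90 = mean(nexp90, na.rm = TRUE))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        scenario = scenario, variant = v, p = p, site_id = sites$site_id,
        phi = site_mean, stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, summ),
                 site_means = do.call(rbind, site_rows),
                 scenario = scenario, model = cfg$model, sites = sites,
                 master_seed = master_seed),
            class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat(sprintf("Assessment '%s' (%s model), %d sites x %d realizations\n",
              x$scenario, toupper(x$model), nrow(x$sites),
              x$summary$realizations[1]))
  print(x$summary[c("variant", "p", "p10", "p50", "p90", "managed_area_ha")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Dilution gained per unit of managed area across scenarios
#'
#' Joins the summaries of a flower-strip assessment and an off-field
#' assessment on the same landscape into a dilution-versus-managed-area
#' table, and estimates how much more off-field area than strip area is
#' needed to reach the same 90-percentile dilution (ratio > 1 means strips
#' are more area-efficient).
#'
#' @param strips,off `assessment` objects (or their `summary` data.frames)
#'   for the two scenarios.
#' @param percentile Summary column to match on, default `"p90"`.
#' @return List with `table` (scenario, managed_area_ha, percentile
#'   columns), `ratio` (off-field / strip area at matched dilution; `NA`
#'   with `bounded = TRUE` when the achieved dilution ranges do not
#'   overlap, in which case `ratio_lower_bound` is reported).
#' @export
area_efficiency <- function(strips, off, percentile = "p90") {
  gs <- if (inherits(strips, "assessment")) strips$summary else strips
  go <- if (inherits(off, "assessment")) off$summary else off
  tab <- rbind(
    data.frame(scenario = "flower_strips", managed_area_ha = gs$managed_area_ha,
               phi = gs[[percentile]]),
    data.frame(scenario = "off_field", managed_area_ha = go$managed_area_ha,
               phi = go[[percentile]]))
  ## area needed to push p90 phi down to a target level, by interpolation
  ## along each scenario's (area, phi) curve
  area_at <- function(d, target) {
    d <- d[is.finite(d$phi), ]
    d <- d[order(d$phi), ]
    if (nrow(d) < 2 || target > max(d$phi) || target < min(d$phi)) return(NA_real_)
    stats::approx(d$phi, d$managed_area_ha, xout = target, ties = mean)$y
  }
  ds <- tab[tab$scenario == "flower_strips", ]
  do <- tab[tab$scenario == "off_field", ]
  lo <- max(min(ds$phi, na.rm = TRUE), min(do$phi, na.rm = TRUE))
  hi <- min(max(ds$phi[ds$managed_area_ha > 0], na.rm = TRUE),
            max(do$phi[do$managed_area_ha > 0], na.rm = TRUE))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    ## ranges do not overlap: off-field never reaches the strips' dilution,
    ## so the ratio is bounded below by max area ratio tried
    return(list(table = tab, ratio = NA_real_, bounded = TRUE,
                ratio_lower_bound = max(do$managed_area_ha) /
                  max(ds$managed_area_ha[ds$phi > 0], na.rm = TRUE)))
  }
  targets <- seq(lo, hi, length.out = 5)[2:4]
  ratios <- vapply(targets, function(tg) {
    as_ <- area_at(ds, tg); ao <- area_at(do, tg)
    if (is.na(as_) || is.na(ao) || as_ <= 0) NA_real_ else ao / as_
  }, numeric(1))
  list(table = tab, ratio = mean(ratios, na.rm = TRUE), bounded = FALSE,
       targets = targets, ratios = ratios)
}
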