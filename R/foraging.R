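## Single-day foraging simulators on a table of resource patches.
## Patches are rows of an ordinary data.frame carrying the resolved resource
## coefficients, so every energetics kernel applies column-wise.

#' Construct a resource patch
#'
#' One homogeneous patch of a single resource, as a one-row data.frame.
#' Rows from several calls can be `rbind`-ed into a patch table for
#' [simulate_day()].
#'
#' @param id Stable patch identifier (character).
#' @param rt [resource_type()] of the patch.
#' @param A Patch area, m^2 (`> 0`).
#' @param D Distance from the focal hive, m.
#' @param C Chemical concentration in the patch's nectar, ug mg^-1.
#' @param treated Treatment flag (`delta` in the exposure sums).
#' @param category One of `"target-field"`, `"alternative-field"`,
#'   `"flower-strip"`, `"off-field"`.
#' @param F Current open-flower density; defaults to the undepleted `rt$F0`.
#' @param sigma Per-scout encounter probability for detection (default 1).
#' @return A one-row `data.frame` with the resolved resource coefficients.
#' @examples
#' p <- patch("osr1", resource_preset("osr"), A = 4e4, D = 500, treated = TRUE, C = 1)
#' @export
patch <- function(id, rt, A, D, C = 0, treated = FALSE,
                  category = "target-field", F = rt$F0, sigma = 1) {
  stopifnot(inherits(rt, "resource_type"))
  if (A <= 0) stop("patch area A must be > 0")
  if (C < 0) stop("contamination C must be >= 0")
  if (F < 0 || F > rt$F0) stop("F must lie in [0, F0]")
  out <- data.frame(id = as.character(id), category = category,
                    resource = rt$name, A = A, D = D, F = F, F0 = rt$F0,
                    g = rt$g, a = rt$a, h = rt$h, e_R = rt$e_R,
                    sugar_share = rt$sugar_share, r = rt$r,
                    C = C, treated = treated, sigma = sigma,
                    stringsAsFactors = FALSE)
  out$anthesis <- list(rt$anthesis)
  out
}

#' Simulation configuration
#'
#' @param model `"so"` (single optimal patch per hour) or `"rl"`
#'   (recruitment-limited multi-patch exploitation).
#' @param Z Background density of competing nectar foragers, m^-2
#'   (same functional response as honeybees). Default 0.
#' @param perfect_knowledge If `TRUE` (default) every patch is known
#'   (`P = 1`); otherwise detection is drawn once per day from
#'   [detection_probability()] using each patch's `sigma`.
#' @param seed Optional integer seed for the day's stochastic elements
#'   (detection draws, and RL transitions when `stochastic = TRUE`).
#' @param kappa_a RL abandonment rate constant. Default 0.3.
#' @param rho RL fraction of the unemployed pool recruited per hour.
#'   Default 0.3.
#' @param epsilon RL floor dance weight letting unoccupied feasible patches
#'   enter the recruitment lottery. Default 0.01.
#' @param stochastic If `TRUE`, RL abandonment/recruitment use binomial and
#'   multinomial draws of whole foragers; default `FALSE` uses deterministic
#'   expected-value (fractional) updates.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = c("so", "rl"), Z = 0, perfect_knowledge = TRUE,
                       seed = NULL, kappa_a = 0.3, rho = 0.3, epsilon = 0.01,
                       stochastic = FALSE) {
  model <- match.arg(model)
  if (Z < 0) stop("competitor density Z must be >= 0")
  if (kappa_a < 0 || rho < 0 || rho > 1 || epsilon < 0)
    stop("invalid recruitment parameters")
  structure(list(model = model, Z = Z,
                 perfect_knowledge = isTRUE(perfect_knowledge), seed = seed,
                 kappa_a = kappa_a, rho = rho, epsilon = epsilon,
                 stochastic = isTRUE(stochastic)),
            class = "sim_config")
}

#' Trips per forager per hour
#'
#' `b = dt / (t_trip + t_UD)`, kept continuous: trips are a rate, not an
#' integer count.
#'
#' @inheritParams trip_duration
#' @return Trips per forager per time step.
#' @export
trips_per_hour <- function(D, F, rt, bee) {
  bee$dt / (trip_duration(D, F, rt, bee) + bee$t_UD)
}

#' Nectar and sugar delivered to the hive in one hour
#'
#' With `n` foragers on the patch, `n (gamma - E_c/e_R) b` mg of nectar and
#' `n (gamma e_R - E_c)/e_sugar b` mg of sugar arrive, after the return
#' flight consumed part of the load. Infeasible patches deliver zero.
#'
#' @param n Foragers allocated to the patch.
#' @inheritParams trip_duration
#' @return List with `nectar` (mg), `sugar` (mg) and `b` (trips per forager).
#' @export
hourly_delivery <- function(n, D, F, rt, bee) {
  feas <- patch_feasible(D, F, rt, bee)
  b <- ifelse(feas, trips_per_hour(D, F, rt, bee), 0)
  rc <- return_consumption(D, rt, bee)
  nectar <- ifelse(feas, n * rc$arriving * b, 0)
  sugar <- ifelse(feas, n * (bee$gamma * rt$e_R - rc$energy) / bee$e_sugar * b, 0)
  list(nectar = nectar, sugar = sugar, b = b)
}

#' Hourly open-flower density update
#'
#' `F' = F - n gamma b / (g A) - f(F) Z + r (F0 - F)`, clamped to
#' `[0, F0]`: depletion by the colony (a full load visits exactly
#' `gamma/g` flowers), depletion by competitors at density `Z`, and renewal
#' of a fraction `r` of spent flowers.
#'
#' @param p Patch table (rows with columns `F`, `F0`, `g`, `a`, `h`, `A`, `r`).
#' @param n Foragers per patch (vector).
#' @param b Trips per forager per patch (vector).
#' @param bee [bee_parameters()].
#' @param Z Competitor density, m^-2.
#' @param open Logical vector: anthesis open this hour (competitors only
#'   deplete open flowers). Default all open.
#' @return New flower-density vector.
#' @export
update_flower_density <- function(p, n, b, bee, Z = 0, open = TRUE) {
  f <- visit_rate(p$F, p)
  Fnew <- p$F - n * bee$gamma * b / (p$g * p$A) -
    ifelse(open, f * Z, 0) + p$r * (p$F0 - p$F)
  pmin(pmax(Fnew, 0), p$F0)
}

## anthesis open at hour h? (list-column of hour vectors; NULL = all day)
.anthesis_open <- function(p, hour) {
  if (is.null(p$anthesis)) return(rep(TRUE, nrow(p)))
  vapply(p$anthesis, function(a) is.null(a) || (hour %in% a), logical(1))
}

#' Which patches can be foraged this hour?
#'
#' A patch qualifies when its flowers are open this hour, it lies within
#' `D_max`, it was detected, flowers remain (`F > 0`) and the trip energy
#' balance is positive.
#'
#' @param p Patch table.
#' @param hour Hour of the day (1-based).
#' @param bee [bee_parameters()].
#' @param detected Logical vector of per-day detection outcomes (default all).
#' @return Logical vector over patches.
#' @export
feasible_patches <- function(p, hour, bee, detected = TRUE) {
  .anthesis_open(p, hour) & detected & patch_feasible(p$D, p$F, p, bee)
}

## SO choice: maximum NEE, ties broken by smaller D then smaller id
.so_select <- function(neev, p, feas) {
  idx <- which(feas)
  if (length(idx) == 0L) return(NA_integer_)
  idx[order(-neev[idx], p$D[idx], p$id[idx])[1L]]
}

#' Simulate one foraging day
#'
#' Runs the hourly loop for one hive over a patch table. Each hour the
#' feasible set and per-patch NEE are computed at the current flower
#' densities; foragers are allocated (all to the NEE-argmax patch in the SO
#' model, via abandonment/recruitment dynamics in the RL model); deliveries
#' are recorded and flower densities are updated synchronously.
#'
#' In the RL model every employed forager abandons patch `i` with
#' probability `kappa_a (1 - NEE_i / NEE*)` (probability 1 when the patch
#' has become infeasible), where `NEE*` is the hour's maximum; a fraction
#' `rho` of the unemployed pool is then recruited across feasible patches
#' in proportion to dance strength `n_i * NEE_i`, with a floor weight
#' `epsilon * NEE_i` for unoccupied patches. Foragers are conserved every
#' hour. By default the transitions are deterministic expected-value
#' updates; see [sim_config()].
#'
#' @param patches Patch table: rows created by [patch()] (or a compatible
#'   data.frame), with distances `D` already set for the focal hive.
#' @param bee [bee_parameters()].
#' @param cfg [sim_config()].
#' @return An object of class `foraging_day`: list with `hourly` (one row
#'   per hour x exploited patch: `hour, id, n, b, D, F, e_R, C, treated,
#'   E_c, nectar, sugar`), `patch_totals` (per-patch daily nectar/sugar),
#'   `exploited` (ids with positive delivery), `rl_trace` (per-hour
#'   employed/unemployed totals, RL model only), `bee`, `cfg`.
#' @examples
#' p <- patch("f1", resource_preset("osr"), A = 5e4, D = 200, treated = TRUE, C = 1)
#' day <- simulate_day(p, bee_parameters(), sim_config("so"))
#' sum(day$hourly$sugar)  # mg sugar brought home
#' @export
simulate_day <- function(patches, bee, cfg = sim_config()) {
  p <- patches
  np <- nrow(p)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  detected <- rep(TRUE, np)
  if (np > 0L && !cfg$perfect_knowledge) {
    sig <- if ("sigma" %in% names(p)) p$sigma else rep(1, np)
    detected <- runif(np) < detection_probability(sig, bee$s_scouts)
  }
  employed <- rep(0, np)
  unemployed <- bee$n_foragers
  rows <- vector("list", bee$day_hours)
  trace <- if (cfg$model == "rl")
    data.frame(hour = seq_len(bee$day_hours), employed = NA_real_,
               unemployed = NA_real_) else NULL

  for (hr in seq_len(bee$day_hours)) {
    if (np == 0L) break
    feas <- feasible_patches(p, hr, bee, detected)
    neev <- rep(-Inf, np)
    neev[feas] <- nee(p$D[feas], p$F[feas], p[feas, , drop = FALSE], bee)

    if (cfg$model == "so") {
      n_i <- rep(0, np)
      sel <- .so_select(neev, p, feas)
      if (!is.na(sel)) n_i[sel] <- bee$n_foragers
    } else {
      ## abandonment
      nee_star <- if (any(feas)) max(neev[feas]) else NA_real_
      p_ab <- rep(1, np)
      if (any(feas))
        p_ab[feas] <- pmin(pmax(cfg$kappa_a * (1 - neev[feas] / nee_star), 0), 1)
      leaving <- if (cfg$stochastic)
        rbinom(np, round(employed), p_ab) else employed * p_ab
      employed <- employed - leaving
      unemployed <- unemployed + sum(leaving)
      ## recruitment among feasible patches
      w <- rep(0, np)
      w[feas] <- pmax(ifelse(employed[feas] > 0, employed[feas], cfg$epsilon), 0) *
        pmax(neev[feas], 0)
      if (sum(w) > 0) {
        recruits <- cfg$rho * unemployed
        if (cfg$stochastic) {
          recruits <- rbinom(1L, round(unemployed), cfg$rho)
          alloc <- as.numeric(stats::rmultinom(1L, recruits, w))
        } else {
          alloc <- recruits * w / sum(w)
        }
        employed <- employed + alloc
        unemployed <- unemployed - sum(alloc)
      }
      n_i <- employed
      trace$employed[hr] <- sum(employed)
      trace$unemployed[hr] <- unemployed
    }

    del <- hourly_delivery(n_i, p$D, p$F, p, bee)
    act <- which(n_i > 0 & del$b > 0)
    if (length(act)) {
      E_c <- bee$e_L * p$D[act] / bee$v
      rows[[hr]] <- data.frame(hour = hr, id = p$id[act], n = n_i[act],
                               b = del$b[act], D = p$D[act], F = p$F[act],
                               e_R = p$e_R[act], C = p$C[act],
                               treated = p$treated[act], E_c = E_c,
                               nectar = del$nectar[act],
                               sugar = del$sugar[act],
                               stringsAsFactors = FALSE)
    }
    open <- .anthesis_open(p, hr)
    p$F <- update_flower_density(p, n_i, del$b, bee, cfg$Z, open)
    ## foragers sitting on patches that just emptied abandon next hour
    ## through the p_ab = 1 branch of the feasibility gate
  }

  hourly <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hourly))
    hourly <- data.frame(hour = integer(), id = character(), n = numeric(),
                         b = numeric(), D = numeric(), F = numeric(),
                         e_R = numeric(), C = numeric(), treated = logical(),
                         E_c = numeric(), nectar = numeric(), sugar = numeric(),
                         stringsAsFactors = FALSE)
  totals <- if (nrow(hourly)) {
    agg <- aggregate(hourly[c("nectar", "sugar")], by = list(id = hourly$id), sum)
    agg[order(-agg$sugar), ]
  } else data.frame(id = character(), nectar = numeric(), sugar = numeric())
  structure(list(hourly = hourly, patch_totals = totals,
                 exploited = totals$id[totals$sugar > 0],
                 final_F = p$F, rl_trace = trace, bee = bee, cfg = cfg),
            class = "foraging_day")
}

#' @export
print.foraging_day <- function(x, ...) {
  cat(sprintf("Foraging day (%s model): %d exploited patches, %.0f mg sugar delivered\n",
              toupper(x$cfg$model), length(x$exploited), sum(x$hourly$sugar)))
  invisible(x)
}

#' Patches accounting for a fraction of the day's sugar
#'
#' Smallest number of patches whose summed sugar deliveries reach at least
#' a fraction `q` of the day's total — the standard way to count exploited
#' patches under the RL model, where arbitrarily small allocations occur.
#'
#' @param day A `foraging_day` result.
#' @param q Fraction in (0, 1].
#' @return Integer count; 0 when no sugar was delivered.
#' @export
patches_for_sugar_fraction <- function(day, q = 0.9) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  s <- sort(day$patch_totals$sugar, decreasing = TRUE)
  tot <- sum(s)
  if (tot <= 0) return(0L)
  ## tolerance guards ties at exact fractions against roundoff
  which(cumsum(s) >= q * tot - 1e-9 * tot)[1L]
}
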