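## Per-trip foraging energetics: closed forms for visitation, trip time,
## energy expenditure/intake, net energetic efficiency (NEE) and the derived
## threshold-distance rules. All rates are per second; the simulation layer
## converts to hours. Functions are vectorized over F, D and the resource
## coefficient vectors so the same kernels serve single resource types and
## whole patch tables (data.frames with columns g, a, h, e_R).

#' Flower visitation rate (type-II functional response)
#'
#' Number of nectar-providing flowers visited per second at open-flower
#' density `F`: `a F / (1 + a h F)`, saturating at `1/h`.
#'
#' @param F Open-flower density, m^-2 (vectorized, `>= 0`).
#' @param rt A [resource_type()] (or any list/data.frame with fields
#'   `g`, `a`, `h`, `e_R`).
#' @return Flowers visited per second.
#' @examples
#' visit_rate(264, resource_preset("osr"))  # ~0.15 /s
#' @export
visit_rate <- function(F, rt) {
  if (any(F < 0)) stop("flower density F must be >= 0")
  rt$a * F / (1 + rt$a * rt$h * F)
}

#' Time to collect a full nectar load
#'
#' `gamma / (f g)` seconds, with `f` the visitation rate at density `F`.
#' Infinite (infeasible patch) when `F = 0`.
#'
#' @inheritParams visit_rate
#' @param bee [bee_parameters()].
#' @return Seconds.
#' @export
load_time <- function(F, rt, bee) {
  f <- visit_rate(F, rt)
  ifelse(f > 0, bee$gamma / (f * rt$g), Inf)
}

#' Duration of one foraging trip
#'
#' Travel out and back plus loading time: `2 D / v + gamma/(f g)`.
#'
#' @param D Hive-to-patch distance, m (vectorized, `>= 0`).
#' @inheritParams load_time
#' @return Seconds.
#' @export
trip_duration <- function(D, F, rt, bee) {
  if (any(D < 0)) stop("distance D must be >= 0")
  2 * D / bee$v + load_time(F, rt, bee)
}

#' Energy spent searching within the patch
#'
#' `gamma e_F / (g a F)` joules per trip. Handling time cancels out of the
#' expenditure (sitting on flowers is taken as energetically free), so the
#' result is independent of `h`.
#'
#' @inheritParams load_time
#' @return Joules.
#' @export
field_energy <- function(F, rt, bee) {
  ifelse(F > 0, bee$gamma * bee$e_F / (rt$g * rt$a * F), Inf)
}

#' Energy spent travelling between hive and patch
#'
#' `2 (D/v) e_F` joules for the round trip; with the default mean flight
#' cost this equals `(D/v)(e_U + e_L)`.
#'
#' @inheritParams trip_duration
#' @return Joules.
#' @export
travel_energy <- function(D, bee) {
  if (any(D < 0)) stop("distance D must be >= 0")
  2 * (D / bee$v) * bee$e_F
}

#' Total energy expenditure of one trip
#'
#' @inheritParams trip_duration
#' @return Joules: [field_energy()] + [travel_energy()].
#' @export
total_energy <- function(D, F, rt, bee) {
  field_energy(F, rt, bee) + travel_energy(D, bee)
}

#' Energy intake of one trip
#'
#' A full load is always collected, so intake is `gamma e_R` joules,
#' independent of distance and flower density.
#'
#' @inheritParams load_time
#' @return Joules.
#' @export
energy_intake <- function(rt, bee) {
  bee$gamma * rt$e_R
}

#' Net energetic efficiency of a foraging trip
#'
#' `NEE = (EI - EE) / EE`, the currency by which patches are ranked.
#' Positive exactly when the trip energy balance is positive.
#'
#' @inheritParams trip_duration
#' @return Dimensionless efficiency.
#' @examples
#' nee(1000, 264, resource_preset("osr"), bee_parameters())  # ~7.4
#' @export
nee <- function(D, F, rt, bee) {
  ee <- total_energy(D, F, rt, bee)
  (energy_intake(rt, bee) - ee) / ee
}

#' Intake/expenditure ratio of a foraging trip
#'
#' `EI/EE`, algebraically `nee + 1`. In the equal-distance form it equals
#' `gaF / (1 + c gaF) * e_R/e_F` with `c = 2D/(gamma v)`, rising
#' asymptotically with the nectar acquisition rate `gaF` to
#' `(1/c) e_R/e_F`.
#'
#' @inheritParams trip_duration
#' @return Dimensionless ratio.
#' @export
ei_ee_ratio <- function(D, F, rt, bee) {
  energy_intake(rt, bee) / total_energy(D, F, rt, bee)
}

#' Trip energy balance
#'
#' `EI - EE` joules; a patch can only be exploited while this is positive.
#'
#' @inheritParams trip_duration
#' @return Joules.
#' @export
energy_balance <- function(D, F, rt, bee) {
  energy_intake(rt, bee) - total_energy(D, F, rt, bee)
}

#' Sugar consumed on the return flight and the arriving load
#'
#' The return flight burns `E_c = e_L D / v` joules, met by consuming
#' `E_c / e_R` mg of the collected nectar, so `gamma - E_c/e_R` mg arrives
#' at the hive. A patch is infeasible on this account when the whole load
#' would be consumed en route (`gamma e_R <= E_c`).
#'
#' @inheritParams trip_duration
#' @return A list with `energy` (J), `nectar` (mg consumed), `arriving`
#'   (mg reaching the hive) and `feasible` (logical), each vectorized
#'   over `D`.
#' @export
return_consumption <- function(D, rt, bee) {
  if (any(D < 0)) stop("distance D must be >= 0")
  E_c <- bee$e_L * D / bee$v
  list(energy = E_c, nectar = E_c / rt$e_R,
       arriving = bee$gamma - E_c / rt$e_R,
       feasible = bee$gamma * rt$e_R > E_c)
}

#' Threshold foraging distance of a resource
#'
#' Distance at which the trip energy balance reaches zero:
#' `D_T = (v gamma / 2) * (e_R/e_F - 1/(g a F))`, evaluated at the
#' undepleted density `F = F0` by default. Beyond `D_T` the patch cannot be
#' exploited. A negative value (resource never profitable) is returned
#' unclamped.
#'
#' @inheritParams load_time
#' @param F Open-flower density at which to evaluate; default `rt$F0`.
#' @return Metres.
#' @examples
#' # ~8.1 km for oilseed rape, ~12.7 km for clover under the calibrated preset
#' bee <- bee_preset("calibrated")
#' threshold_distance(resource_preset("osr"), bee) / 1000
#' threshold_distance(resource_preset("clover"), bee) / 1000
#' @export
threshold_distance <- function(rt, bee, F = rt$F0) {
  (bee$v * bee$gamma / 2) * (rt$e_R / bee$e_F - 1 / (rt$g * rt$a * F))
}

#' Threshold distance in the mass-flowering limit
#'
#' With saturating flower density the field search cost vanishes and the
#' threshold simplifies to `[gamma v / (2 e_F)] e_R`: linear in the nectar
#' energy density with a slope set only by honeybee constants.
#'
#' @inheritParams load_time
#' @return Metres; always `>=` [threshold_distance()] for the same resource.
#' @export
threshold_distance_massflowering <- function(rt, bee) {
  (bee$gamma * bee$v / (2 * bee$e_F)) * rt$e_R
}

#' Probability that a patch is detected by at least one scout
#'
#' `1 - (1 - sigma)^s` for per-scout encounter probability `sigma` and `s`
#' scouts. The studied scenarios assume perfect knowledge (`P = 1` for all
#' patches); this operation supports the general case.
#'
#' @param sigma Per-scout encounter probability, in \[0, 1\] (vectorized).
#' @param s Number of scouts, `>= 0`.
#' @return Detection probability.
#' @examples
#' detection_probability(0.5, 2)  # 0.75
#' @export
detection_probability <- function(sigma, s) {
  if (any(sigma < 0 | sigma > 1)) stop("sigma must be in [0, 1]")
  if (any(s < 0)) stop("scout count s must be >= 0")
  1 - (1 - sigma)^s
}

#' Is a patch energetically exploitable?
#'
#' A patch is feasible when flowers are present (`F > 0`), it lies within
#' the maximum foraging distance, and the trip energy balance is positive
#' (which also guarantees the return flight does not consume the whole
#' load). Used as a predicate rather than an error so simulation loops can
#' skip infeasible patches cheaply.
#'
#' @inheritParams trip_duration
#' @return Logical, vectorized.
#' @export
patch_feasible <- function(D, F, rt, bee) {
  F > 0 & D <= bee$D_max & energy_balance(D, F, rt, bee) > 0
}
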