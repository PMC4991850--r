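#' Honeybee energetic and behavioural parameters
#'
#' Bundles the colony-level constants of the foraging model. Defaults are
#' the standard tabulated values for *Apis mellifera* nectar foragers.
#'
#' @param gamma Crop capacity (maximum nectar load), mg. Default 32.5.
#' @param v Flight speed, m s^-1. Default 4.17.
#' @param e_U Unloaded flight cost, J s^-1. Default 0.037.
#' @param e_L Loaded flight cost, J s^-1. Default 0.075.
#' @param e_F Mean flight cost while foraging in the field, J s^-1.
#'   Defaults to `(e_U + e_L)/2` but may be set independently; see
#'   [bee_preset()] for the alternative calibrated value.
#' @param e_sugar Energy density of sugar, J mg^-1. Default 17.2.
#' @param t_UD Time spent unloading and dancing between trips, s. Default 300.
#' @param D_max Maximum foraging distance considered, m. Default 2000.
#' @param n_foragers Number of active foragers per time step. Default 100.
#' @param s_scouts Scout count used by [detection_probability()]. Default 10.
#' @param dt Time-step length, s. Default 3600 (one hour).
#' @param day_hours Length of the foraging day, h. Default 10.
#'
#' @return An object of class `bee_parameters` (a named list).
#' @examples
#' bee <- bee_parameters()
#' bee$e_F  # mean of loaded and unloaded flight cost
#' @export
bee_parameters <- function(gamma = 32.5, v = 4.17, e_U = 0.037, e_L = 0.075,
                           e_F = NULL, e_sugar = 17.2, t_UD = 300,
                           D_max = 2000, n_foragers = 100, s_scouts = 10,
                           dt = 3600, day_hours = 10) {
  if (is.null(e_F)) e_F <- (e_U + e_L) / 2
  bee <- list(gamma = gamma, v = v, e_U = e_U, e_L = e_L, e_F = e_F,
              e_sugar = e_sugar, t_UD = t_UD, D_max = D_max,
              n_foragers = n_foragers, s_scouts = s_scouts,
              dt = dt, day_hours = as.integer(day_hours))
  for (nm in c("gamma", "v", "e_U", "e_L", "e_F", "e_sugar", "t_UD", "dt"))
    if (!is.numeric(bee[[nm]]) || length(bee[[nm]]) != 1L || bee[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  if (bee$e_U > bee$e_L) stop("unloaded flight cost e_U must not exceed loaded cost e_L")
  if (bee$D_max < 0) stop("D_max must be >= 0")
  if (bee$n_foragers < 0 || bee$s_scouts < 0) stop("counts must be >= 0")
  if (bee$day_hours < 1) stop("day_hours must be >= 1")
  class(bee) <- "bee_parameters"
  bee
}

#' Named bee-parameter presets
#'
#' `"default"` uses the mean flight cost `e_F = (e_U + e_L)/2 = 0.056` J s^-1
#' implied by the tabulated loaded/unloaded costs. `"calibrated"` sets
#' `e_F = 0.066` J s^-1, an alternative mean flight-cost estimate under
#' which the threshold foraging distances for oilseed rape and clover come
#' out at 8.1 and 12.7 km (see [threshold_distance()]); with the default
#' they are 9.6 and 15.1 km. Both parameterizations are in circulation and
#' the choice matters only for absolute threshold distances, not for patch
#' ranking at a common `e_F`.
#'
#' @param name `"default"` or `"calibrated"`.
#' @param ... Further arguments passed to [bee_parameters()].
#' @return A `bee_parameters` object.
#' @examples
#' threshold_distance(resource_preset("osr"), bee_preset("calibrated")) / 1000
#' @export
bee_preset <- function(name = c("default", "calibrated"), ...) {
  name <- match.arg(name)
  switch(name,
    default = bee_parameters(...),
    calibrated = bee_parameters(e_F = 0.066, ...)
  )
}

#' Define a nectar resource type
#'
#' A resource type describes one nectar-providing flower species or crop:
#' how much nectar a bee obtains per flower, how densely open flowers occur,
#' the sugar content of the nectar, and the search/handling coefficients of
#' the type-II functional response.
#'
#' @param name Label, e.g. `"osr"`.
#' @param g Nectar obtained per flower visit, mg.
#' @param F0 Undepleted open-flower density, m^-2.
#' @param sugar_share Sugar content of nectar, g g^-1 (0, 1].
#' @param a Attack (search) rate, m^2 s^-1.
#' @param h Handling time per flower, s.
#' @param e_R Energy density of the nectar, J mg^-1. Defaults to
#'   `sugar_share * e_sugar` and must equal it to within floating tolerance.
#' @param anthesis Integer vector of day-hours (1-based) during which flowers
#'   are open, or `NULL` for the whole day. Anthesis is binary: all flowers
#'   open or all closed.
#' @param r Hourly renewal fraction of depleted flowers, in \[0, 1\]. Default 0.
#' @param e_sugar Energy density of sugar, J mg^-1 (used to derive `e_R`).
#'
#' @return An object of class `resource_type` (a named list).
#' @examples
#' resource_type("osr", g = 1.071, F0 = 264, sugar_share = 0.47,
#'               a = 0.00147, h = 4.1)
#' @export
resource_type <- function(name, g, F0, sugar_share, a, h, e_R = NULL,
                          anthesis = NULL, r = 0, e_sugar = 17.2) {
  if (is.null(e_R)) e_R <- sugar_share * e_sugar
  if (g <= 0 || F0 <= 0 || a <= 0 || h <= 0)
    stop("g, F0, a and h must be strictly positive")
  if (sugar_share <= 0 || sugar_share > 1)
    stop("sugar_share must be in (0, 1]")
  if (abs(e_R - sugar_share * e_sugar) > 1e-6 * e_sugar)
    stop("e_R must equal sugar_share * e_sugar")
  if (r < 0 || r > 1) stop("renewal fraction r must be in [0, 1]")
  if (!is.null(anthesis)) anthesis <- sort(unique(as.integer(anthesis)))
  rt <- list(name = name, g = g, F0 = F0, sugar_share = sugar_share,
             e_R = e_R, a = a, h = h, anthesis = anthesis, r = r)
  class(rt) <- "resource_type"
  rt
}

#' Built-in resource types
#'
#' `"osr"` is oilseed rape (*Brassica napus*), a mass-flowering crop with a
#' conservative parameter choice; `"clover"` is white clover
#' (*Trifolium repens*) with an optimistic choice, used for flower strips
#' and off-field habitats.
#'
#' @param name `"osr"` or `"clover"`.
#' @return A [resource_type()].
#' @examples
#' resource_preset("clover")$e_R  # 0.74 * 17.2 = 12.728 J/mg
#' @export
resource_preset <- function(name = c("osr", "clover")) {
  name <- match.arg(name)
  switch(name,
    osr = resource_type("osr", g = 1.071, F0 = 264, sugar_share = 0.47,
                        a = 0.00147, h = 4.1),
    clover = resource_type("clover", g = 0.373, F0 = 2808, sugar_share = 0.74,
                           a = 0.00020, h = 1.22)
  )
}

#' @export
print.bee_parameters <- function(x, ...) {
  cat("Honeybee parameters\n")
  cat(sprintf("  load gamma %.1f mg | speed %.2f m/s | e_U %.3f  e_L %.3f  e_F %.3f J/s\n",
              x$gamma, x$v, x$e_U, x$e_L, x$e_F))
  cat(sprintf("  e_sugar %.1f J/mg | t_UD %g s | D_max %g m | %d foragers | %d h day\n",
              x$e_sugar, x$t_UD, x$D_max, x$n_foragers, x$day_hours))
  invisible(x)
}

#' @export
print.resource_type <- function(x, ...) {
  cat(sprintf("Resource '%s': g %.3f mg, F0 %g /m2, sugar %.2f (e_R %.3f J/mg), a %g m2/s, h %.2f s, r %g\n",
              x$name, x$g, x$F0, x$sugar_share, x$e_R, x$a, x$h, x$r))
  if (!is.null(x$anthesis)) cat("  open hours:", paste(x$anthesis, collapse = " "), "\n")
  invisible(x)
}

#' Read or write a full model configuration as YAML
#'
#' The configuration mirrors the parameter tables: a `bee` block (Table-style
#' honeybee constants), a named `resources` block, a `simulation` block
#' ([sim_config()] fields) and an `exposure` block ([exposure_config()]
#' fields). Values absent from the file keep their defaults.
#'
#' @param path File path.
#' @return `read_model_config()` returns a list with elements `bee`,
#'   `resources`, `sim`, `exposure`; `write_model_config()` writes and
#'   returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bee <- do.call(bee_parameters, raw$bee %||% list())
  res <- lapply(names(raw$resources %||% list()), function(nm) {
    do.call(resource_type, c(list(name = nm), raw$resources[[nm]]))
  })
  names(res) <- vapply(res, `[[`, "", "name")
  if (length(res) == 0L)
    res <- list(osr = resource_preset("osr"), clover = resource_preset("clover"))
  sim <- do.call(sim_config, raw$simulation %||% list())
  eraw <- raw$exposure %||% list()
  if (is.character(eraw$reference)) {
    ref <- eraw$reference
    eraw$reference <- if (ref %in% names(res)) res[[ref]] else resource_preset(ref)
  }
  exp <- do.call(exposure_config, c(eraw, list(e_sugar = bee$e_sugar)))
  list(bee = bee, resources = res, sim = sim, exposure = exp)
}

#' @rdname read_model_config
#' @param config A list as returned by [read_model_config()], or `NULL` for
#'   the package defaults.
#' @export
write_model_config <- function(path, config = NULL) {
  if (is.null(config))
    config <- list(bee = bee_parameters(),
                   resources = list(osr = resource_preset("osr"),
                                    clover = resource_preset("clover")),
                   sim = sim_config(), exposure = exposure_config())
  strip <- function(x, drop = character()) {
    x <- unclass(x)
    x[setdiff(names(x), drop)]
  }
  out <- list(
    bee = strip(config$bee),
    resources = lapply(config$resources, strip, drop = "name"),
    simulation = strip(config$sim),
    exposure = strip(config$exposure, drop = "reference")
  )
  out$exposure$reference <- config$exposure$reference$name
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
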