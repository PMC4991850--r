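## Exposure at the hive entrance: chemical mass flux, sugar-based
## concentrations and dilution factors relative to a treated reference crop.

#' Exposure configuration
#'
#' @param C_P Reference chemical concentration in nectar on a treated
#'   target-crop field (wet-weight base, ug mg^-1); the predicted
#'   environmental concentration. Must be `> 0`.
#' @param metabolized If `TRUE` (default) the chemical is metabolized
#'   together with the sugar consumed on the return flight (no enrichment,
#'   `X_m`); if `FALSE` the whole chemical load arrives while some sugar is
#'   burned, enriching the concentration (`X_e`).
#' @param reference [resource_type()] of the treated reference crop, used to
#'   convert `C_P` to a sugar base. Default oilseed rape.
#' @param e_sugar Energy density of sugar, J mg^-1.
#' @return An object of class `exposure_config`.
#' @export
exposure_config <- function(C_P = 1, metabolized = TRUE,
                            reference = resource_preset("osr"),
                            e_sugar = 17.2) {
  if (C_P <= 0) stop("C_P must be > 0")
  if (is.character(reference)) reference <- resource_preset(reference)
  structure(list(C_P = C_P, metabolized = isTRUE(metabolized),
                 reference = reference, e_sugar = e_sugar),
            class = "exposure_config")
}

#' Chemical mass entering the hive over a day
#'
#' Without metabolization the full collected load of chemical arrives:
#' `sum n_i gamma b_i C_i`. With metabolization the chemical is burned with
#' the sugar and only `sum n_i (gamma - E_c_i/e_R_i) b_i C_i` arrives.
#'
#' @param day A `foraging_day` result from [simulate_day()].
#' @param metabolized Logical; see [exposure_config()].
#' @return Micrograms of chemical.
#' @export
chemical_influx <- function(day, metabolized = TRUE) {
  h <- day$hourly
  if (!nrow(h)) return(0)
  load <- if (metabolized) day$bee$gamma - h$E_c / h$e_R else day$bee$gamma
  sum(h$n * load * h$b * h$C)
}

#' Sugar mass entering the hive over a day
#'
#' @param day A `foraging_day` result.
#' @return Milligrams of sugar.
#' @export
sugar_influx <- function(day) {
  sum(day$hourly$sugar)
}

#' Sugar-based chemical concentration at the hive entrance
#'
#' Total chemical divided by total sugar entering the hive (ug mg^-1 sugar):
#' the daily-averaged concentration `X_e` (enrichment variant) or `X_m`
#' (metabolized variant). When no sugar was collected at all the
#' concentration is undefined; the explicit no-exposure marker `NA` is
#' returned (never `NaN`).
#'
#' @param day A `foraging_day` result.
#' @param cfg [exposure_config()].
#' @return ug chemical per mg sugar, or `NA` if no sugar was collected.
#' @export
hive_concentration <- function(day, cfg = exposure_config()) {
  sug <- sugar_influx(day)
  if (sug <= 0) return(NA_real_)
  chemical_influx(day, cfg$metabolized) / sug
}

#' Sugar-based reference concentration on a treated field
#'
#' `X_P = C_P e_sugar / e_R`: the wet-weight reference concentration
#' converted to a per-mg-sugar base; the factor exceeds one whenever the
#' nectar is not pure sugar.
#'
#' @param cfg [exposure_config()].
#' @return ug chemical per mg sugar.
#' @examples
#' reference_concentration(exposure_config(C_P = 1))  # 17.2/8.084 ~ 2.13
#' @export
reference_concentration <- function(cfg = exposure_config()) {
  cfg$C_P * cfg$e_sugar / cfg$reference$e_R
}

#' Dilution factor of hive-entrance exposure
#'
#' `phi = X / X_P`: 1 means the hive receives the treated-field
#' concentration undiluted, 0 means no exposure; values above 1 are
#' possible only in the enrichment variant. Days without any collected
#' sugar propagate the `NA` no-exposure marker.
#'
#' @inheritParams hive_concentration
#' @return Dimensionless factor, or `NA` when undefined.
#' @export
dilution_factor <- function(day, cfg = exposure_config()) {
  hive_concentration(day, cfg) / reference_concentration(cfg)
}

#' Full exposure summary for one foraging day
#'
#' @inheritParams hive_concentration
#' @return An object of class `exposure_result`: list with `chemical` (ug),
#'   `sugar` (mg), `X` (ug/mg sugar), `phi`, `defined` (FALSE when no sugar
#'   was collected) and `per_patch` (per-patch sugar and chemical
#'   contributions, whose sums reproduce the totals).
#' @export
exposure_summary <- function(day, cfg = exposure_config()) {
  h <- day$hourly
  per <- if (nrow(h)) {
    load <- if (cfg$metabolized) day$bee$gamma - h$E_c / h$e_R else day$bee$gamma
    contrib <- data.frame(id = h$id, sugar = h$sugar,
                          chemical = h$n * load * h$b * h$C,
                          stringsAsFactors = FALSE)
    aggregate(contrib[c("sugar", "chemical")], by = list(id = contrib$id), sum)
  } else data.frame(id = character(), sugar = numeric(), chemical = numeric())
  sug <- sugar_influx(day)
  chem <- chemical_influx(day, cfg$metabolized)
  X <- hive_concentration(day, cfg)
  structure(list(chemical = chem, sugar = sug, X = X,
                 phi = X / reference_concentration(cfg),
                 defined = sug > 0, per_patch = per),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  if (!x$defined) {
    cat("Exposure: no sugar collected (no-exposure day)\n")
  } else {
    cat(sprintf("Exposure: %.3g ug chemical in %.3g mg sugar -> X %.4g ug/mg, phi %.4g\n",
                x$chemical, x$sugar, x$X, x$phi))
  }
  invisible(x)
}
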