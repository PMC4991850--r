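## The three mitigation-scenario generators. Each produces a "realization":
## a resolved patch table (resource coefficients joined on, treatment flags
## drawn) ready to be priced per hive site and simulated.

## join resource coefficients onto landscape patch rows
resolve_patches <- function(ls, idx = seq_len(nrow(ls$patches))) {
  p <- ls$patches[idx, , drop = FALSE]
  rt <- ls$resources[p$resource]
  out <- data.frame(id = p$id, category = p$category, resource = p$resource,
                    A = p$area, stringsAsFactors = FALSE)
  out$geometry <- p$geometry
  out$F0 <- vapply(rt, `[[`, numeric(1), "F0")
  out$g <- vapply(rt, `[[`, numeric(1), "g")
  out$a <- vapply(rt, `[[`, numeric(1), "a")
  out$h <- vapply(rt, `[[`, numeric(1), "h")
  out$e_R <- vapply(rt, `[[`, numeric(1), "e_R")
  out$sugar_share <- vapply(rt, `[[`, numeric(1), "sugar_share")
  out$r <- vapply(rt, `[[`, numeric(1), "r")
  out$anthesis <- lapply(rt, `[[`, "anthesis")
  out$C <- 0
  out$treated <- FALSE
  rownames(out) <- NULL
  out
}

.realization <- function(patches, ls, scenario, params) {
  structure(list(patches = patches, resolution = ls$resolution,
                 scenario = scenario, params = params),
            class = "realization")
}

#' @export
print.realization <- function(x, ...) {
  cat(sprintf("Scenario '%s' realization: %d patches (%d treated)\n",
              x$scenario, nrow(x$patches), sum(x$patches$treated)))
  invisible(x)
}

#' Scenario (i): untreated alternative crop fields
#'
#' Target-crop fields are treated independently with probability `p`
#' (the field adjacent to a hive site is additionally forced treated when
#' the realization is run for that site). Alternative-crop fields are never
#' treated; their attractiveness is manipulated by scaling the sugar
#' content (and hence nectar energy density) by `sugar_mult`. Off-field
#' elements provide no resources in this scenario.
#'
#' @param ls A [landscape()].
#' @param p Treatment probability in \[0, 1\].
#' @param sugar_mult Sugar-content multiplier for the alternative crop
#'   (tested values 0.8, 0.9, 1, 1.1, 1.2). Default 1.
#' @param seed Integer seed for the treatment draw.
#' @return A realization object (resolved patch table plus metadata).
#' @export
scenario_alternative_fields <- function(ls, p, sugar_mult = 1, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  keep <- which(ls$patches$category %in% c("target-field", "alternative-field"))
  pt <- resolve_patches(ls, keep)
  set.seed(as.integer(seed))
  tgt <- pt$category == "target-field"
  pt$treated[tgt] <- runif(sum(tgt)) < p
  alt <- pt$category == "alternative-field"
  pt$sugar_share[alt] <- pt$sugar_share[alt] * sugar_mult
  pt$e_R[alt] <- pt$e_R[alt] * sugar_mult
  .realization(pt, ls, "alternative_fields",
               list(p = p, sugar_mult = sugar_mult, seed = seed))
}

## candidate strips: 4 per target field, along the bounding-box sides.
## Carried area is exactly w * perimeter/4; the thin side rectangle is used
## for distance only.
.strip_candidates <- function(ls, w) {
  tgt <- which(ls$patches$category == "target-field")
  out <- vector("list", length(tgt) * 4L)
  k <- 0L
  for (i in tgt) {
    xy <- ls$patches$geometry[[i]]
    xr <- range(xy[, 1]); yr <- range(xy[, 2])
    n <- nrow(xy)
    j <- c(seq_len(n)[-1], 1L)
    perim <- sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
    A_strip <- w * perim / 4
    if (4 * A_strip >= ls$patches$area[i])
      stop("strip area would exceed area of field ", ls$patches$id[i])
    sides <- list(
      rect_poly(xr[1], yr[1], diff(xr), min(w, diff(yr))),             # bottom
      rect_poly(xr[2] - min(w, diff(xr)), yr[1], min(w, diff(xr)), diff(yr)),  # right
      rect_poly(xr[1], yr[2] - min(w, diff(yr)), diff(xr), min(w, diff(yr))),  # top
      rect_poly(xr[1], yr[1], min(w, diff(xr)), diff(yr)))             # left
    for (s in 1:4) {
      k <- k + 1L
      out[[k]] <- list(id = sprintf("%s_strip%d", ls$patches$id[i], s),
                       field = ls$patches$id[i], area = A_strip,
                       geometry = sides[[s]])
    }
  }
  out
}

#' Scenario (ii): in-field flower strips at target-field edges
#'
#' Each target-crop field receives up to 4 clover strips along its edges,
#' each present independently with probability `p`, of length one quarter
#' of the field perimeter and width `w`, so each strip covers
#' `w * perimeter/4` square metres. Strip area is subtracted from the crop
#' field (strips are in-field, off-crop habitat). All target fields are
#' treated; strips are untreated. Clover density equals the clover-field
#' density.
#'
#' @param ls A [landscape()].
#' @param p Per-strip presence probability.
#' @param w Strip width, m (tested values 1, 2, 5, 10).
#' @param seed Integer seed for the presence draws.
#' @return A realization; field + strip areas conserve the original field
#'   area exactly.
#' @export
scenario_flower_strips <- function(ls, p, w, seed = 1L) {
  stopifnot(p >= 0, p <= 1, w > 0)
  fields <- resolve_patches(ls, which(ls$patches$category == "target-field"))
  fields$treated <- TRUE
  cand <- .strip_candidates(ls, w)
  set.seed(as.integer(seed))
  present <- runif(length(cand)) < p
  strips <- NULL
  if (any(present)) {
    cl <- ls$resources$clover %||% resource_preset("clover")
    sel <- cand[present]
    strips <- data.frame(
      id = vapply(sel, `[[`, "", "id"),
      category = "flower-strip", resource = cl$name,
      A = vapply(sel, `[[`, numeric(1), "area"),
      stringsAsFactors = FALSE)
    strips$geometry <- lapply(sel, `[[`, "geometry")
    strips$F0 <- cl$F0; strips$g <- cl$g; strips$a <- cl$a; strips$h <- cl$h
    strips$e_R <- cl$e_R; strips$sugar_share <- cl$sugar_share; strips$r <- cl$r
    strips$anthesis <- rep(list(cl$anthesis), nrow(strips))
    strips$C <- 0; strips$treated <- FALSE
    ## subtract in-field strip area from the host fields
    lost <- tapply(strips$A, vapply(sel, `[[`, "", "field"), sum)
    m <- match(names(lost), fields$id)
    fields$A[m] <- fields$A[m] - as.numeric(lost)
  }
  pt <- rbind(fields, strips)
  rownames(pt) <- NULL
  .realization(pt, ls, "flower_strips", list(p = p, w = w, seed = seed))
}

#' Scenario (iii): managed off-field habitats
#'
#' Each off-field semi-natural element independently becomes a clover
#' resource patch with probability `p`; non-selected elements stay inert.
#' Resource quality scales the open-flower density by `quality_mult`
#' (low/medium/high = 0.5/1/1.5 times the clover-field density; at 1 the
#' patches are identical in resource terms to flower strips). All target
#' fields are treated.
#'
#' @param ls A [landscape()].
#' @param p Probability that an off-field element provides nectar.
#' @param quality_mult Flower-density multiplier.
#' @param seed Integer seed for the selection draw.
#' @return A realization.
#' @export
scenario_off_field <- function(ls, p, quality_mult = 1, seed = 1L) {
  stopifnot(p >= 0, p <= 1, quality_mult > 0)
  fields <- resolve_patches(ls, which(ls$patches$category == "target-field"))
  fields$treated <- TRUE
  off_idx <- which(ls$patches$category == "off-field")
  set.seed(as.integer(seed))
  sel <- off_idx[runif(length(off_idx)) < p]
  off <- NULL
  if (length(sel)) {
    off <- resolve_patches(ls, sel)
    off$F0 <- off$F0 * quality_mult
    off$treated <- FALSE
  }
  pt <- rbind(fields, off)
  rownames(pt) <- NULL
  .realization(pt, ls, "off_field",
               list(p = p, quality_mult = quality_mult, seed = seed))
}
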