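## Landscape data model: a table of polygonal resource patches with
## category and resource attributes, plus readers/writers, a seeded
## synthetic generator, hive-site enumeration on the grid and hive-patch
## distances.

.categories <- c("target-field", "alternative-field", "flower-strip", "off-field")

#' Construct a landscape
#'
#' @param patches `data.frame` with columns `id`, `category`, `resource`,
#'   a list-column `geometry` of two-column vertex matrices, and optionally
#'   `area` (m^2; computed from geometry when absent).
#' @param resources Named list of [resource_type()] objects covering every
#'   name in `patches$resource`.
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)`; computed from the
#'   geometries when `NULL`.
#' @param resolution Hive-site grid resolution, m. Default 25.
#' @return Object of class `landscape`.
#' @export
landscape <- function(patches, resources, extent = NULL, resolution = 25) {
  stopifnot(is.data.frame(patches), is.list(patches$geometry))
  if (!all(patches$category %in% .categories))
    stop("unknown patch category; expected one of ",
         paste(.categories, collapse = ", "))
  miss <- setdiff(unique(patches$resource), names(resources))
  if (length(miss)) stop("unknown resource name(s): ", paste(miss, collapse = ", "))
  if (is.null(patches$area))
    patches$area <- vapply(patches$geometry, poly_area, numeric(1))
  if (any(patches$area <= 0)) stop("all patch areas must be > 0")
  patches$id <- as.character(patches$id)
  if (anyDuplicated(patches$id)) stop("patch ids must be unique")
  if (is.null(extent)) {
    allxy <- do.call(rbind, patches$geometry)
    extent <- c(min(allxy[, 1]), min(allxy[, 2]), max(allxy[, 1]), max(allxy[, 2]))
  }
  structure(list(patches = patches, resources = resources,
                 extent = extent, resolution = resolution),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  tab <- table(x$patches$category)
  ha <- tapply(x$patches$area, x$patches$category, sum) / 1e4
  cat(sprintf("Landscape: %d patches on [%g, %g] x [%g, %g] m (grid %g m)\n",
              nrow(x$patches), x$extent[1], x$extent[3], x$extent[2],
              x$extent[4], x$resolution))
  for (nm in names(tab))
    cat(sprintf("  %-18s %4d patches, %8.1f ha\n", nm, tab[[nm]], ha[[nm]]))
  invisible(x)
}

#' Summary statistics of a landscape
#' @param object A `landscape`.
#' @param ... Unused.
#' @return data.frame with per-category patch counts and total hectares.
#' @export
summary.landscape <- function(object, ...) {
  p <- object$patches
  agg <- aggregate(list(area_ha = p$area / 1e4), by = list(category = p$category), sum)
  agg$n <- as.integer(table(p$category)[agg$category])
  agg[c("category", "n", "area_ha")]
}

#' Generate a reproducible synthetic agricultural landscape
#'
#' Emulates an arable study region: large rectangular target-crop (oilseed
#' rape) fields, a set of alternative-crop fields, and numerous small
#' elongated off-field semi-natural elements (verges, ditch sides), placed
#' without field overlap on a square extent. Field corners snap to the
#' hive-site grid so that field borders coincide with cell boundaries.
#'
#' @param seed Integer seed; the same seed yields a byte-identical landscape.
#' @param extent Side length of the square region, m. Default 5000.
#' @param n_target,n_alt,n_offfield Patch counts per category.
#' @param field_ha Range of field areas, ha. Default `c(2, 10)`.
#' @param offfield_length,offfield_width Ranges for off-field element
#'   dimensions, m.
#' @param resolution Grid resolution, m. Default 25.
#' @param resources Resource registry; defaults to the built-in oilseed
#'   rape and clover types (alternative fields start as `"osr"`; scenario
#'   generators retype them).
#' @param max_tries Placement attempts per patch before giving up.
#' @return A [landscape()].
#' @examples
#' ls <- generate_synthetic_landscape(seed = 1, extent = 2000, n_target = 6,
#'                                    n_alt = 2, n_offfield = 30)
#' summary(ls)
#' @export
generate_synthetic_landscape <- function(seed, extent = 5000, n_target = 50,
                                         n_alt = 20, n_offfield = 500,
                                         field_ha = c(2, 10),
                                         offfield_length = c(50, 400),
                                         offfield_width = c(2, 10),
                                         resolution = 25,
                                         resources = NULL,
                                         max_tries = 2000) {
  set.seed(as.integer(seed))
  if (is.null(resources))
    resources <- list(osr = resource_preset("osr"),
                      clover = resource_preset("clover"))
  snap <- function(x) pmax(resolution, round(x / resolution) * resolution)
  fields <- list()
  place_field <- function(k, prefix) {
    for (try in seq_len(max_tries)) {
      A <- runif(1, field_ha[1], field_ha[2]) * 1e4
      asp <- runif(1, 1, 2.5)
      w <- snap(sqrt(A * asp)); h <- snap(A / sqrt(A * asp))
      x0 <- snap(runif(1, 0, extent - w)) ; y0 <- snap(runif(1, 0, extent - h))
      if (x0 + w > extent || y0 + h > extent) next
      g <- rect_poly(x0, y0, w, h)
      if (!any(vapply(fields, rects_overlap, logical(1), b = g))) {
        fields[[length(fields) + 1L]] <<- g
        return(g)
      }
    }
    stop("could not place field ", prefix, k, " after ", max_tries,
         " tries; lower the counts or enlarge the extent")
  }
  rows <- list()
  for (k in seq_len(n_target)) {
    g <- place_field(k, "t")
    rows[[length(rows) + 1L]] <- list(id = sprintf("t%03d", k),
                                      category = "target-field",
                                      resource = "osr", geometry = g)
  }
  for (k in seq_len(n_alt)) {
    g <- place_field(k, "a")
    rows[[length(rows) + 1L]] <- list(id = sprintf("a%03d", k),
                                      category = "alternative-field",
                                      resource = "osr", geometry = g)
  }
  for (k in seq_len(n_offfield)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      L <- runif(1, offfield_length[1], offfield_length[2])
      W <- runif(1, offfield_width[1], offfield_width[2])
      if (runif(1) < 0.5) { tmp <- L; L <- W; W <- tmp }  # random orientation
      x0 <- runif(1, 0, extent - L); y0 <- runif(1, 0, extent - W)
      g <- rect_poly(x0, y0, L, W)
      ## off-field elements may abut fields but not lie inside them
      if (!any(vapply(fields, rects_overlap, logical(1), b = g))) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place off-field element ", k)
    rows[[length(rows) + 1L]] <- list(id = sprintf("o%04d", k),
                                      category = "off-field",
                                      resource = "clover", geometry = g)
  }
  patches <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    category = vapply(rows, `[[`, "", "category"),
    resource = vapply(rows, `[[`, "", "resource"),
    stringsAsFactors = FALSE)
  patches$geometry <- lapply(rows, `[[`, "geometry")
  landscape(patches, resources, extent = c(0, 0, extent, extent),
            resolution = resolution)
}

#' Read a landscape from GeoJSON or CSV-with-WKT
#'
#' GeoJSON input must be a FeatureCollection of Polygon features with
#' properties `id`, `category`, `resource` (and optionally `area`). CSV
#' input must have columns `id`, `category`, `resource`, `geometry` (WKT
#' `POLYGON`) and optionally `area`. Area is computed from the geometry
#' when absent.
#'
#' @param path File path (`.geojson`/`.json` or `.csv`).
#' @param resources Resource registry; defaults to the built-in presets.
#' @param resolution Grid resolution, m.
#' @return A [landscape()].
#' @export
load_landscape <- function(path, resources = NULL, resolution = 25) {
  if (is.null(resources))
    resources <- list(osr = resource_preset("osr"),
                      clover = resource_preset("clover"))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    if (!identical(gj$type, "FeatureCollection"))
      stop("expected a GeoJSON FeatureCollection")
    feats <- gj$features
    geom <- lapply(feats, function(f) {
      if (!identical(f$geometry$type, "Polygon"))
        stop("only Polygon features are supported")
      ring <- f$geometry$coordinates[[1]]
      xy <- t(vapply(ring, function(pt) as.numeric(unlist(pt)[1:2]), numeric(2)))
      if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
        xy <- xy[-nrow(xy), , drop = FALSE]
      colnames(xy) <- c("x", "y")
      xy
    })
    prop <- function(nm, default = NA) vapply(feats, function(f)
      as.character(f$properties[[nm]] %||% default), character(1))
    patches <- data.frame(id = prop("id"), category = prop("category"),
                          resource = prop("resource"), stringsAsFactors = FALSE)
    ar <- vapply(feats, function(f) as.numeric(f$properties$area %||% NA_real_),
                 numeric(1))
    patches$geometry <- geom
    if (!all(is.na(ar))) {
      comp <- vapply(geom, poly_area, numeric(1))
      patches$area <- ifelse(is.na(ar), comp, ar)
    }
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "category", "resource", "geometry")
    if (!all(need %in% names(tab)))
      stop("CSV landscape needs columns ", paste(need, collapse = ", "))
    patches <- tab[setdiff(names(tab), "geometry")]
    patches$geometry <- lapply(tab$geometry, parse_wkt_polygon)
  }
  landscape(patches, resources, resolution = resolution)
}

#' Write a landscape to GeoJSON or CSV-with-WKT
#'
#' @param ls A [landscape()].
#' @param path Output path; format chosen by extension as in
#'   [load_landscape()].
#' @return `path`, invisibly.
#' @export
write_landscape <- function(ls, path) {
  p <- ls$patches
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(p)), function(i) {
      xy <- p$geometry[[i]]
      ring <- rbind(xy, xy[1, , drop = FALSE])
      list(type = "Feature",
           properties = list(id = p$id[i], category = p$category[i],
                             resource = p$resource[i], area = p$area[i]),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                             function(j) as.numeric(ring[j, ])))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    out <- p[c("id", "category", "resource", "area")]
    out$geometry <- vapply(p$geometry, wkt_polygon, character(1))
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

## grid cell centres covered by target fields; returns logical matrix [nx, ny]
.target_mask <- function(ls) {
  res <- ls$resolution
  nx <- ceiling((ls$extent[3] - ls$extent[1]) / res)
  ny <- ceiling((ls$extent[4] - ls$extent[2]) / res)
  mask <- matrix(FALSE, nx, ny)
  owner <- matrix(NA_character_, nx, ny)
  tgt <- which(ls$patches$category == "target-field")
  for (i in tgt) {
    xy <- ls$patches$geometry[[i]]
    ix <- seq(max(1, floor((min(xy[, 1]) - ls$extent[1]) / res)),
              min(nx, ceiling((max(xy[, 1]) - ls$extent[1]) / res)))
    iy <- seq(max(1, floor((min(xy[, 2]) - ls$extent[2]) / res)),
              min(ny, ceiling((max(xy[, 2]) - ls$extent[2]) / res)))
    if (!length(ix) || !length(iy)) next
    cx <- ls$extent[1] + (ix - 0.5) * res
    cy <- ls$extent[2] + (iy - 0.5) * res
    grid <- expand.grid(kx = seq_along(ix), ky = seq_along(iy))
    inside <- point_in_poly(cx[grid$kx], cy[grid$ky], xy)
    sel <- grid[inside, , drop = FALSE]
    mask[cbind(ix[sel$kx], iy[sel$ky])] <- TRUE
    owner[cbind(ix[sel$kx], iy[sel$ky])] <- ls$patches$id[i]
  }
  list(mask = mask, owner = owner, nx = nx, ny = ny)
}

#' Enumerate candidate hive sites along target-field borders
#'
#' Every grid cell that is not itself part of a target-crop field but is
#' 8-adjacent to one is a candidate beehive location. A seeded random
#' sample of a fraction of these sites is returned; the same seed yields
#' the identical subset regardless of scenario, so scenario comparisons
#' share sites.
#'
#' @param ls A [landscape()].
#' @param sample_fraction Fraction of candidate sites to keep (default 0.1);
#'   1 keeps all.
#' @param seed Integer seed for the site sample.
#' @return data.frame with `site_id`, cell-centre coordinates `x`, `y`, and
#'   `adj_patch` (id of the adjacent target field, the one always treated).
#'   Empty (with a warning) when the landscape has no target fields.
#' @export
enumerate_hive_sites <- function(ls, sample_fraction = 0.1, seed = 1L) {
  if (!any(ls$patches$category == "target-field")) {
    warning("landscape contains no target-crop fields; no hive sites")
    return(data.frame(site_id = character(), x = numeric(), y = numeric(),
                      adj_patch = character(), stringsAsFactors = FALSE))
  }
  tm <- .target_mask(ls)
  res <- ls$resolution
  ## 8-neighbour dilation of the target mask
  shift <- function(m, dx, dy) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    sx <- seq_len(nrow(m)); sx <- sx[sx + dx >= 1 & sx + dx <= nrow(m)]
    sy <- seq_len(ncol(m)); sy <- sy[sy + dy >= 1 & sy + dy <= ncol(m)]
    out[sx + dx, sy + dy] <- m[sx, sy]
    out
  }
  near <- matrix(FALSE, tm$nx, tm$ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    near <- near | shift(tm$mask, dx, dy)
  }
  cand <- which(near & !tm$mask, arr.ind = TRUE)
  if (!nrow(cand)) {
    warning("target fields cover the whole grid; no border cells")
    return(data.frame(site_id = character(), x = numeric(), y = numeric(),
                      adj_patch = character(), stringsAsFactors = FALSE))
  }
  ## adjacent target patch: owner of the nearest neighbouring target cell
  adj <- character(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    best <- NA_character_
    for (dx in -1:1) for (dy in -1:1) {
      ii <- i + dx; jj <- j + dy
      if (ii < 1 || jj < 1 || ii > tm$nx || jj > tm$ny) next
      if (is.na(best) && tm$mask[ii, jj]) best <- tm$owner[ii, jj]
    }
    adj[k] <- best
  }
  sites <- data.frame(
    site_id = sprintf("s%05d", seq_len(nrow(cand))),
    x = ls$extent[1] + (cand[, 1] - 0.5) * res,
    y = ls$extent[2] + (cand[, 2] - 0.5) * res,
    adj_patch = adj, stringsAsFactors = FALSE)
  sites <- sites[order(sites$site_id), ]
  if (sample_fraction < 1) {
    set.seed(as.integer(seed))
    keep <- sort(sample.int(nrow(sites), max(1L, ceiling(sample_fraction * nrow(sites)))))
    sites <- sites[keep, ]
  }
  rownames(sites) <- NULL
  sites
}

#' Distance from a hive site to a patch
#'
#' Euclidean distance from the site's cell centre to the nearest point of
#' the patch polygon, floored at half a grid cell so that the adjacent
#' field keeps a small positive distance (it remains near-optimal without
#' a zero-distance singularity).
#'
#' @param site One row of [enumerate_hive_sites()] (or a list with `x`, `y`).
#' @param geometry Patch vertex matrix.
#' @param resolution Grid resolution, m.
#' @return Metres.
#' @export
hive_patch_distance <- function(site, geometry, resolution = 25) {
  max(dist_point_poly(site$x, site$y, geometry), resolution / 2)
}

## distances from one site to every patch of a patch data.frame
site_distances <- function(site, patches, resolution = 25) {
  vapply(patches$geometry, function(g)
    max(dist_point_poly(site$x, site$y, g), resolution / 2), numeric(1))
}
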