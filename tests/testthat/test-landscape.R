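bee <- bee_parameters()

test_that("synthetic landscapes are reproducible and sized as requested", {
  a <- generate_synthetic_landscape(seed = 11, extent = 2500, n_target = 8,
                                    n_alt = 3, n_offfield = 40)
  b <- generate_synthetic_landscape(seed = 11, extent = 2500, n_target = 8,
                                    n_alt = 3, n_offfield = 40)
  expect_identical(a$patches$id, b$patches$id)
  expect_identical(a$patches$geometry, b$patches$geometry)
  expect_equal(sum(a$patches$category == "target-field"), 8)
  expect_equal(sum(a$patches$category == "alternative-field"), 3)
  expect_equal(sum(a$patches$category == "off-field"), 40)
  # field areas stay in the requested band despite grid snapping
  ha <- a$patches$area[a$patches$category == "target-field"] / 1e4
  expect_true(all(ha > 2 * 0.85 & ha < 10 * 1.15))
  # mean field area tracks the centre of the sampling band
  big <- generate_synthetic_landscape(seed = 2, extent = 6000, n_target = 50,
                                      n_alt = 0, n_offfield = 0)
  tot <- sum(big$patches$area) / 1e4
  expect_lt(abs(tot - 50 * 6) / (50 * 6), 0.15)
  # fields never overlap
  g <- a$patches$geometry[a$patches$category != "off-field"]
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    xi <- range(g[[i]][, 1]); yi <- range(g[[i]][, 2])
    xj <- range(g[[j]][, 1]); yj <- range(g[[j]][, 2])
    expect_false(min(xi[2], xj[2]) > max(xi[1], xj[1]) &&
                 min(yi[2], yj[2]) > max(yi[1], yj[1]))
  }
})

test_that("landscape IO round-trips through GeoJSON and CSV-with-WKT", {
  ls <- generate_synthetic_landscape(seed = 4, extent = 1500, n_target = 4,
                                     n_alt = 2, n_offfield = 10)
  gj <- file.path(tempdir(), "ls.geojson")
  cs <- file.path(tempdir(), "ls.csv")
  write_landscape(ls, gj)
  write_landscape(ls, cs)
  back_gj <- load_landscape(gj)
  back_cs <- load_landscape(cs)
  for (back in list(back_gj, back_cs)) {
    expect_equal(nrow(back$patches), nrow(ls$patches))
    expect_equal(back$patches$id, ls$patches$id)
    expect_equal(back$patches$category, ls$patches$category)
    expect_equal(back$patches$area, ls$patches$area, tolerance = 1e-4)
  }
  # geometry survives exactly through GeoJSON
  expect_equal(back_gj$patches$geometry[[1]][, 1], ls$patches$geometry[[1]][, 1])
  unlink(c(gj, cs))
})

test_that("degenerate patches and unknown resources are rejected", {
  line <- cbind(x = c(0, 100, 0), y = c(0, 0, 0))  # zero area
  p <- data.frame(id = "z", category = "target-field", resource = "osr",
                  stringsAsFactors = FALSE)
  p$geometry <- list(line)
  expect_error(landscape(p, list(osr = resource_preset("osr"))), "area")
  p2 <- data.frame(id = "z", category = "target-field", resource = "lupin",
                   stringsAsFactors = FALSE)
  p2$geometry <- list(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  expect_error(landscape(p2, list(osr = resource_preset("osr"))), "resource")
  bad <- file.path(tempdir(), "bad.csv")
  writeLines("id,category,resource\nx,target-field,osr", bad)
  expect_error(load_landscape(bad), "geometry")
  unlink(bad)
})

test_that("a 4x4-cell square field has 20 border hive sites", {
  mk <- rbind(c(100, 100), c(200, 100), c(200, 200), c(100, 200))
  p <- data.frame(id = "t1", category = "target-field", resource = "osr",
                  stringsAsFactors = FALSE)
  p$geometry <- list(mk)
  ls <- landscape(p, list(osr = resource_preset("osr")),
                  extent = c(0, 0, 300, 300), resolution = 25)
  sites <- enumerate_hive_sites(ls, sample_fraction = 1)
  expect_equal(nrow(sites), 20)       # (6x6 - 4x4) ring of 8-adjacent cells
  expect_true(all(sites$adj_patch == "t1"))
  # two disjoint fields: union of border sets
  ls2 <- toy_landscape()
  s2 <- enumerate_hive_sites(ls2, sample_fraction = 1)
  expect_setequal(unique(s2$adj_patch), c("t1", "t2"))
  # sampling is seeded and nested in the full set
  half <- enumerate_hive_sites(ls2, sample_fraction = 0.3, seed = 9)
  half_again <- enumerate_hive_sites(ls2, sample_fraction = 0.3, seed = 9)
  expect_identical(half, half_again)
  expect_true(all(half$site_id %in% s2$site_id))
})

test_that("hive-patch distance floors at half a grid cell", {
  site <- list(x = 87.5, y = 150, site_id = "s")
  field <- rbind(c(100, 100), c(200, 100), c(200, 200), c(100, 200))
  expect_equal(hive_patch_distance(site, field), 12.5)
  # rectangle centred 1 km due north: distance is 1000 minus half-height
  north <- rbind(c(0, 950), c(200, 950), c(200, 1050), c(0, 1050))
  s0 <- list(x = 100, y = 0)
  expect_equal(hive_patch_distance(s0, north), 950)
  # translation invariance
  shift <- 1234.5
  expect_equal(hive_patch_distance(list(x = 100 + shift, y = 0 + shift),
                                   north + shift),
               hive_patch_distance(s0, north))
})

test_that("alternative-fields scenario treats fields Bernoulli(p)", {
  ls <- toy_landscape()
  r1 <- scenario_alternative_fields(ls, p = 1, seed = 3)
  expect_true(all(r1$patches$treated[r1$patches$category == "target-field"]))
  r0 <- scenario_alternative_fields(ls, p = 0, seed = 3)
  expect_false(any(r0$patches$treated))
  # seeded reproducibility
  expect_identical(scenario_alternative_fields(ls, 0.5, seed = 8)$patches$treated,
                   scenario_alternative_fields(ls, 0.5, seed = 8)$patches$treated)
  # treated count across seeds behaves like a binomial sample
  big <- generate_synthetic_landscape(seed = 1, extent = 4000, n_target = 30,
                                      n_alt = 0, n_offfield = 0)
  counts <- vapply(1:200, function(s)
    sum(scenario_alternative_fields(big, 0.3, seed = s)$patches$treated),
    numeric(1))
  expect_lt(abs(mean(counts) - 30 * 0.3), 4 * sqrt(30 * 0.3 * 0.7 / 200))
  # sugar multiplier rescales the alternative crop's energy density
  rs <- scenario_alternative_fields(ls, 0.5, sugar_mult = 1.2, seed = 1)
  # toy landscape has no alternative fields; use a synthetic one
  ls2 <- generate_synthetic_landscape(seed = 5, extent = 2000, n_target = 3,
                                      n_alt = 2, n_offfield = 0)
  rs2 <- scenario_alternative_fields(ls2, 0.5, sugar_mult = 1.2, seed = 1)
  alt <- rs2$patches$category == "alternative-field"
  expect_equal(unique(rs2$patches$e_R[alt]), 8.084 * 1.2)
  expect_false(any(rs2$patches$treated[alt]))
})

test_that("flower strips conserve field area exactly and follow p", {
  ls <- toy_landscape()
  orig <- sum(ls$patches$area[ls$patches$category == "target-field"])
  r <- scenario_flower_strips(ls, p = 1, w = 2, seed = 1)
  flds <- r$patches$category == "target-field"
  strips <- r$patches$category == "flower-strip"
  expect_equal(sum(r$patches$A[flds]) + sum(r$patches$A[strips]), orig)
  # square 400x400 field, w = 2: four strips of 800 m2 each
  t1s <- strips & grepl("^t1_", r$patches$id)
  expect_equal(sum(t1s), 4)
  expect_equal(unique(r$patches$A[t1s]), 2 * (4 * 400) / 4)
  expect_equal(r$patches$A[r$patches$id == "t1"], 400 * 400 - 4 * 800)
  # p = 0 adds nothing
  r0 <- scenario_flower_strips(ls, p = 0, w = 2, seed = 1)
  expect_equal(sum(r0$patches$category == "flower-strip"), 0)
  expect_equal(sum(r0$patches$A[r0$patches$category == "target-field"]), orig)
  # expected strips per field = 4p across seeds
  cnt <- vapply(1:200, function(s)
    sum(scenario_flower_strips(ls, 0.5, w = 1, seed = s)$patches$category ==
          "flower-strip"), numeric(1))
  expect_lt(abs(mean(cnt) - 2 * 4 * 0.5), 4 * sqrt(8 * 0.25 / 200))
  # absurd width rejected
  expect_error(scenario_flower_strips(ls, 1, w = 200, seed = 1), "exceed")
})

test_that("off-field scenario selects clover patches Bernoulli(p)", {
  ls <- toy_landscape()
  r0 <- scenario_off_field(ls, p = 0, seed = 2)
  expect_equal(sum(r0$patches$category == "off-field"), 0)
  r1 <- scenario_off_field(ls, p = 1, quality_mult = 1.5, seed = 2)
  off <- r1$patches$category == "off-field"
  expect_equal(sum(off), 2)
  expect_equal(unique(r1$patches$F0[off]), 2808 * 1.5)
  # quality 1 makes off-field patches identical in resource terms to strips
  rs <- scenario_flower_strips(ls, 1, w = 2, seed = 2)
  rq <- scenario_off_field(ls, 1, quality_mult = 1, seed = 2)
  scol <- c("F0", "g", "a", "h", "e_R", "sugar_share", "r")
  expect_equal(unique(rq$patches[rq$patches$category == "off-field", scol]),
               unique(rs$patches[rs$patches$category == "flower-strip", scol]),
               ignore_attr = TRUE)
  # selection count is binomial across seeds
  big <- generate_synthetic_landscape(seed = 3, extent = 3000, n_target = 2,
                                      n_alt = 0, n_offfield = 100)
  cnt <- vapply(1:150, function(s)
    sum(scenario_off_field(big, 0.2, seed = s)$patches$category == "off-field"),
    numeric(1))
  expect_lt(abs(mean(cnt) - 20), 4 * sqrt(100 * 0.2 * 0.8 / 150))
})
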