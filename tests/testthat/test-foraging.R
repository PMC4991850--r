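bee <- bee_parameters()
osr <- resource_preset("osr")
clv <- resource_preset("clover")

test_that("trips per hour derive from trip and unload times", {
  expect_equal(trips_per_hour(1000, 264, osr, bee), 3600 / (682.2266 + 300),
               tolerance = 1e-6)
  D <- seq(100, 1900, by = 200)
  expect_true(all(diff(trips_per_hour(D, 264, osr, bee)) < 0))
})

test_that("hourly deliveries follow n (gamma - E_c/e_R) b", {
  d0 <- hourly_delivery(0, 500, 264, osr, bee)
  expect_equal(d0$nectar, 0)
  # at the hive doorstep nothing is consumed on the return
  dd <- hourly_delivery(10, 0, 264, osr, bee)
  expect_equal(dd$nectar, 10 * bee$gamma * dd$b)
  d <- hourly_delivery(100, 1000, 264, osr, bee)
  expect_equal(d$nectar, 11096.28, tolerance = 1e-4)
  # sugar is the energy-based form of the same flux
  expect_equal(d$sugar, d$nectar * osr$e_R / bee$e_sugar, tolerance = 1e-10)
  # infeasible patch (beyond threshold) delivers nothing
  far <- hourly_delivery(100, 264, 264, osr, bee_parameters(D_max = 1e6))
  expect_gt(far$nectar, 0)
  beyond <- hourly_delivery(100, 1e7, 264, osr, bee_parameters(D_max = 1e8))
  expect_equal(beyond$nectar, 0)
})

test_that("flower-density update applies depletion, competition and renewal", {
  p <- patch("p", osr, A = 1e4, D = 500)
  expect_equal(update_flower_density(p, 0, 0, bee, Z = 0), p$F0)
  # full renewal restores F0
  p_dep <- p; p_dep$F <- 100
  p_r1 <- p_dep
  p_r1$r <- 1
  expect_equal(update_flower_density(p_r1, 0, 0, bee), p$F0)
  # one trip removes exactly gamma/g flowers: dF * A = n b gamma / g
  n <- 50; b <- 3
  Fnew <- update_flower_density(p, n, b, bee)
  expect_equal((p$F0 - Fnew) * p$A, n * b * bee$gamma / osr$g)
  # competitors deplete through the functional response
  f <- visit_rate(p$F, p)
  expect_equal(update_flower_density(p, 0, 0, bee, Z = 2), p$F0 - 2 * f)
  # clamped at zero
  tiny <- patch("t", osr, A = 1, D = 10)
  expect_equal(update_flower_density(tiny, 1000, 10, bee), 0)
})

test_that("feasibility gate combines anthesis, distance, depletion and balance", {
  morning <- resource_type("osr_am", g = osr$g, F0 = osr$F0,
                           sugar_share = osr$sugar_share, a = osr$a,
                           h = osr$h, anthesis = 1:4)
  pt <- rbind(patch("near", osr, A = 1e4, D = 500),
              patch("far", osr, A = 1e4, D = 2500),     # beyond D_max
              patch("am", morning, A = 1e4, D = 500),
              patch("bare", osr, A = 1e4, D = 500, F = 0))
  f1 <- feasible_patches(pt, 1, bee)
  expect_equal(f1, c(TRUE, FALSE, TRUE, FALSE))
  f6 <- feasible_patches(pt, 6, bee)   # morning resource closed by now
  expect_equal(f6, c(TRUE, FALSE, FALSE, FALSE))
  # within D_max but beyond the energetic threshold distance
  wide <- bee_parameters(D_max = 2e4)
  pt2 <- patch("beyond", osr, A = 1e4, D = threshold_distance(osr, wide) + 1)
  expect_false(feasible_patches(pt2, 1, wide))
})

test_that("SO model sends every forager to the NEE argmax each hour", {
  # two identical big patches: nearer one exploited exclusively
  pt <- rbind(patch("a", osr, A = 1e6, D = 800),
              patch("b", osr, A = 1e6, D = 300))
  day <- simulate_day(pt, bee, sim_config("so"))
  expect_equal(day$exploited, "b")
  expect_equal(nrow(day$hourly), bee$day_hours)
  # single patch adjacent to the hive: exploited all 10 hours
  one <- patch("only", osr, A = 1e6, D = 12.5, treated = TRUE, C = 1)
  d1 <- simulate_day(one, bee, sim_config("so"))
  expect_equal(unique(d1$hourly$id), "only")
  expect_equal(d1$hourly$hour, 1:10)
})

test_that("SO switches patches when a small patch depletes", {
  pt <- rbind(patch("tiny", clv, A = 30, D = 200),
              patch("big", osr, A = 1e6, D = 400))
  day <- simulate_day(pt, bee, sim_config("so"))
  expect_gt(length(day$exploited), 1)
  expect_true("tiny" %in% day$hourly$id[1])  # starts on the better patch
})

test_that("SO selection matches the brute-force hourly argmax", {
  for (seed in 1:12) {
    n <- sample(3:20, 1)
    pt <- rand_patch_table(n, seed = seed)
    day <- simulate_day(pt, bee, sim_config("so"))
    want <- oracle_so_day(pt, bee)
    got <- rep(NA_character_, bee$day_hours)
    got[day$hourly$hour] <- day$hourly$id
    expect_equal(got, want)
  }
})

test_that("RL with one feasible patch converges to the SO totals", {
  one <- patch("only", osr, A = 1e6, D = 500)
  so <- simulate_day(one, bee, sim_config("so"))
  rl <- simulate_day(one, bee, sim_config("rl", rho = 1, epsilon = 0.01))
  expect_equal(sum(rl$hourly$sugar), sum(so$hourly$sugar), tolerance = 1e-10)
})

test_that("RL conserves foragers every hour", {
  for (seed in 1:6) {
    pt <- rand_patch_table(12, seed = 100 + seed)
    rl <- simulate_day(pt, bee, sim_config("rl", seed = seed))
    tot <- rl$rl_trace$employed + rl$rl_trace$unemployed
    expect_equal(tot, rep(bee$n_foragers, bee$day_hours), tolerance = 1e-9)
  }
  # also in the integer-sampling mode
  pt <- rand_patch_table(8, seed = 77)
  rl <- simulate_day(pt, bee, sim_config("rl", seed = 9, stochastic = TRUE))
  expect_equal(rl$rl_trace$employed + rl$rl_trace$unemployed,
               rep(bee$n_foragers, bee$day_hours), tolerance = 1e-9)
})

test_that("RL spreads effort over more patches than SO on many small patches", {
  set.seed(5)
  n <- 60
  rows <- lapply(seq_len(n), function(i)
    patch(sprintf("c%02d", i), clv, A = 500, D = runif(1, 150, 1200)))
  pt <- rbind(do.call(rbind, rows),
              patch("osr", osr, A = 1e5, D = 12.5, treated = TRUE, C = 1))
  so <- simulate_day(pt, bee, sim_config("so"))
  rl <- simulate_day(pt, bee, sim_config("rl"))
  expect_gt(patches_for_sugar_fraction(rl, 0.9),
            length(so$exploited))
})

test_that("flower mass balance holds over an unclamped SO day", {
  pt <- patch("f", osr, A = 5e4, D = 600)
  day <- simulate_day(pt, bee, sim_config("so"))
  removed_flowers <- sum(day$hourly$n * day$hourly$b) * bee$gamma / osr$g
  expect_equal((osr$F0 - day$final_F) * pt$A, removed_flowers,
               tolerance = 1e-9)
  # depletion monotone with r = 0, Z = 0
  expect_true(all(diff(day$hourly$F) <= 0))
})

test_that("patch count for a sugar fraction matches a brute-force scan", {
  one <- patch("only", osr, A = 1e6, D = 500)
  d1 <- simulate_day(one, bee, sim_config("so"))
  expect_equal(patches_for_sugar_fraction(d1, 0.9), 1L)
  # equal deliveries: need ceiling(q * n) patches
  fake <- d1
  fake$patch_totals <- data.frame(id = letters[1:4], nectar = 1, sugar = 10)
  expect_equal(patches_for_sugar_fraction(fake, 0.9), 4L)
  expect_equal(patches_for_sugar_fraction(fake, 0.5), 2L)
  # randomized: smallest top-k prefix covering the fraction
  set.seed(31)
  for (i in 1:10) {
    s <- runif(sample(2:10, 1), 0, 100)
    fake$patch_totals <- data.frame(id = seq_along(s), nectar = s, sugar = s)
    q <- runif(1, 0.05, 1)
    sorted <- sort(s, decreasing = TRUE)
    want <- min(which(cumsum(sorted) >= q * sum(s) - 1e-9))
    expect_equal(patches_for_sugar_fraction(fake, q), want)
  }
  empty <- simulate_day(patch("far", osr, A = 1e4, D = 3000), bee,
                        sim_config("so"))
  expect_equal(patches_for_sugar_fraction(empty, 0.9), 0L)
})

test_that("days are deterministic given a seed and config", {
  pt <- rand_patch_table(15, seed = 3)
  a <- simulate_day(pt, bee, sim_config("rl", seed = 11, stochastic = TRUE))
  b <- simulate_day(pt, bee, sim_config("rl", seed = 11, stochastic = TRUE))
  expect_identical(a$hourly, b$hourly)
})
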