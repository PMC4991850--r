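# Independent oracle implementations: direct transcriptions of the closed
# forms and a brute-force replay of the hourly single-optimal loop. These
# deliberately share no code with the package internals.

# trip energetics written out longhand
oracle_ee <- function(D, F, g, a, e_R, bee) {
  bee$gamma * bee$e_F / (g * a * F) + 2 * (D / bee$v) * bee$e_F
}
oracle_nee <- function(D, F, g, a, e_R, bee) {
  ee <- oracle_ee(D, F, g, a, e_R, bee)
  (bee$gamma * e_R - ee) / ee
}

# brute-force replay of the SO day: per hour recompute NEE from scratch over
# all patches, pick the argmax (ties: nearer, then lexicographic id), apply
# the flower-density update longhand. Returns the per-hour selected id.
oracle_so_day <- function(pt, bee, Z = 0) {
  F <- pt$F
  sel <- character(bee$day_hours)
  for (hr in seq_len(bee$day_hours)) {
    ee <- bee$gamma * bee$e_F / (pt$g * pt$a * F) + 2 * (pt$D / bee$v) * bee$e_F
    bal <- bee$gamma * pt$e_R - ee
    ok <- F > 0 & pt$D <= bee$D_max & bal > 0
    if (!any(ok)) { sel[hr] <- NA_character_; next }
    neev <- bal / ee
    ord <- order(-ifelse(ok, neev, -Inf), pt$D, pt$id)
    best <- ord[1]
    sel[hr] <- pt$id[best]
    f <- pt$a[best] * F[best] / (1 + pt$a[best] * pt$h[best] * F[best])
    t_trip <- 2 * pt$D[best] / bee$v + bee$gamma / (f * pt$g[best])
    b <- bee$dt / (t_trip + bee$t_UD)
    F[best] <- F[best] - bee$n_foragers * bee$gamma * b / (pt$g[best] * pt$A[best])
    f_all <- pt$a * F / (1 + pt$a * pt$h * F)
    F <- F - f_all * Z
    F <- F + pt$r * (pt$F0 - F)
    F <- pmin(pmax(F, 0), pt$F0)
  }
  sel
}

# random patch table on OSR/clover with jittered densities and sizes
rand_patch_table <- function(n, seed, D_range = c(50, 1900),
                             A_range = c(1e3, 1e5)) {
  set.seed(seed)
  rts <- list(resource_preset("osr"), resource_preset("clover"))
  rows <- lapply(seq_len(n), function(i) {
    rt <- rts[[1 + (i %% 2)]]
    p <- patch(sprintf("p%02d", i), rt,
               A = runif(1, A_range[1], A_range[2]),
               D = runif(1, D_range[1], D_range[2]),
               C = round(runif(1)), treated = runif(1) < 0.5)
    p$F <- p$F0 * runif(1, 0.3, 1)
    p
  })
  do.call(rbind, rows)
}

# n interchangeable target fields at a common distance from the hive
ring_patch_table <- function(n = 20, D = 500, A = 5e4, treated = rep(FALSE, n),
                             C_P = 1) {
  osr <- resource_preset("osr")
  rows <- lapply(seq_len(n), function(i)
    patch(sprintf("r%02d", i), osr, A = A, D = D,
          C = if (treated[i]) C_P else 0, treated = treated[i]))
  do.call(rbind, rows)
}

# tiny manually-built landscape: square target fields + off-field slivers
toy_landscape <- function(extent = 1500, res = 25) {
  mk <- function(x0, y0, w, h) cbind(x = c(x0, x0 + w, x0 + w, x0),
                                     y = c(y0, y0, y0 + h, y0 + h))
  patches <- data.frame(
    id = c("t1", "t2", "o1", "o2"),
    category = c("target-field", "target-field", "off-field", "off-field"),
    resource = c("osr", "osr", "clover", "clover"),
    stringsAsFactors = FALSE)
  patches$geometry <- list(mk(100, 100, 400, 400), mk(900, 900, 400, 300),
                           mk(550, 100, 200, 5), mk(100, 700, 300, 4))
  landscape(patches,
            list(osr = resource_preset("osr"),
                 clover = resource_preset("clover")),
            extent = c(0, 0, extent, extent), resolution = res)
}
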