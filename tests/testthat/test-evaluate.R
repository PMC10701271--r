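test_that("DVH of a uniform dose is a step function", {
  sph <- sphere_dose_case(value = 30)
  curve <- dvh(sph$dose, sph$mask, bin_width = 0.5)
  expect_equal(curve$volume_fraction[curve$dose_gy <= 30],
               rep(1, sum(curve$dose_gy <= 30)))
  expect_equal(curve$volume_fraction[curve$dose_gy > 30],
               rep(0, sum(curve$dose_gy > 30)))
  expect_true(all(diff(curve$volume_fraction) <= 0))
  expect_equal(curve$volume_fraction[1], 1)
  expect_error(dvh(sph$dose, grid_like(sph$grid)), "empty")
})

test_that("DVH of a linear ramp is linear with D50 at the midpoint", {
  n <- 10
  g <- voxel_grid(array(rep(seq(0, 40, length.out = n), each = 1),
                        c(n, 1, 1)), c(1, 1, 1), c(0, 0, 0))
  mask <- grid_like(g, array(1, c(n, 1, 1)))
  mid <- dose_at_volume(g, mask, 50)
  expect_equal(mid, 20, tolerance = 1e-9)
  curve <- dvh(g, mask, bin_width = 40 / (n - 1))
  inner <- curve$volume_fraction[curve$dose_gy <= 40]
  expect_equal(diff(inner), rep(-1 / n, length(inner) - 1),
               tolerance = 1e-9)
})

test_that("dose-at-volume agrees with the sort oracle", {
  g <- voxel_grid(array(1:100, c(100, 1, 1)), c(1, 1, 1), c(0, 0, 0))
  mask <- grid_like(g, array(1, c(100, 1, 1)))
  for (q in c(2, 50, 95, 98)) {
    expect_equal(dose_at_volume(g, mask, q),
                 dose_at_volume_brute(1:100, q), tolerance = 1e-12)
  }
  expect_equal(dose_at_volume(g, mask, 100), 1)  # q = 100 -> minimum
  set.seed(12)
  vals <- runif(257, 0, 40)
  g2 <- voxel_grid(array(vals, c(257, 1, 1)), c(1, 1, 1), c(0, 0, 0))
  m2 <- grid_like(g2, array(1, c(257, 1, 1)))
  for (q in c(2, 37.5, 95))
    expect_equal(dose_at_volume(g2, m2, q), dose_at_volume_brute(vals, q),
                 tolerance = 1e-12)
  # uniform dose: every quantile is the value itself
  sph <- sphere_dose_case(30)
  expect_equal(dose_at_volume(sph$dose, sph$mask, 95), 30)
})

test_that("conformity index follows its defining ratio", {
  sph <- sphere_dose_case(value = 30)
  expect_equal(conformity_index(sph$dose, sph$mask, 30), 1)
  # prescription isodose covering the target with twice its volume
  n_pgtv <- sum(sph$mask$data)
  big <- grid_like(sph$grid)
  ord <- order(distance_transform(sph$mask))
  big$data[ord[seq_len(2 * n_pgtv)]] <- 30
  expect_equal(conformity_index(big, sph$mask, 30),
               n_pgtv^2 / (n_pgtv * 2 * n_pgtv))
  # disjoint isodose region
  far <- grid_like(sph$grid)
  far$data[1:5, 1, 1] <- 30
  expect_equal(conformity_index(far, sph$mask, 30), 0)
  expect_equal(conformity_index(grid_like(sph$grid), sph$mask, 30), 0)
})

test_that("conformity index stays within [0, 1] on random doses", {
  sph <- sphere_dose_case()
  set.seed(13)
  for (i in 1:20) {
    d <- grid_like(sph$grid,
                   array(runif(length(sph$grid$data), 0, 40),
                         dim(sph$grid$data)))
    ci <- conformity_index(d, sph$mask, 30)
    expect_gte(ci, 0); expect_lte(ci, 1)
  }
})

test_that("homogeneity index is zero for uniform dose, scale invariant", {
  sph <- sphere_dose_case(value = 30)
  expect_equal(homogeneity_index(sph$dose, sph$mask), 0)
  set.seed(14)
  d <- grid_like(sph$grid, array(runif(length(sph$grid$data), 10, 40),
                                 dim(sph$grid$data)))
  h1 <- homogeneity_index(d, sph$mask)
  d2 <- grid_like(sph$grid, 3.7 * d$data)
  expect_equal(homogeneity_index(d2, sph$mask), h1, tolerance = 1e-12)
  expect_error(homogeneity_index(grid_like(sph$grid), sph$mask), "zero")
})

test_that("the D-metric ordering chain holds on random doses", {
  sph <- sphere_dose_case()
  set.seed(15)
  for (i in 1:10) {
    d <- grid_like(sph$grid, array(runif(length(sph$grid$data), 0, 40),
                                   dim(sph$grid$data)))
    d98 <- dose_at_volume(d, sph$mask, 98)
    d95 <- dose_at_volume(d, sph$mask, 95)
    d50 <- dose_at_volume(d, sph$mask, 50)
    d2 <- dose_at_volume(d, sph$mask, 2)
    expect_true(d98 <= d95 && d95 <= d50 && d50 <= d2)
    expect_lte(d2, max(d$data[sph$mask$data != 0]))
  }
})

test_that("R50 counts the half-prescription isodose volume", {
  sph <- sphere_dose_case(value = 30)
  n_pgtv <- sum(sph$mask$data)
  d <- grid_like(sph$grid)
  ord <- order(distance_transform(sph$mask))
  d$data[ord[seq_len(2 * n_pgtv)]] <- 16   # >= 15 Gy = 0.5 * 30
  expect_equal(r50(d, sph$mask, 30), 2)
  expect_equal(r50(grid_like(sph$grid, array(10, dim(sph$grid$data))),
                   sph$mask, 30), 0)
})

test_that("D2cm reads the dose on the 20 mm shell", {
  sph <- sphere_dose_case(radius = 10, n = 40, spacing = 2.5)
  dist <- distance_transform(sph$mask)
  # dose zero beyond 15 mm -> nothing reaches the shell
  d <- grid_like(sph$grid, array(30 * (dist < 15), dim(dist)))
  expect_equal(d2cm(d, sph$mask), 0)
  # radially symmetric analytic fall-off: D2cm = profile at 20 mm
  d2 <- grid_like(sph$grid, array(30 * 0.5^(dist / 10), dim(dist)))
  shell_min <- min(dist[dist >= 20])
  expect_equal(d2cm(d2, sph$mask), 30 * 0.5^(shell_min / 10),
               tolerance = 1e-9)
  # shell membership identical to the brute-force distance oracle
  small <- sphere_dose_case(radius = 8, n = 16, spacing = 5)
  bd <- edt_brute(small$mask$data, small$mask$spacing)
  dd <- distance_transform(small$mask)
  sel_pkg <- dd >= 20 & dd < 25
  sel_oracle <- bd >= 20 & bd < 25
  expect_identical(sel_pkg, sel_oracle)
  # target touching the border: shell missing -> instructive error
  tiny <- sphere_dose_case(radius = 10, n = 10, spacing = 2.5)
  expect_error(d2cm(tiny$dose, tiny$mask), "pad")
})

test_that("volume-at-dose percentages are exact counts", {
  sph <- sphere_dose_case(value = 20)
  expect_equal(volume_at_dose(sph$dose, sph$mask, 0), 100)
  expect_equal(volume_at_dose(sph$dose, sph$mask, 23), 0)
  n <- sum(sph$mask$data)
  d <- grid_like(sph$grid)
  in_mask <- which(sph$mask$data != 0)
  d$data[in_mask[seq_len(n %/% 2)]] <- 30
  d$data[in_mask[(n %/% 2 + 1):n]] <- 10
  expect_equal(volume_at_dose(d, sph$mask, 23), 100 * (n %/% 2) / n)
})

test_that("pointwise statistics match the naive loop", {
  sph <- sphere_dose_case(value = 30)
  s <- pointwise_stats(sph$dose, sph$dose)
  expect_equal(c(s$mean, s$sd, s$mae), c(0, 0, 0))
  offset <- grid_like(sph$grid, sph$dose$data + 3)
  s2 <- pointwise_stats(sph$dose, offset, rx = 30)
  expect_equal(s2$mean, -3)
  expect_equal(s2$sd, 0)
  expect_equal(s2$mae, 3)
  expect_equal(s2$mae_pct, 10)
  set.seed(16)
  g10 <- voxel_grid(array(0, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0))
  a <- grid_like(g10, array(runif(1000), c(10, 10, 10)))
  b <- grid_like(g10, array(runif(1000), c(10, 10, 10)))
  s3 <- pointwise_stats(a, b, rx = 30)
  delta <- numeric(0)
  for (i in seq_len(1000)) delta[i] <- a$data[i] - b$data[i]
  expect_equal(s3$mean, mean(delta), tolerance = 1e-12)
  expect_equal(s3$sd, sd(delta), tolerance = 1e-12)
  expect_equal(s3$mae, mean(abs(delta)), tolerance = 1e-12)
})

test_that("isodose Dice follows voxel-counted geometry", {
  sph10 <- sphere_dose_case(value = 30, radius = 10, n = 24)
  expect_equal(isodose_dsc(sph10$dose, sph10$dose, 0.9, rx = 30), 1)
  sph12 <- sphere_dose_case(value = 30, radius = 12, n = 24)
  v10 <- sum(sph10$dose$data >= 27)
  v12 <- sum(sph12$dose$data >= 27)
  expect_equal(isodose_dsc(sph10$dose, sph12$dose, 0.9, rx = 30),
               2 * v10 / (v10 + v12))  # nested spheres
  # disjoint high-dose regions
  a <- grid_like(sph10$grid); a$data[1:3, 1, 1] <- 30
  b <- grid_like(sph10$grid); b$data[10:12, 10, 10] <- 30
  expect_equal(isodose_dsc(a, b, 0.9, rx = 30), 0)
  expect_equal(isodose_dsc(grid_like(sph10$grid), grid_like(sph10$grid),
                           0.9, rx = 30), 1)  # both empty, by convention
})

test_that("panel comparison flags only real differences", {
  set.seed(17)
  a <- data.frame(d95 = rnorm(12, 30, 0.1), hi = rnorm(12, 0.2, 0.01))
  b <- a
  b$d95 <- a$d95 + 1 + rnorm(12, 0, 0.05)  # systematic shift -> significant
  b$hi <- a$hi + rnorm(12, 0, 1e-4)
  cmp <- compare_panels(a, b)
  expect_true(cmp$significant[cmp$metric == "d95"])
  expect_false(cmp$significant[cmp$metric == "hi"])
  s <- format_panel_summary(a)
  expect_match(s[["d95"]], "^[0-9.]+ ± [0-9.]+$")
})
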