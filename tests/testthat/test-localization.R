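test_that("ellipsoid volume ratios are analytic and correctly clipped", {
  g <- nucleus_ellipsoid(c(4, 4, 4))
  expect_equal(volume_ratio(c(0, 0, 0), g), 0)
  expect_equal(volume_ratio(c(4, 0, 0), g), 1)
  expect_equal(volume_ratio(c(2, 0, 0), g), 0.125)  # (1/2)^3

  ge <- nucleus_ellipsoid(c(5, 4, 1.5), center = c(1, 2, 3))
  expect_equal(volume_ratio(c(1, 2, 3), ge), 0)
  expect_equal(volume_ratio(c(6, 2, 3), ge), 1)
  expect_error(volume_ratio(c(7, 2, 3), ge), "outside")
  # marginally outside is clipped to the boundary
  expect_equal(volume_ratio(c(1 + 5 * (1 + 1e-8), 2, 3), ge, tol = 1e-6), 1)
})

test_that("volume ratio is invariant under rigid translation and uniform scaling", {
  set.seed(121)
  pts <- matrix(runif(30, -0.5, 0.5), ncol = 3) %*% diag(c(5, 4, 1.5))
  g0 <- nucleus_ellipsoid(c(5, 4, 1.5))
  r0 <- volume_ratio(pts, g0)
  shift <- c(10, -3, 7)
  g1 <- nucleus_ellipsoid(c(5, 4, 1.5), center = shift)
  expect_equal(volume_ratio(sweep(pts, 2, shift, `+`), g1), r0)
  g2 <- nucleus_ellipsoid(2.5 * c(5, 4, 1.5))
  expect_equal(volume_ratio(2.5 * pts, g2), r0)
})

test_that("zones split the unit ratio scale into equal-volume thirds", {
  expect_equal(assign_zone(c(0.2, 0.5, 0.9)), c(1L, 2L, 3L))
  expect_equal(assign_zone(c(0, 1 / 3, 2 / 3, 1)), c(1L, 2L, 3L, 3L))
  expect_error(assign_zone(1.2), "\\[0, 1\\]")

  g <- nucleus_ellipsoid(c(5, 4, 1.5))
  sp <- simulate_nuclei(radial_law(), 5000, g, 2, seed = 122)
  r <- volume_ratio(sp, g)
  s <- summarize_localization(r)
  n <- s$n
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(s$zones / n - 1 / 3) < 3 * se))
  expect_equal(sum(s$zones), n)
  expect_lt(abs(s$mean - 0.5), 3 * sqrt(1 / 12 / n))
})

test_that("localization summaries handle degenerate inputs", {
  s1 <- summarize_localization(rep(1, 10))
  expect_equal(s1$mean, 1)
  expect_equal(s1$sem, 0)
  expect_equal(unname(s1$zones), c(0, 0, 10))
  expect_warning(s_single <- summarize_localization(0.4), "single spot")
  expect_equal(s_single$sem, 0)
  expect_error(summarize_localization(numeric(0)), "at least one")
})

test_that("voxel-mask ratios converge to the ellipsoid law and honour anisotropy", {
  # sphere of radius 4.6 um in a 100^3 isotropic mask (0.1 um voxels)
  n <- 100; v <- 0.1
  centre <- (n / 2) * v
  ax <- seq_len(n) * v - v / 2
  arr <- array(FALSE, c(n, n, n))
  grid <- expand.grid(z = ax, y = ax, x = ax)
  arr[] <- (grid$x - centre)^2 + (grid$y - centre)^2 +
    (grid$z - centre)^2 <= 4.6^2
  gm <- nucleus_mask(arr, voxel_size = c(v, v, v))
  ge <- nucleus_ellipsoid(rep(4.6, 3), center = rep(centre, 3))

  sp <- simulate_nuclei(radial_law(), 300, ge, 1, seed = 123)
  discrepancy <- abs(volume_ratio(sp, gm) - volume_ratio(sp, ge))
  expect_lt(mean(discrepancy), 0.05)
  # the centre voxel is as deep as the voxelization allows
  expect_lt(volume_ratio(rep(centre, 3), gm), 1e-4)

  # anisotropic z spacing: same physical sphere, 0.48 um sections
  nz <- 21; vz <- 0.48
  cz <- (nz / 2) * vz
  azz <- seq_len(nz) * vz - vz / 2
  arr2 <- array(FALSE, c(nz, n, n))
  g2 <- expand.grid(z = azz, y = ax, x = ax)
  arr2[] <- (g2$x - centre)^2 + (g2$y - centre)^2 + (g2$z - cz)^2 <= 4.6^2
  gm2 <- nucleus_mask(arr2, voxel_size = c(v, v, vz))
  ge2 <- nucleus_ellipsoid(rep(4.6, 3), center = c(centre, centre, cz))
  sp2 <- simulate_nuclei(radial_law(), 200, ge2, 1, seed = 124)
  expect_lt(mean(abs(volume_ratio(sp2, gm2) - volume_ratio(sp2, ge2))),
            0.1)
})

test_that("lamin reference is 1 for ellipsoids and approaches 1 with mask resolution", {
  expect_identical(lamin_reference(nucleus_ellipsoid(c(5, 4, 1.5))), 1.0)

  sphere_mask <- function(n, radius_frac = 0.46) {
    v <- 0.1
    centre <- (n / 2) * v
    ax <- seq_len(n) * v - v / 2
    arr <- array(FALSE, c(n, n, n))
    grid <- expand.grid(z = ax, y = ax, x = ax)
    arr[] <- (grid$x - centre)^2 + (grid$y - centre)^2 +
      (grid$z - centre)^2 <= (radius_frac * n * v)^2
    nucleus_mask(arr, voxel_size = c(v, v, v))
  }
  g50 <- sphere_mask(50)
  ref50 <- lamin_reference(g50)
  expect_gt(ref50, 0.9)
  expect_lte(ref50, 1.0)
  ref25 <- lamin_reference(sphere_mask(25))
  expect_gt(ref50, ref25)  # finer voxels move the reference toward 1
})

test_that("timing-localization coupling is recovered and vanishes under shuffling", {
  d <- default_design()
  mus <- seq(0.8, 5.2, length.out = 9)
  g <- nucleus_ellipsoid(c(5, 4, 1.5))
  mean_ratios <- vapply(seq_along(mus), function(i) {
    law <- radial_law_mean(0.2 + 0.6 * mus[i] / d$s_length, 10)
    sp <- simulate_nuclei(law, 50, g, 1, seed = 1300 + i)
    mean(volume_ratio(sp, g))
  }, numeric(1))
  mrts <- vapply(mus, function(m)
    expected_mrt(arm_profile("a", m, 1), d), numeric(1))
  res <- correlate_timing_localization(mrts, mean_ratios)
  expect_gte(res$rho, 0.9)

  # monotone increasing means give rho = 1 by rank invariance
  expect_equal(correlate_timing_localization(sort(mrts),
                                             sort(mean_ratios))$rho, 1)

  # shuffled pairings should show no association most of the time
  set.seed(131)
  null_p <- replicate(60, {
    correlate_timing_localization(mrts, sample(mean_ratios))$p
  })
  expect_gte(mean(null_p > 0.05), 0.9)

  expect_error(correlate_timing_localization(mrts, mean_ratios[-1]),
               "same length")
})
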