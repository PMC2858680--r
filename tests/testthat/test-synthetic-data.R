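test_that("arm profile generation is seed-deterministic, seed-sensitive and in range", {
  d <- default_design()
  p1 <- make_arm_profiles(5, d, seed = 42)
  p2 <- make_arm_profiles(5, d, seed = 42)
  expect_identical(p1, p2)

  p3 <- make_arm_profiles(3, d, seed = 1)
  p4 <- make_arm_profiles(3, d, seed = 2)
  expect_false(identical(vapply(p3, `[[`, numeric(1), "mu"),
                         vapply(p4, `[[`, numeric(1), "mu")))

  p46 <- make_arm_profiles(46, d, seed = 7)
  mus <- vapply(p46, `[[`, numeric(1), "mu")
  expect_true(all(mus >= 0.5 & mus <= 5.5))

  expect_error(make_arm_profiles(0, d, seed = 1), "n_arms")
})

test_that("a near-point-mass profile detargets only in its own pulse", {
  d <- default_design()
  prof <- list(arm_profile("4q", mu = 2.3, sigma = 1e-9))
  ev <- simulate_redfish_events(prof, d, n_metaphases_per_pulse = 20,
                                copies_per_arm = 2, noise = noise_model(),
                                seed = 3)
  det <- ev[ev$status == "detargeted", ]
  expect_true(all(det$pulse_index == 3))
  expect_equal(sum(ev$pulse_index == 3 & ev$status == "detargeted"), 40)
})

test_that("per-pulse detargeting fractions match truncated-normal interval masses", {
  d <- default_design()
  prof <- list(arm_profile("a", mu = 3, sigma = 1))
  n_met <- 2500  # 10,000 telomere copies per pulse with 4 copies
  ev <- simulate_redfish_events(prof, d, n_metaphases_per_pulse = n_met,
                                copies_per_arm = 4, noise = noise_model(),
                                seed = 101)
  masses <- oracle_pulse_masses(3, 1, d)
  for (i in seq_len(d$n_pulses)) {
    sub <- ev[ev$pulse_index == i, ]
    n <- nrow(sub)
    frac <- mean(sub$status == "detargeted")
    se <- sqrt(masses[i] * (1 - masses[i]) / n)
    expect_lt(abs(frac - masses[i]), 3 * se + 1e-12)
  }
})

test_that("each telomere replicates in exactly one pulse of the tiling", {
  d <- default_design()
  prof <- make_arm_profiles(2, d, seed = 5)
  ev <- simulate_redfish_events(prof, d, 30, 2, noise_model(), seed = 6)
  # true detargeting indicator equals membership of true_time in the
  # observed pulse; summing indicators over the pulse tiling gives 1
  in_pulse <- vapply(seq_len(d$n_pulses), function(i)
    sum(ev$true_time > (i - 1) & ev$true_time <= i), numeric(1))
  expect_equal(sum(in_pulse), nrow(ev))
  expect_true(all(ev$true_time >= 0 & ev$true_time <= d$s_length))
})

test_that("event simulation honours the noise model and degenerate drop-out", {
  d <- default_design()
  prof <- list(arm_profile("a", mu = 3, sigma = 1))
  ev_all_drop <- simulate_redfish_events(prof, d, 10, 2,
    noise_model(p_unscorable = 1 - 1e-12), seed = 8)
  expect_true(all(ev_all_drop$status == "unscorable"))
  expect_equal(nrow(aggregate_counts(ev_all_drop, d)[
    aggregate_counts(ev_all_drop, d)$n_scored > 0, ]), 0)

  expect_error(simulate_redfish_events(
    list(arm_profile("a", mu = 3, sigma = 1, s_length = 10)),
    d, 10, 2, noise_model(), seed = 1), "outside")
})

test_that("intensity generation has exact noiseless limits and is deterministic", {
  d <- default_design()
  prof <- list(arm_profile("a", mu = 3, sigma = 1.2))
  ev <- simulate_redfish_events(prof, d, 30, 2, noise_model(), seed = 21)
  ints <- simulate_intensities(ev, snr = Inf, seed = 22)

  det <- ints[ints$status == "detargeted", ]
  rho1 <- det$red_s1 / (det$red_s1 + det$green_s1)
  rho2 <- det$red_s2 / (det$red_s2 + det$green_s2)
  expect_true(all((rho1 == 1 & rho2 == 0) | (rho1 == 0 & rho2 == 1)))

  mix <- ints[ints$status == "mixed", ]
  expect_equal(mix$red_s1 / (mix$red_s1 + mix$green_s1),
               rep(0.5, nrow(mix)))
  expect_equal(mix$red_s2 / (mix$red_s2 + mix$green_s2),
               rep(0.5, nrow(mix)))

  again <- simulate_intensities(ev, snr = Inf, seed = 22)
  expect_identical(ints, again)
  noisy1 <- simulate_intensities(ev, snr = 10, seed = 23)
  noisy2 <- simulate_intensities(ev, snr = 10, seed = 23)
  expect_identical(noisy1, noisy2)
})

test_that("uniform radial law yields uniform volume ratios; point mass sits on the boundary", {
  g <- nucleus_ellipsoid(c(5, 4, 1.5))
  sp <- simulate_nuclei(radial_law(), n_nuclei = 5000, geometry = g,
                        spots_per_nucleus = 2, seed = 31)
  expect_equal(nrow(sp), 10000)
  r <- volume_ratio(sp, g)
  ks <- suppressWarnings(stats::ks.test(r, stats::punif))$statistic
  expect_lt(as.numeric(ks), 1.628 / sqrt(length(r)))  # 1% critical value

  boundary <- simulate_nuclei(radial_law("point", location = 1),
                              n_nuclei = 50, geometry = g,
                              spots_per_nucleus = 2, seed = 32)
  expect_equal(nrow(boundary), 100)
  expect_equal(volume_ratio(boundary, g), rep(1, 100))

  expect_error(radial_law("beta", shape1 = -1), "shape1")
})

test_that("qfish intensity generator matches the requested coefficient of variation", {
  eq <- simulate_qfish(200, cv = 0, seed = 41)
  expect_equal(length(unique(eq$intensity)), 1L)

  big <- simulate_qfish(20000, cv = 0.5, seed = 42)
  cv_hat <- stats::sd(big$intensity) / mean(big$intensity)
  expect_lt(abs(cv_hat - 0.5) / 0.5, 0.1)

  a <- simulate_qfish(100, cv = 0.3, seed = 43)
  b <- simulate_qfish(100, cv = 0.3, seed = 43)
  expect_identical(a, b)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_qfish(10, cv = 0.2, seed = 1))
  invisible(make_arm_profiles(3, default_design(), seed = 2))
  expect_identical(.Random.seed, before)
})
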