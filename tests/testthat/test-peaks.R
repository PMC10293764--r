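# Peak model: noise filtering, gap clustering, centroid and per-peak
# confidence-interval estimation.

test_that("filter_noise keeps points at or above the threshold, order kept", {
  pts <- tibble::tibble(mz = c(100, 101), intensity = c(5, 50))
  expect_identical(filter_noise(pts, 0), pts)
  expect_identical(filter_noise(pts, 10)$mz, 101)
  sim <- simulate_spectrum(simulation_spec(
    "C6NH6+", abundance = 1000, sigma_ppm = 3, points_per_peak = 10,
    noise_points = 200, noise_intensity = c(0, 5), seed = 42
  ))
  kept <- filter_noise(sim, 6)
  expect_false(any(kept$is_noise))
  expect_equal(sum(!sim$is_noise & sim$intensity >= 6), nrow(kept))
})

test_that("cluster_points splits on relative m/z gaps", {
  one <- cluster_points(tibble::tibble(mz = 100, intensity = 1), 10)
  expect_identical(one$cluster, 1L)
  two <- tibble::tibble(mz = c(100.0000, 100.0005), intensity = 1)
  expect_identical(cluster_points(two, 20)$cluster, c(1L, 1L)) # 5 ppm < 20
  expect_identical(cluster_points(two, 2)$cluster, c(1L, 2L))  # 5 ppm > 2
  expect_error(cluster_points(tibble::tibble(mz = c(2, 1), intensity = 1), 10),
               "sorted")
})

test_that("clusters are disjoint maximal runs covering the input", {
  sim <- simulate_spectrum(simulation_spec(
    sulfa_fragments, sigma_ppm = 3, points_per_peak = 8, seed = 9
  ))
  cl <- cluster_points(sim, 10)
  expect_equal(nrow(cl), nrow(sim))
  expect_true(all(diff(cl$cluster) %in% c(0L, 1L))) # contiguous runs
  # within-cluster gaps all <= threshold; boundary gaps all > threshold
  gaps <- diff(cl$mz)
  thr <- 10 * head(cl$mz, -1) / 1e6
  same <- diff(cl$cluster) == 0L
  expect_true(all(gaps[same] <= thr[same]))
  expect_true(all(gaps[!same] > thr[!same]))
})

test_that("estimate_peak matches the closed-form t-interval", {
  cl <- tibble::tibble(mz = c(100.0000, 100.0001, 100.0002),
                       intensity = c(10, 20, 10))
  pk <- estimate_peak(cl)
  expect_equal(pk$measured_mz, 100.0001)
  # independent hand computation of the 95% t-interval of the mean
  half <- qt(0.975, df = 2) * sd(cl$mz) / sqrt(3)
  expect_equal(pk$ci_ppm, half / 100.0001 * 1e6)
  expect_equal(pk$n_points, 3L)
  expect_equal(pk$relative_intensity_pct, 100)
  # single point: undefined CI, not zero
  lone <- estimate_peak(tibble::tibble(mz = 100, intensity = 1))
  expect_true(is.na(lone$ci_ppm))
})

test_that("Shapiro-Wilk p-values behave on normal clusters", {
  ps <- vapply(1:20, function(seed) {
    sim <- simulate_spectrum(simulation_spec(
      "C10SO3N3H12+", sigma_ppm = 5, points_per_peak = 1000, seed = seed
    ))
    estimate_peak(sim)$shapiro_p
  }, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gte(mean(ps > 0.05), 0.9)
  # degenerate cluster: all m/z equal -> no test
  same <- tibble::tibble(mz = rep(100, 5), intensity = 1)
  expect_true(is.na(estimate_peak(same)$shapiro_p))
})

test_that("relative intensities sum to 100 only when nothing is discarded", {
  sim <- simulate_spectrum(simulation_spec(
    sulfa_fragments, sigma_ppm = 3, points_per_peak = 8,
    noise_points = 100, noise_intensity = c(0, 2), seed = 21
  ))
  all_kept <- pick_peaks(sim, noise_threshold = 0, min_points = 1,
                         intensity_floor_pct = 0)
  expect_equal(sum(all_kept$relative_intensity_pct), 100, tolerance = 1e-9)
  filtered <- pick_peaks(sim, noise_threshold = 3)
  expect_lt(sum(filtered$relative_intensity_pct), 100)
})

test_that("the confidence interval shrinks as 1/sqrt(n)", {
  mean_ci <- vapply(c(4, 16, 64, 256), function(n) {
    mean(vapply(1:40, function(rep) {
      sim <- simulate_spectrum(simulation_spec(
        "C6NH6+", sigma_ppm = 5, points_per_peak = n, seed = 1000 * n + rep
      ))
      estimate_peak(sim)$ci_ppm
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ci) < 0))
  # quadrupling n should roughly halve the CI (sampling tolerance)
  ratios <- mean_ci[-length(mean_ci)] / mean_ci[-1]
  expect_true(all(ratios > 1.5 & ratios < 3.5))
})

test_that("centroids recover the true m/z within 1 ppm at sigma 5 ppm, n >= 50", {
  for (seed in 1:10) {
    sim <- simulate_spectrum(simulation_spec(
      "C10SO3N3H12+", sigma_ppm = 5, points_per_peak = 64, seed = seed
    ))
    pk <- estimate_peak(sim)
    expect_lt(abs(pk$measured_mz - ion_mz("C10SO3N3H12+")) /
                pk$measured_mz * 1e6, 1)
  }
})

test_that("an 8-point precursor cluster reproduces the reported CI magnitude", {
  # reported precursor row: CI 8 ppm from 8 data points; with n = 8 the
  # t-interval half-width is 2.36 * sigma / sqrt(8), so sigma ~ 9.6 ppm
  cis <- vapply(1:20, function(seed) {
    sim <- simulate_spectrum(simulation_spec(
      "C10SO3N3H12+", sigma_ppm = 9.6, points_per_peak = 8, seed = seed
    ))
    pk <- estimate_peak(sim)
    expect_identical(pk$n_points, 8L)
    pk$ci_ppm
  }, numeric(1))
  expect_gt(mean(cis), 4)
  expect_lt(mean(cis), 16)
})
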