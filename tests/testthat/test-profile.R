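test_that("two constant-force replicas give mean 4, SD sqrt(2) per bin", {
  z <- seq(0, 2, by = 0.01)
  tr3 <- make_traj(z, z, z, rep(3, length(z)), replica_id = 1L)
  tr5 <- make_traj(z, z, z, rep(5, length(z)), replica_id = 2L)
  prof <- mean_force_profile(replica_set(list(tr3, tr5)), bin_width = 0.5)
  expect_true(all(abs(prof$mean_force_magnitude - 4) < 1e-12))
  expect_true(all(abs(prof$sd_force - sqrt(2)) < 1e-12))
  expect_true(all(prof$n_per_bin == 2L))
})

test_that("profile preconditions: replicas and bin width", {
  z <- seq(0, 1, by = 0.1)
  tr <- make_traj(z, z, z, rep(1, length(z)))
  expect_error(mean_force_profile(replica_set(list(tr)), 0.2), ">= 2 replicas")
  two <- replica_set(list(tr, make_traj(z, z, z, rep(2, length(z)),
                                        replica_id = 2L)))
  expect_error(mean_force_profile(two, 0), "bin_width")
})

test_that("low-temperature flat pulls plateau at gamma*v", {
  cfg <- pull_config(spring_k = 1000, drag_gamma = 50, pull_rate_v = 0.05,
                     dt = 0.002, total_time_ts = 50, temperature_T = 1e-6,
                     potential = binding_potential("flat"),
                     n_replicas = 2L, seed = 31L, equilibration_time = 1)
  prof <- mean_force_profile(simulate_replicas(cfg), bin_width = 0.25)
  plateau <- prof$mean_force_magnitude[prof$bin_centers > 1]
  expect_equal(mean(plateau), 50 * 0.05, tolerance = 0.1)
})

test_that("error-bar crossing reproduces the constructed linear example", {
  x <- 1:12
  a <- force_profile(x, 5 - 0.5 * x, rep(0.5, 12), bin_width = 1)
  b <- force_profile(x, rep(1, 12), rep(0.5, 12), bin_width = 1)
  out <- errorbar_crossing(a, b, m_consecutive = 1)
  expect_identical(out$crossing, 6)
  expect_identical(out$cutoff, 12)
  # identical profiles overlap from the first bin
  same <- errorbar_crossing(a, a, m_consecutive = 1)
  expect_identical(same$crossing, 1)
  # disjoint profiles never converge
  hi <- force_profile(x, rep(100, 12), rep(0.5, 12), bin_width = 1)
  expect_error(errorbar_crossing(hi, b), "never overlap")
})

test_that("sustained overlap is required: single-bin flukes are skipped", {
  x <- 1:10
  # overlaps at bin 3 only, then from bin 6 onward
  mean_a <- c(10, 10, 1, 10, 10, 1, 1, 1, 1, 1)
  a <- force_profile(x, mean_a, rep(0.5, 10), bin_width = 1)
  b <- force_profile(x, rep(1, 10), rep(0.5, 10), bin_width = 1)
  out <- errorbar_crossing(a, b, m_consecutive = 3)
  expect_identical(out$crossing, 6)
})

test_that("halving the bin width moves the crossing by at most one bin", {
  f_mean <- function(x) 4 * exp(-x) + 1
  coarse <- force_profile(seq(0.5, 11.5, by = 1), f_mean(seq(0.5, 11.5, 1)),
                          rep(0.4, 12), bin_width = 1)
  base <- force_profile(seq(0.5, 11.5, by = 1), rep(1, 12), rep(0.4, 12),
                        bin_width = 1)
  fine_x <- seq(0.25, 11.75, by = 0.5)
  fine <- force_profile(fine_x, f_mean(fine_x), rep(0.4, length(fine_x)),
                        bin_width = 0.5)
  base_f <- force_profile(fine_x, rep(1, length(fine_x)),
                          rep(0.4, length(fine_x)), bin_width = 0.5)
  c1 <- errorbar_crossing(coarse, base, m_consecutive = 3)$crossing
  c2 <- errorbar_crossing(fine, base_f, m_consecutive = 3)$crossing
  expect_lte(abs(c1 - c2), 1)
})

test_that("region partition: fraction arithmetic and edge cases", {
  cfg <- tiny_well_config(pull_rate_v = 0.25, n_replicas = 2L) # travel 5
  series <- lapply(simulate_replicas(cfg)$trajectories, accumulate_work)
  part <- partition_work(series, 1.47, 5)
  expect_equal(part$interior_fraction, 0.294, tolerance = 1e-12)
  terminal <- max(series[[1]]$pull_coordinate)
  full <- partition_work(series, terminal, terminal)
  expect_identical(full$interior_fraction, 1)
  expect_equal(full$interior_work,
               mean(vapply(series, function(s) work_at(s, terminal),
                           numeric(1))), tolerance = 1e-12)
  none <- partition_work(series, 0, 5)
  expect_identical(none$interior_fraction, 0)
  expect_identical(none$interior_work, 0)
  expect_error(partition_work(series, 6, 5), "exceed")
  # interior + exterior segment = terminal work (additivity)
  w_b <- vapply(series, function(s) work_at(s, 1.47), numeric(1))
  w_t <- vapply(series, function(s) work_at(s, terminal), numeric(1))
  expect_equal(part$interior_work + mean(w_t - w_b), mean(w_t),
               tolerance = 1e-10)
})

test_that("work histograms: separation statistics and count conservation", {
  set.seed(14)
  sb <- work_sample(stats::rnorm(30, 10, 1), temperature_T = 1)
  sv <- work_sample(stats::rnorm(30, 2, 1), temperature_T = 1)
  h <- work_histogram_summary(sb, sv, n_bins = 15)
  expect_identical(sum(h$counts["bound", ]), 30L)
  expect_identical(sum(h$counts["viscous", ]), 30L)
  # populations 8 SDs apart: smd ~ 8, Gaussian overlap below 1%
  expect_gt(h$standardized_mean_difference, 6.5)
  expect_lt(h$standardized_mean_difference, 9.5)
  expect_lt(h$overlap_coefficient, 0.01)
  # identical samples: no separation, full overlap
  h0 <- work_histogram_summary(sb, sb, n_bins = 10)
  expect_identical(h0$standardized_mean_difference, 0)
  expect_equal(h0$overlap_coefficient, 1, tolerance = 1e-6)
  expect_error(work_histogram_summary(sb, sv, n_bins = 1), "n_bins")
})
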