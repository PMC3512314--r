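test_that("sample count is floor(ts/dt) + 1", {
  cfg <- pull_config(spring_k = 1, drag_gamma = 50, dt = 0.5,
                     total_time_ts = 500, pull_rate_v = 0.01,
                     potential = binding_potential("flat"),
                     equilibration_time = 0)
  tr <- simulate_pull(cfg, 1L)
  expect_identical(length(tr$time), 1001L)
  expect_identical(nrow(tr$force), 1001L)
})

test_that("identical (config, seed) pairs reproduce bit-identical trajectories", {
  cfg <- tiny_well_config()
  a <- simulate_pull(cfg, 42L)
  b <- simulate_pull(cfg, 42L)
  expect_identical(a$position, b$position)
  expect_identical(a$force, b$force)
  c_ <- simulate_pull(cfg, 43L)
  expect_false(identical(a$position, c_$position))
})

test_that("spring end moves monotonically at the pull rate", {
  tr <- simulate_pull(tiny_well_config(), 5L)
  disp <- pull_displacement(tr)
  expect_true(all(diff(disp) >= 0))
  expect_equal(disp, 0.05 * tr$time, tolerance = 1e-12)
})

test_that("deterministic flat pull reaches the drag steady state |F| = gamma*v", {
  # T = 0: after the transient (timescale gamma/k), the particle tracks the
  # anchor with constant lag gamma*v/k, so the spring force is gamma*v
  cfg <- pull_config(spring_k = 50, drag_gamma = 5, pull_rate_v = 0.1,
                     dt = 0.005, total_time_ts = 10, temperature_T = 0,
                     potential = binding_potential("flat"),
                     equilibration_time = 0)
  tr <- simulate_pull(cfg, 1L)
  f_term <- abs(tr$force[nrow(tr$force), 1])
  expect_equal(f_term, 5 * 0.1, tolerance = 0.01)
})

test_that("no pulling, no noise, no potential: force and work are identically zero", {
  cfg <- pull_config(spring_k = 50, drag_gamma = 5, pull_rate_v = 0,
                     dt = 0.005, total_time_ts = 5, temperature_T = 0,
                     potential = binding_potential("flat"),
                     x0 = 0, z0 = 0, equilibration_time = 0)
  tr <- simulate_pull(cfg, 1L)
  expect_identical(max(abs(tr$force)), 0)
  ws <- accumulate_work(tr)
  expect_identical(max(abs(ws$cumulative_work)), 0)
})

test_that("protocol validation and the stability guard reject bad inputs", {
  expect_error(pull_config(dt = -0.1), "dt")
  expect_error(pull_config(total_time_ts = -5), "total_time_ts")
  expect_error(pull_config(drag_gamma = 0), "drag_gamma")
  # dt * (k + max|U''|) / gamma >= 0.1 must fail with the timescale named
  bad <- pull_config(spring_k = 400, drag_gamma = 5, dt = 0.01)
  expect_error(simulate_pull(bad, 1L), "relaxation timescale")
})

test_that("spring-clamped fluctuations satisfy equipartition", {
  # v = 0: var(x - z) should be kBT/(k + kappa_well) within 5%
  base <- list(pull_rate_v = 0, dt = 0.002, total_time_ts = 2000,
               drag_gamma = 20, equilibration_time = 20,
               n_replicas = 1L)
  cases <- list(
    list(potential = binding_potential("flat"), k = 100, kappa = 0),
    # depth 9, width 0.6: curvature at the well bottom is 9/0.36 = 25
    list(potential = binding_potential("well", depth = 9, width = 0.6),
         k = 100, kappa = 25)
  )
  for (cs in cases) {
    cfg <- do.call(pull_config, c(base, list(spring_k = cs$k,
                                             potential = cs$potential)))
    tr <- simulate_pull(cfg, 404L)
    dev <- tr$position[, 1] - tr$spring_end[, 1]
    expect_equal(stats::var(dev), 1 / (cs$k + cs$kappa), tolerance = 0.05)
  }
})

test_that("stiff-spring low-temperature flat pulls dissipate gamma*v*L", {
  cfg <- pull_config(spring_k = 1000, drag_gamma = 50, pull_rate_v = 0.05,
                     dt = 0.002, total_time_ts = 50, temperature_T = 1e-6,
                     potential = binding_potential("flat"),
                     n_replicas = 3L, seed = 7L, equilibration_time = 1)
  works <- vapply(seq_len(3), function(i) {
    ws <- accumulate_work(simulate_pull(cfg, cfg$seed + i - 1L))
    work_at(ws, max(ws$pull_coordinate))
  }, numeric(1))
  expect_equal(mean(works), 50 * 0.05 * 2.5, tolerance = 0.02)
})

test_that("slower pulls dissipate less on the reference well", {
  cfg_fast <- pull_config(pull_rate_v = 0.1, total_time_ts = 50,
                          n_replicas = 5L, seed = 900L)
  cfg_slow <- pull_config(pull_rate_v = 0.01, total_time_ts = 500,
                          n_replicas = 5L, seed = 950L)
  w_fast <- pullwork:::replica_works(cfg_fast, 4)$works
  w_slow <- pullwork:::replica_works(cfg_slow, 4)$works
  se <- sqrt(stats::var(w_fast) / 5 + stats::var(w_slow) / 5)
  expect_gt(mean(w_fast) - mean(w_slow), 3 * se)
})

test_that("3-D pulls move along the pull direction with transverse confinement", {
  dir <- c(1, 1, 1) / sqrt(3)
  cfg <- pull_config(spring_k = 50, drag_gamma = 5, pull_rate_v = 0.1,
                     dt = 0.005, total_time_ts = 10, temperature_T = 0,
                     potential = binding_potential("flat"),
                     dimensions = 3L, pull_dir = dir, equilibration_time = 0)
  tr <- simulate_pull(cfg, 1L)
  n <- nrow(tr$force)
  # anchor displacement is v*t along dir
  expect_equal(tr$spring_end[n, ], 0.1 * tr$time[n] * dir, tolerance = 1e-12)
  # steady-state force vector is gamma*v along dir, component-wise
  expect_equal(tr$force[n, ], 5 * 0.1 * dir, tolerance = 0.01)
  # work from component-wise integration matches the 1-D equivalent protocol
  w3 <- work_at(accumulate_work(tr), 0.9)
  cfg1 <- pull_config(spring_k = 50, drag_gamma = 5, pull_rate_v = 0.1,
                      dt = 0.005, total_time_ts = 10, temperature_T = 0,
                      potential = binding_potential("flat"),
                      equilibration_time = 0)
  w1 <- work_at(accumulate_work(simulate_pull(cfg1, 1L)), 0.9)
  expect_equal(w3, w1, tolerance = 1e-9)
})
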