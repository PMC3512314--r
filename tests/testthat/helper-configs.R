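# Small, fast protocols used across the unit tests. The package default
# (pull_config()) is the reference scenario; these are scaled down so a test
# replica takes milliseconds.

tiny_well_config <- function(...) {
  args <- list(spring_k = 50, pull_rate_v = 0.05, dt = 0.005,
               total_time_ts = 20, temperature_T = 1, drag_gamma = 5,
               potential = binding_potential("well", depth = 3, width = 0.3),
               n_replicas = 3L, seed = 101L, equilibration_time = 2)
  override <- list(...)
  args[names(override)] <- override
  do.call(pull_config, args)
}

tiny_flat_config <- function(...) {
  cfg <- tiny_well_config(...)
  viscous_control(cfg)
}

# deterministic hand-made 1-D trajectory for work-integration tests
make_traj <- function(time, z, x, f, units = "reduced", replica_id = 1L) {
  pull_trajectory(time = time, spring_end = cbind(z), position = cbind(x),
                  force = cbind(f), spring_k = 1, pull_rate_v = 1,
                  temperature_T = 1, units = units, replica_id = replica_id)
}

# random proper rotation matrix (QR with positive diagonal, det forced to +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
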