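#' Pull trajectories and replica sets
#'
#' A `pull_trajectory` holds one replica's time series: spring-end (anchor)
#' position, pulled-point position and applied spring force, each as an
#' n x dim matrix, plus the protocol metadata needed downstream (spring
#' constant, pull rate, temperature, unit system, replica id).
#'
#' @param time strictly increasing numeric vector (length >= 2).
#' @param spring_end,position,force numeric matrices, one row per sample.
#' @param spring_k,pull_rate_v,temperature_T,drag_gamma protocol scalars
#'   (`drag_gamma` may be `NA` for trajectories of unknown provenance).
#' @param units unit system (`"reduced"`, `"gromacs"`, `"si"`).
#' @param replica_id integer replica label.
#' @return an object of class `pull_trajectory`.
#' @export
pull_trajectory <- function(time, spring_end, position, force,
                            spring_k, pull_rate_v, temperature_T,
                            units = c("reduced", "gromacs", "si"),
                            replica_id = 1L, drag_gamma = NA_real_) {
  units <- match.arg(units)
  time <- as.numeric(unname(time))
  spring_end <- unname(as.matrix(spring_end))
  position <- unname(as.matrix(position))
  force <- unname(as.matrix(force))
  n <- length(time)
  if (n < 2) stop("a trajectory needs at least 2 samples", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  for (m in list(spring_end, position, force)) {
    if (nrow(m) != n) stop("all arrays must have one row per time sample",
                           call. = FALSE)
  }
  if (ncol(position) != ncol(force) || ncol(spring_end) != ncol(position)) {
    stop("spring_end, position and force must have the same number of ",
         "components", call. = FALSE)
  }
  structure(
    list(time = time, spring_end = spring_end, position = position,
         force = force, spring_k = spring_k, pull_rate_v = pull_rate_v,
         temperature_T = temperature_T, drag_gamma = drag_gamma,
         units = units, replica_id = as.integer(replica_id)),
    class = "pull_trajectory"
  )
}

#' @rdname pull_trajectory
#' @param trajectory a `pull_trajectory`.
#' @return `pull_displacement()`: the pull coordinate — the non-negative
#'   displacement |z(t) - z(0)| of the spring's free end at every sample.
#' @export
pull_displacement <- function(trajectory) {
  z <- trajectory$spring_end
  d <- sweep(z, 2, z[1, ])
  sqrt(rowSums(d^2))
}

#' @export
print.pull_trajectory <- function(x, ...) {
  cat(sprintf(paste0(
    "<pull_trajectory> replica %d, %d samples x %d component(s), units: %s\n",
    "  t in [%g, %g]; spring travel %.4g; k = %g, v = %g, T = %g\n"),
    x$replica_id, length(x$time), ncol(x$position), x$units,
    x$time[1], x$time[length(x$time)], max(pull_displacement(x)),
    x$spring_k, x$pull_rate_v, x$temperature_T))
  invisible(x)
}

#' Simulate one steered-pull replica
#'
#' Integrates the overdamped Langevin equation
#' \deqn{\gamma\,dx = \left[-U'(x) + k\,(z(t) - x)\right]dt +
#'   \sqrt{2\gamma k_B T}\,dW, \qquad z(t) = z_0 + v t,}
#' with the Euler--Maruyama scheme, recording time, spring-end position,
#' particle position and spring force at every step. Before the pull starts
#' the particle relaxes for `equilibration_time` with the spring end clamped
#' at `z0`, so work samples are drawn from the equilibrium initial ensemble
#' the Jarzynski identity requires. Identical `(config, replica_seed)` pairs
#' reproduce bit-identical trajectories.
#'
#' @param config a [pull_config()].
#' @param replica_seed integer seed for this replica.
#' @return a [pull_trajectory()].
#' @export
simulate_pull <- function(config, replica_seed = config$seed) {
  stopifnot(inherits(config, "pull_config"))
  check_stability(config)
  steps <- n_samples(config) - 1L
  equil_steps <- as.integer(floor(config$equilibration_time / config$dt + 1e-9))
  dim <- config$dimensions
  dir <- if (dim == 3L) config$pull_dir else 1
  x_init <- if (dim == 3L) config$x0 else config$x0
  anchor_init <- if (dim == 3L) config$z0 * config$pull_dir else config$z0
  kbt <- kbt_energy(config$temperature_T, config$units)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(replica_seed))

  raw <- pull_langevin_cpp(
    n_steps = steps, dt = config$dt, spring_k = config$spring_k,
    pull_rate = config$pull_rate_v, drag_gamma = config$drag_gamma,
    kbt = kbt, x_init = as.numeric(x_init),
    anchor_init = as.numeric(anchor_init), pull_dir = as.numeric(dir),
    depth = config$potential$depth, width = config$potential$width,
    center = config$potential$center, n_equil_steps = equil_steps
  )
  pull_trajectory(
    time = raw$time, spring_end = raw$anchor, position = raw$position,
    force = raw$force, spring_k = config$spring_k,
    pull_rate_v = config$pull_rate_v, temperature_T = config$temperature_T,
    units = config$units, replica_id = as.integer(replica_seed - config$seed + 1L),
    drag_gamma = config$drag_gamma
  )
}

#' Replica sets
#'
#' A `replica_set` is a list of [pull_trajectory()] objects sharing one
#' protocol (unit system, spring constant, pull rate, temperature).
#'
#' @param trajectories list of `pull_trajectory` objects (length >= 1).
#' @return an object of class `replica_set`.
#' @export
replica_set <- function(trajectories) {
  if (length(trajectories) < 1) stop("need at least one trajectory",
                                     call. = FALSE)
  for (tr in trajectories) {
    if (!inherits(tr, "pull_trajectory")) {
      stop("all elements must be pull_trajectory objects", call. = FALSE)
    }
  }
  ref <- trajectories[[1]]
  for (tr in trajectories[-1]) {
    same <- identical(tr$units, ref$units) &&
      isTRUE(all.equal(tr$spring_k, ref$spring_k)) &&
      isTRUE(all.equal(tr$pull_rate_v, ref$pull_rate_v)) &&
      isTRUE(all.equal(tr$temperature_T, ref$temperature_T))
    if (!same) {
      stop("replica ", tr$replica_id, " does not share the set's protocol ",
           "(units, spring_k, pull_rate_v, temperature_T)", call. = FALSE)
    }
  }
  structure(list(trajectories = trajectories,
                 spring_k = ref$spring_k, pull_rate_v = ref$pull_rate_v,
                 temperature_T = ref$temperature_T, units = ref$units),
            class = "replica_set")
}

#' @rdname replica_set
#' @param config a [pull_config()]; replica i is simulated with seed
#'   `config$seed + i - 1`.
#' @return `simulate_replicas()`: a `replica_set` of `config$n_replicas`
#'   simulated trajectories.
#' @export
simulate_replicas <- function(config) {
  stopifnot(inherits(config, "pull_config"))
  trajs <- vector("list", config$n_replicas)
  for (i in seq_len(config$n_replicas)) {
    trajs[[i]] <- simulate_pull(config, replica_seed = config$seed + i - 1L)
  }
  replica_set(trajs)
}

#' @export
length.replica_set <- function(x) length(x$trajectories)

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf(
    "<replica_set> %d replicas, units: %s, k = %g, v = %g, T = %g\n",
    length(x), x$units, x$spring_k, x$pull_rate_v, x$temperature_T))
  invisible(x)
}
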