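#' Specification of a synthetic steered-pull experiment
#'
#' Bundles the full protocol of a constant-velocity harmonic-spring pull of an
#' overdamped Langevin particle: spring constant, pull rate, duration, time
#' step, temperature, drag coefficient, the model [binding_potential()], and
#' replica bookkeeping.
#'
#' The defaults are the package's reference scenario, in reduced units
#' (kB = 1, kBT = 1 at `temperature_T = 1`): spring constant 400 (the MD
#' protocol's 1,000 kJ/(mol nm^2) expressed in kBT per length^2 at 300 K),
#' pull rate 0.01, duration 500 (total spring-end travel 5, matching
#' 0.01 nm/ps x 500 ps), 30 replicas, drag 400 (a viscous baseline of
#' gamma*v*L = 20 kBT, the scale of the MD control system), and a Gaussian
#' binding well of depth 35 kBT and width 0.3 — deep enough that the bound
#' and viscous work populations are cleanly separated.
#'
#' @param spring_k harmonic spring constant (energy/length^2, >= 0).
#' @param pull_rate_v speed of the spring's free end (length/time, >= 0).
#' @param dt integration and recording time step (> 0). Must satisfy the
#'   stability guard `dt * (spring_k + max|U''|) / drag_gamma < 0.1`.
#' @param total_time_ts total pull duration; `floor(total_time_ts/dt) + 1`
#'   samples are recorded per replica.
#' @param temperature_T temperature (>= 0; 0 switches thermal noise off).
#' @param drag_gamma drag coefficient (mass/time, > 0).
#' @param potential a [binding_potential()].
#' @param x0 initial particle position (scalar, or length-3 when
#'   `dimensions = 3`).
#' @param z0 initial spring-end position along the pull axis.
#' @param n_replicas number of replicas (>= 1).
#' @param seed base RNG seed; replica i uses `seed + i - 1`.
#' @param dimensions 1 or 3. In 3-D the spring end moves along `pull_dir`
#'   and off-axis components feel only the spring's transverse restoring
#'   force; the potential acts on the coordinate along `pull_dir`.
#' @param pull_dir pulling direction (unit 3-vector; only used when
#'   `dimensions = 3`). See [pull_direction()].
#' @param units unit system of all fields.
#' @param equilibration_time pre-pull relaxation at a fixed spring end, so
#'   replicas start from the spring-clamped equilibrium ensemble the
#'   Jarzynski identity assumes.
#' @return an object of class `pull_config`.
#' @export
pull_config <- function(spring_k = 400,
                        pull_rate_v = 0.01,
                        dt = 0.02,
                        total_time_ts = 500,
                        temperature_T = 1,
                        drag_gamma = 400,
                        potential = binding_potential("well", depth = 35,
                                                      width = 0.3, center = 0),
                        x0 = 0,
                        z0 = 0,
                        n_replicas = 30L,
                        seed = 1L,
                        dimensions = 1L,
                        pull_dir = c(1, 0, 0),
                        units = c("reduced", "gromacs", "si"),
                        equilibration_time = 10) {
  units <- match.arg(units)
  scalars <- c(spring_k = spring_k, pull_rate_v = pull_rate_v, dt = dt,
               total_time_ts = total_time_ts, temperature_T = temperature_T,
               drag_gamma = drag_gamma, equilibration_time = equilibration_time)
  if (any(!is.finite(scalars))) {
    stop("all protocol scalars must be finite", call. = FALSE)
  }
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (total_time_ts <= 0) stop("total_time_ts must be > 0", call. = FALSE)
  if (spring_k < 0 || pull_rate_v < 0 || temperature_T < 0) {
    stop("spring_k, pull_rate_v and temperature_T must be >= 0", call. = FALSE)
  }
  if (drag_gamma <= 0) stop("drag_gamma must be > 0", call. = FALSE)
  if (equilibration_time < 0) stop("equilibration_time must be >= 0",
                                   call. = FALSE)
  if (!inherits(potential, "binding_potential")) {
    stop("potential must be a binding_potential", call. = FALSE)
  }
  n_replicas <- as.integer(n_replicas)
  if (is.na(n_replicas) || n_replicas < 1) {
    stop("n_replicas must be >= 1", call. = FALSE)
  }
  dimensions <- as.integer(dimensions)
  if (!dimensions %in% c(1L, 3L)) stop("dimensions must be 1 or 3",
                                       call. = FALSE)
  if (dimensions == 3L) {
    if (length(pull_dir) != 3 || !all(is.finite(pull_dir))) {
      stop("pull_dir must be a finite 3-vector", call. = FALSE)
    }
    nrm <- sqrt(sum(pull_dir^2))
    if (nrm < 1e-12) stop("pull_dir must be non-zero", call. = FALSE)
    pull_dir <- pull_dir / nrm
    if (length(x0) == 1) x0 <- x0 * pull_dir
    if (length(x0) != 3) stop("x0 must be scalar or length 3", call. = FALSE)
  } else {
    pull_dir <- 1
    if (length(x0) != 1) stop("x0 must be scalar in 1-D", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  if (seed + n_replicas >= .Machine$integer.max) {
    stop("seed too large: replica seeds seed + 0..n_replicas-1 must stay ",
         "below 2^31", call. = FALSE)
  }
  structure(
    list(spring_k = spring_k, pull_rate_v = pull_rate_v, dt = dt,
         total_time_ts = total_time_ts, temperature_T = temperature_T,
         drag_gamma = drag_gamma, potential = potential,
         x0 = x0, z0 = z0, n_replicas = n_replicas, seed = seed,
         dimensions = dimensions, pull_dir = pull_dir, units = units,
         equilibration_time = equilibration_time),
    class = "pull_config"
  )
}

#' @rdname pull_config
#' @param config a `pull_config`.
#' @return `viscous_control()`: the same protocol with the potential replaced
#'   by the flat form — the receptor-free control used to measure viscous
#'   (drag-only) work.
#' @export
viscous_control <- function(config) {
  stopifnot(inherits(config, "pull_config"))
  config$potential <- binding_potential("flat")
  config
}

# number of recorded samples = floor(ts/dt) + 1; small tolerance so exact
# ratios are not lost to floating-point division
n_samples <- function(config) {
  as.integer(floor(config$total_time_ts / config$dt + 1e-9)) + 1L
}

# Euler-Maruyama stability guard. The fastest relaxation timescale is
# gamma/(k + max|U''|); the step must resolve it.
check_stability <- function(config) {
  stiff <- config$spring_k + potential_max_curvature(config$potential)
  if (stiff <= 0) return(invisible(TRUE))
  ratio <- config$dt * stiff / config$drag_gamma
  if (ratio >= 0.1) {
    stop(sprintf(paste0(
      "unstable time step: dt*(spring_k + max|U''|)/drag_gamma = %.3g ",
      ">= 0.1; the fastest relaxation timescale gamma/(k + max|U''|) = %.3g ",
      "requires dt < %.3g"),
      ratio, config$drag_gamma / stiff, 0.1 * config$drag_gamma / stiff),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.pull_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<pull_config> %d-D, units: %s\n",
    "  spring_k = %g, pull_rate_v = %g, total_time_ts = %g (travel %g)\n",
    "  dt = %g (%d samples/replica), T = %g, drag_gamma = %g\n",
    "  replicas = %d (base seed %d), equilibration_time = %g\n"),
    x$dimensions, x$units, x$spring_k, x$pull_rate_v, x$total_time_ts,
    x$pull_rate_v * x$total_time_ts, x$dt, n_samples(x), x$temperature_T,
    x$drag_gamma, x$n_replicas, x$seed, x$equilibration_time))
  print(x$potential)
  invisible(x)
}
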