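#' Cumulative mechanical work along a pull
#'
#' Integrates the applied force against displacement with the trapezoidal
#' rule, summed over components:
#' \deqn{W_m = \sum_{i<m} \sum_c \tfrac12 (F_{c,i} + F_{c,i+1})
#'   (r_{c,i+1} - r_{c,i}).}
#' The displacement variable `r` is chosen by `convention`:
#' \describe{
#'   \item{`control_parameter`}{the spring-end (anchor) path — the work
#'     conjugate to the pulling schedule z(t), for which the Jarzynski
#'     identity is exact. The default.}
#'   \item{`com_path`}{the pulled-point (center-of-mass) path, the variable
#'     against which MD force records are conventionally plotted.}
#' }
#' Whatever the convention, the returned series is indexed by the spring-end
#' displacement (see [pull_displacement()]), so both conventions live on one
#' comparable axis. Locally non-monotone pulled-point displacement (thermal
#' jitter) is integrated as-is: mechanical work is path-signed, and
#' rectifying it would bias the work upward.
#'
#' @param trajectory a [pull_trajectory()].
#' @param convention displacement variable for the integrand.
#' @return an object of class `work_series` with fields `pull_coordinate`
#'   (non-decreasing), `cumulative_work` (starting at 0), `convention`,
#'   `replica_id`, `temperature_T`, `units`.
#' @export
accumulate_work <- function(trajectory,
                            convention = c("control_parameter", "com_path")) {
  convention <- match.arg(convention)
  stopifnot(inherits(trajectory, "pull_trajectory"))
  force <- trajectory$force
  r <- if (convention == "control_parameter") trajectory$spring_end
       else trajectory$position
  if (anyNA(force) || any(!is.finite(force))) {
    stop("non-finite force at index ",
         which(!is.finite(rowSums(force)))[1], call. = FALSE)
  }
  if (anyNA(r) || any(!is.finite(r))) {
    stop("non-finite displacement at index ",
         which(!is.finite(rowSums(r)))[1], call. = FALSE)
  }
  n <- nrow(force)
  dW <- rowSums((force[-n, , drop = FALSE] + force[-1, , drop = FALSE]) / 2 *
                (r[-1, , drop = FALSE] - r[-n, , drop = FALSE]))
  structure(
    list(pull_coordinate = pull_displacement(trajectory),
         cumulative_work = c(0, cumsum(dW)),
         convention = convention,
         replica_id = trajectory$replica_id,
         temperature_T = trajectory$temperature_T,
         units = trajectory$units),
    class = "work_series"
  )
}

#' @rdname accumulate_work
#' @param series a `work_series`.
#' @param coordinate pull coordinate(s) at which to evaluate the cumulative
#'   work, by linear interpolation between bracketing samples.
#' @return `work_at()`: cumulative work value(s).
#' @export
work_at <- function(series, coordinate) {
  stopifnot(inherits(series, "work_series"))
  pc <- series$pull_coordinate
  if (any(coordinate < pc[1] - 1e-12) ||
      any(coordinate > pc[length(pc)] + 1e-12)) {
    stop(sprintf(paste0("replica %d: pull coordinate spans [%.6g, %.6g]; ",
                        "cannot evaluate work at %g"),
                 series$replica_id, pc[1], pc[length(pc)], max(coordinate)),
         call. = FALSE)
  }
  stats::approx(pc, series$cumulative_work, xout = coordinate, ties = "ordered",
                rule = 2)$y
}

#' Terminal work samples at a production cutoff
#'
#' Evaluates every replica's cumulative work at exactly the cutoff
#' displacement (linear interpolation between bracketing samples) and bundles
#' the N_s values with the temperature they were sampled at — the input of
#' the work estimators.
#'
#' @param replicas a [replica_set()], or a list of `work_series`.
#' @param cutoff pull-coordinate cutoff; every replica must reach it.
#' @param convention see [accumulate_work()] (ignored when work series are
#'   supplied directly).
#' @return an object of class `work_sample`: `works` (length N_s), `cutoff`,
#'   `temperature_T`, `kbt`, `convention`, `units`.
#' @export
collect_work_sample <- function(replicas, cutoff,
                                convention = c("control_parameter",
                                               "com_path")) {
  convention <- match.arg(convention)
  series <- if (inherits(replicas, "replica_set")) {
    lapply(replicas$trajectories, accumulate_work, convention = convention)
  } else {
    for (s in replicas) stopifnot(inherits(s, "work_series"))
    replicas
  }
  works <- vapply(series, function(s) {
    if (max(s$pull_coordinate) < cutoff - 1e-12) {
      stop("replica ", s$replica_id, " ends at pull coordinate ",
           signif(max(s$pull_coordinate), 6), ", before the cutoff ", cutoff,
           call. = FALSE)
    }
    work_at(s, cutoff)
  }, numeric(1))
  ref <- series[[1]]
  work_sample(works, cutoff = cutoff, temperature_T = ref$temperature_T,
              units = ref$units, convention = ref$convention)
}

#' @rdname collect_work_sample
#' @param works numeric vector of work values (finite, length >= 1).
#' @param temperature_T temperature the works were sampled at.
#' @param units unit system (sets kB, hence kBT).
#' @export
work_sample <- function(works, cutoff = NA_real_, temperature_T = 1,
                        units = c("reduced", "gromacs", "si"),
                        convention = "control_parameter") {
  units <- match.arg(units)
  works <- as.numeric(works)
  if (length(works) < 1) stop("empty work sample", call. = FALSE)
  if (any(!is.finite(works))) stop("non-finite work values", call. = FALSE)
  kbt <- kbt_energy(temperature_T, units)
  if (!is.finite(kbt) || kbt <= 0) {
    stop("work_sample needs temperature_T > 0 (kBT sets the estimator scale)",
         call. = FALSE)
  }
  structure(list(works = works, cutoff = cutoff,
                 temperature_T = temperature_T, kbt = kbt,
                 convention = convention, units = units),
            class = "work_sample")
}

#' @export
print.work_sample <- function(x, ...) {
  cat(sprintf(paste0("<work_sample> N_s = %d at cutoff %g (%s, %s units)\n",
                     "  mean %.4g, sd %.4g, range [%.4g, %.4g]\n"),
              length(x$works), x$cutoff, x$convention, x$units,
              mean(x$works), stats::sd(x$works), min(x$works), max(x$works)))
  invisible(x)
}

# Simulate-and-integrate without retaining trajectories: returns the terminal
# works of config's replicas at `cutoff`. Used by the repeated-experiment
# studies, where keeping every trajectory would be wasteful.
replica_works <- function(config, cutoff,
                          convention = c("control_parameter", "com_path"),
                          base_seed = config$seed) {
  convention <- match.arg(convention)
  works <- numeric(config$n_replicas)
  for (i in seq_len(config$n_replicas)) {
    tr <- simulate_pull(config, replica_seed = base_seed + i - 1L)
    works[i] <- work_at(accumulate_work(tr, convention), cutoff)
  }
  work_sample(works, cutoff = cutoff, temperature_T = config$temperature_T,
              units = config$units, convention = convention)
}
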