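#' Model binding potentials for synthetic pulls
#'
#' A one-dimensional potential acting along the pull axis, standing in for a
#' ligand's binding well. Three forms are supported:
#' \describe{
#'   \item{`well`}{a single Gaussian well,
#'     `U(x) = -depth * exp(-(x - center)^2 / (2 width^2))`.}
#'   \item{`double_well`}{the sum of two such wells (`depth`, `width`,
#'     `center` are then length-2 vectors).}
#'   \item{`flat`}{`U == 0` everywhere — the receptor-free viscous control,
#'     where the particle is dragged through solvent friction only.}
#' }
#'
#' @param form potential form.
#' @param depth well depth(s), in the energy unit of the experiment (> 0).
#' @param width Gaussian width(s) sigma (> 0).
#' @param center well center(s) along the pull axis.
#' @return an object of class `binding_potential`.
#' @examples
#' pot <- binding_potential("well", depth = 35, width = 0.3)
#' potential_energy(pot, 0)    # -35 at the bottom
#' @export
binding_potential <- function(form = c("well", "double_well", "flat"),
                              depth = numeric(), width = numeric(),
                              center = numeric()) {
  form <- match.arg(form)
  n_wells <- switch(form, flat = 0L, well = 1L, double_well = 2L)
  if (n_wells == 0L) {
    depth <- numeric(); width <- numeric(); center <- numeric()
  } else {
    if (length(center) == 0) center <- rep(0, n_wells)
    if (length(depth) != n_wells || length(width) != n_wells ||
        length(center) != n_wells) {
      stop("form '", form, "' needs ", n_wells,
           " value(s) each of depth, width, center", call. = FALSE)
    }
    if (any(!is.finite(depth)) || any(depth <= 0)) {
      stop("well depth must be finite and > 0", call. = FALSE)
    }
    if (any(!is.finite(width)) || any(width <= 0)) {
      stop("well width must be finite and > 0", call. = FALSE)
    }
  }
  structure(
    list(form = form, depth = as.numeric(depth), width = as.numeric(width),
         center = as.numeric(center)),
    class = "binding_potential"
  )
}

#' @rdname binding_potential
#' @param potential a `binding_potential`.
#' @param x positions along the pull axis (vectorised).
#' @return `potential_energy()`: U(x); exactly zero for the flat form.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "binding_potential"))
  u <- numeric(length(x))
  for (j in seq_along(potential$depth)) {
    d <- (x - potential$center[j]) / potential$width[j]
    u <- u - potential$depth[j] * exp(-0.5 * d^2)
  }
  u
}

#' @rdname binding_potential
#' @return `potential_gradient()`: dU/dx; exactly zero for the flat form.
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "binding_potential"))
  g <- numeric(length(x))
  for (j in seq_along(potential$depth)) {
    w <- potential$width[j]
    d <- (x - potential$center[j]) / w
    g <- g + potential$depth[j] * d / w * exp(-0.5 * d^2)
  }
  g
}

# Upper bound on |U''| over the axis; used by the integrator stability guard.
# For one Gaussian well the curvature magnitude peaks at the center with
# value depth/width^2; summing over wells bounds the double-well case.
potential_max_curvature <- function(potential) {
  if (length(potential$depth) == 0) return(0)
  sum(potential$depth / potential$width^2)
}

#' @export
print.binding_potential <- function(x, ...) {
  if (x$form == "flat") {
    cat("<binding_potential> flat (U == 0)\n")
  } else {
    cat(sprintf("<binding_potential> %s: depth %s, width %s, center %s\n",
                x$form, paste(x$depth, collapse = "/"),
                paste(x$width, collapse = "/"),
                paste(x$center, collapse = "/")))
  }
  invisible(x)
}

# log of \int_a^b exp(-U(x)/kBT - extra(x)) dx, computed with a shift so deep
# wells (exp(+depth/kBT) large) cannot overflow. `extra` is an optional
# additional energy term (the spring, for the anchored variant), in the same
# units as U.
.log_boltzmann_weight <- function(potential, lower, upper, kbt,
                                  extra = NULL, rel_tol = 1e-10,
                                  n_pieces = 1L) {
  logf <- function(x) {
    e <- potential_energy(potential, x)
    if (!is.null(extra)) e <- e + extra(x)
    -e / kbt
  }
  probe <- seq(lower, upper, length.out = 4096)
  shift <- max(logf(probe))
  # piecewise panels so the adaptive rule cannot overlook a feature much
  # narrower than the integration window (e.g. a stiff spring's thermal width)
  breaks <- seq(lower, upper, length.out = n_pieces + 1L)
  total <- 0
  for (i in seq_len(n_pieces)) {
    val <- stats::integrate(function(x) exp(logf(x) - shift),
                            breaks[i], breaks[i + 1L],
                            rel.tol = rel_tol, abs.tol = rel_tol,
                            subdivisions = 2000L, stop.on.error = FALSE)
    if (!val$message %in% c("OK", "the integral is probably divergent") ||
        !is.finite(val$value)) {
      stop("quadrature failed to converge over [", breaks[i], ", ",
           breaks[i + 1L], "]: ", val$message, call. = FALSE)
    }
    total <- total + val$value
  }
  if (total <= 0) stop("quadrature returned a non-positive weight",
                       call. = FALSE)
  shift + log(total)
}

#' Exact free-energy oracles by quadrature
#'
#' `analytic_delta_g()` returns the unbinding free energy between a bound and
#' a reference interval of a one-dimensional potential,
#' \deqn{\Delta G = k_B T \, \ln\!\left[\int_{bound} e^{-U/k_BT} dx \Big/
#'   \int_{ref} e^{-U/k_BT} dx\right],}
#' positive for a binding well — the same orientation as the experimental
#' convention \eqn{\Delta G = k_B T \ln K_a} (see [delta_g_from_ka()]), so it
#' is directly comparable with the (positive) extraction work estimators.
#' For the flat form the value is the exact log length ratio.
#'
#' `analytic_delta_g_spring()` returns the free-energy difference of the
#' spring-anchored system between two anchor positions,
#' \eqn{G(z_{end}) - G(z_0)} with
#' \eqn{G(z) = -k_B T \ln \int e^{-(U(x) + k(z-x)^2/2)/k_B T} dx}.
#' This is the quantity that work conjugate to the moving anchor estimates,
#' hence the proper oracle for the Jarzynski bound on synthetic pulls.
#'
#' @param potential a [binding_potential()].
#' @param bound_interval,reference_interval length-2 numeric intervals.
#' @param temperature_T temperature.
#' @param units unit system (sets kB).
#' @param rel_tol quadrature relative tolerance.
#' @return free energy in the energy unit of `units`.
#' @export
analytic_delta_g <- function(potential, bound_interval, reference_interval,
                             temperature_T = 1,
                             units = c("reduced", "gromacs", "si"),
                             rel_tol = 1e-10) {
  units <- match.arg(units)
  kbt <- kbt_energy(temperature_T, units)
  for (iv in list(bound_interval, reference_interval)) {
    if (length(iv) != 2 || !all(is.finite(iv)) || diff(iv) <= 0) {
      stop("intervals must be finite, non-degenerate (lower < upper)",
           call. = FALSE)
    }
  }
  if (potential$form == "flat") {
    # identical integrands: the ratio is the ratio of lengths, exactly
    return(kbt * (log(diff(bound_interval)) - log(diff(reference_interval))))
  }
  lzb <- .log_boltzmann_weight(potential, bound_interval[1], bound_interval[2],
                               kbt, rel_tol = rel_tol)
  lzr <- .log_boltzmann_weight(potential, reference_interval[1],
                               reference_interval[2], kbt, rel_tol = rel_tol)
  kbt * (lzb - lzr)
}

#' @rdname analytic_delta_g
#' @param spring_k spring constant of the harmonic anchor.
#' @param z_start,z_end anchor positions along the pull axis.
#' @export
analytic_delta_g_spring <- function(potential, spring_k, z_start, z_end,
                                    temperature_T = 1,
                                    units = c("reduced", "gromacs", "si"),
                                    rel_tol = 1e-10) {
  units <- match.arg(units)
  stopifnot(is.finite(spring_k), spring_k > 0,
            is.finite(z_start), is.finite(z_end))
  kbt <- kbt_energy(temperature_T, units)
  # integration window: wide enough for the spring's thermal width and for
  # every well the particle could occupy
  pad <- max(10 * sqrt(kbt / spring_k),
             if (length(potential$width)) 10 * max(potential$width) else 0)
  lo <- min(z_start, z_end, potential$center) - pad
  hi <- max(z_start, z_end, potential$center) + pad
  feature <- min(sqrt(kbt / spring_k),
                 if (length(potential$width)) min(potential$width) else Inf)
  n_pieces <- min(1024L, max(1L, ceiling((hi - lo) / feature)))
  logz <- function(z) {
    .log_boltzmann_weight(potential, lo, hi, kbt,
                          extra = function(x) 0.5 * spring_k * (z - x)^2,
                          rel_tol = rel_tol, n_pieces = n_pieces)
  }
  kbt * (logz(z_start) - logz(z_end))
}
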