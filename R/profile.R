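#' Replica-averaged force profile
#'
#' Bins every replica's force record by spring-end displacement, averages the
#' force vector within each bin per replica, and reports, per bin, the mean
#' and standard deviation across replicas of the per-replica mean-force
#' magnitudes — the force-vs-pull-coordinate curve with its replica scatter.
#' Bin-averaging within a replica before taking the magnitude keeps the
#' stiff-spring thermal noise (SD ~ k sqrt(kBT/k_eff), typically much larger
#' than the mean force) from swamping the profile.
#'
#' @param replicas a [replica_set()] with at least 2 members (the SD across
#'   replicas is undefined otherwise).
#' @param bin_width bin width on the pull coordinate (> 0); the package
#'   default elsewhere is total travel / 100.
#' @return an object of class `force_profile`: `bin_centers`,
#'   `mean_force_magnitude`, `sd_force`, `n_per_bin` (replicas contributing),
#'   `bin_width`, `units`. Bins with no data are omitted; bins seen by a
#'   single replica are dropped too (no SD).
#' @export
mean_force_profile <- function(replicas, bin_width) {
  stopifnot(inherits(replicas, "replica_set"))
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  if (length(replicas) < 2) {
    stop("need >= 2 replicas for the profile dispersion", call. = FALSE)
  }
  per_rep <- lapply(replicas$trajectories, function(tr) {
    disp <- pull_displacement(tr)
    bin <- floor(disp / bin_width + 1e-12)
    # average the force vector within each bin, then take its magnitude
    mags <- vapply(split(seq_along(bin), bin), function(ix) {
      sqrt(sum(colMeans(tr$force[ix, , drop = FALSE])^2))
    }, numeric(1))
    data.frame(bin = as.integer(names(mags)), mag = as.numeric(mags))
  })
  all_bins <- sort(unique(unlist(lapply(per_rep, `[[`, "bin"))))
  stats_by_bin <- lapply(all_bins, function(b) {
    v <- unlist(lapply(per_rep, function(d) d$mag[d$bin == b]))
    c(n = length(v), mean = mean(v),
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  })
  m <- do.call(rbind, stats_by_bin)
  keep <- m[, "n"] >= 2
  structure(
    list(bin_centers = (all_bins[keep] + 0.5) * bin_width,
         mean_force_magnitude = m[keep, "mean"],
         sd_force = m[keep, "sd"],
         n_per_bin = as.integer(m[keep, "n"]),
         bin_width = bin_width,
         units = replicas$units),
    class = "force_profile"
  )
}

#' @rdname mean_force_profile
#' @param bin_centers,mean_force_magnitude,sd_force,n_per_bin,units profile
#'   fields, for constructing a profile directly (e.g. published curves).
#' @export
force_profile <- function(bin_centers, mean_force_magnitude, sd_force,
                          n_per_bin = NA_integer_, bin_width = NA_real_,
                          units = "reduced") {
  stopifnot(length(bin_centers) == length(mean_force_magnitude),
            length(bin_centers) == length(sd_force))
  bin_centers <- as.numeric(bin_centers)
  mean_force_magnitude <- as.numeric(mean_force_magnitude)
  sd_force <- as.numeric(sd_force)
  if (is.unsorted(bin_centers, strictly = TRUE)) {
    stop("bin_centers must be strictly increasing", call. = FALSE)
  }
  if (length(n_per_bin) == 1) n_per_bin <- rep(n_per_bin, length(bin_centers))
  if (is.na(bin_width) && length(bin_centers) > 1) {
    bin_width <- min(diff(bin_centers))
  }
  structure(list(bin_centers = bin_centers,
                 mean_force_magnitude = mean_force_magnitude,
                 sd_force = sd_force, n_per_bin = n_per_bin,
                 bin_width = bin_width, units = units),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf(paste0("<force_profile> %d bins of width %g (%s units), ",
                     "pull coordinate in [%g, %g]\n"),
              length(x$bin_centers), x$bin_width, x$units,
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' @export
plot.force_profile <- function(x, y = NULL, add = FALSE, col = "black", ...) {
  if (!add) {
    plot(x$bin_centers, x$mean_force_magnitude, type = "l", col = col,
         xlab = "pull coordinate", ylab = "mean |F|", ...)
  } else {
    graphics::lines(x$bin_centers, x$mean_force_magnitude, col = col, ...)
  }
  graphics::arrows(x$bin_centers, x$mean_force_magnitude - x$sd_force,
                   x$bin_centers, x$mean_force_magnitude + x$sd_force,
                   length = 0.02, angle = 90, code = 3, col = col)
  invisible(x)
}

#' Error-bar-crossing convergence criterion and production cutoff
#'
#' Finds the pull coordinate from which the bound profile's error bars
#' (mean +/- `sd_multiplier` SD) overlap the control profile's for
#' `m_consecutive` consecutive shared bins — the point at which the bound
#' system's force record is statistically indistinguishable from the
#' receptor-free control, i.e. the ligand is out of the binding site. The
#' production cutoff doubles that distance as a safety margin.
#'
#' @param profile_bound,profile_viscous [force_profile()]s on a common grid
#'   (equal bin width; comparison uses their shared bin centers).
#' @param m_consecutive required consecutive overlapping bins (default 3:
#'   sustained overlap guards against single-bin flukes).
#' @param sd_multiplier half-width of the error bars in SDs.
#' @return list with `crossing` (bin center) and `cutoff` (= 2 * crossing).
#' @export
errorbar_crossing <- function(profile_bound, profile_viscous,
                              m_consecutive = 3L, sd_multiplier = 1) {
  stopifnot(inherits(profile_bound, "force_profile"),
            inherits(profile_viscous, "force_profile"))
  if (m_consecutive < 1) stop("m_consecutive must be >= 1", call. = FALSE)
  if (is.finite(profile_bound$bin_width) &&
      is.finite(profile_viscous$bin_width) &&
      abs(profile_bound$bin_width - profile_viscous$bin_width) >
        1e-9 * profile_bound$bin_width) {
    stop("profiles must share a bin grid; re-bin to a common bin_width first",
         call. = FALSE)
  }
  tol <- profile_bound$bin_width * 1e-6
  if (!is.finite(tol)) tol <- 1e-9
  ib <- match_tol(profile_bound$bin_centers, profile_viscous$bin_centers, tol)
  shared <- which(!is.na(ib))
  if (length(shared) == 0) stop("profiles share no bins", call. = FALSE)
  b_lo <- profile_bound$mean_force_magnitude[shared] -
    sd_multiplier * profile_bound$sd_force[shared]
  b_hi <- profile_bound$mean_force_magnitude[shared] +
    sd_multiplier * profile_bound$sd_force[shared]
  v_lo <- profile_viscous$mean_force_magnitude[ib[shared]] -
    sd_multiplier * profile_viscous$sd_force[ib[shared]]
  v_hi <- profile_viscous$mean_force_magnitude[ib[shared]] +
    sd_multiplier * profile_viscous$sd_force[ib[shared]]
  overlap <- b_lo <= v_hi & v_lo <= b_hi
  run <- 0L
  start <- NA_integer_
  for (i in seq_along(overlap)) {
    if (isTRUE(overlap[i])) {
      run <- run + 1L
      if (run == 1L) start <- i
      if (run >= m_consecutive) {
        crossing <- profile_bound$bin_centers[shared[start]]
        return(list(crossing = crossing, cutoff = 2 * crossing))
      }
    } else {
      run <- 0L
      start <- NA_integer_
    }
  }
  stop("error bars never overlap for ", m_consecutive, " consecutive bins; ",
       "the profiles have not converged - extend the pulls", call. = FALSE)
}

# index of each x in table (within tol), NA if absent
match_tol <- function(x, table, tol) {
  vapply(x, function(xi) {
    j <- which(abs(table - xi) <= tol)
    if (length(j) == 0) NA_integer_ else j[1]
  }, integer(1))
}

#' Interior/exterior partition of the pull path
#'
#' Splits the pull into the interior region (inside the binding pocket, up to
#' the pocket-threshold boundary coordinate) and the exterior remainder, and
#' reports the interior fraction of the total pull distance together with the
#' mean (+/- SE) work accumulated inside.
#'
#' @param series_set list of `work_series` (one per replica), or a
#'   [replica_set()] (integrated with the default convention).
#' @param boundary_coordinate pull coordinate of the pocket threshold; every
#'   series must reach it.
#' @param total_distance total pull distance (>= boundary).
#' @return an object of class `region_partition`: `boundary_coordinate`,
#'   `total_distance`, `interior_fraction`, `interior_work`,
#'   `interior_work_se`, `n`.
#' @export
partition_work <- function(series_set, boundary_coordinate, total_distance) {
  if (inherits(series_set, "replica_set")) {
    series_set <- lapply(series_set$trajectories, accumulate_work)
  }
  if (!is.finite(boundary_coordinate) || boundary_coordinate < 0) {
    stop("boundary_coordinate must be >= 0", call. = FALSE)
  }
  if (boundary_coordinate > total_distance) {
    stop("boundary_coordinate must not exceed total_distance", call. = FALSE)
  }
  works <- vapply(series_set, function(s) {
    if (max(s$pull_coordinate) < boundary_coordinate - 1e-12) {
      stop("replica ", s$replica_id, " ends before the boundary coordinate ",
           boundary_coordinate, call. = FALSE)
    }
    work_at(s, boundary_coordinate)
  }, numeric(1))
  n <- length(works)
  structure(
    list(boundary_coordinate = boundary_coordinate,
         total_distance = total_distance,
         interior_fraction = boundary_coordinate / total_distance,
         interior_work = mean(works),
         interior_work_se = if (n >= 2) stats::sd(works) / sqrt(n) else 0,
         n = n),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(paste0(
    "<region_partition> boundary %g of %g (interior %.1f%% of the pull)\n",
    "  interior work %.4g +/- %.2g (n = %d)\n"),
    x$boundary_coordinate, x$total_distance, 100 * x$interior_fraction,
    x$interior_work, x$interior_work_se, x$n))
  invisible(x)
}

#' Work-histogram population summary
#'
#' Histograms the bound and viscous work samples on a common grid, overlays
#' moment-matched Gaussians (sample mean and SD — the curves are drawn from
#' the moments, not fitted), and quantifies population separation by the
#' standardized mean difference
#' \eqn{|m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}} and the Gaussian overlap
#' coefficient (integral of the pointwise minimum of the two overlay
#' densities; 1 for identical populations, ~0 for disjoint ones).
#'
#' @param sample_bound,sample_viscous [work_sample()]s.
#' @param n_bins number of histogram bins (>= 2) spanning both samples.
#' @return a list of class `work_histogram_summary`: `breaks`, `counts`
#'   (2-row matrix), `mean`, `sd` (length-2, bound then viscous),
#'   `standardized_mean_difference`, `overlap_coefficient`.
#' @export
work_histogram_summary <- function(sample_bound, sample_viscous,
                                   n_bins = 20L) {
  stopifnot(inherits(sample_bound, "work_sample"),
            inherits(sample_viscous, "work_sample"))
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  w1 <- sample_bound$works
  w2 <- sample_viscous$works
  rng <- range(c(w1, w2))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- function(w) {
    h <- graphics::hist(w, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    h$counts
  }
  m <- c(bound = mean(w1), viscous = mean(w2))
  s <- c(bound = stats::sd(w1), viscous = stats::sd(w2))
  s[is.na(s)] <- 0
  pooled <- sqrt((s[1]^2 + s[2]^2) / 2)
  smd <- if (pooled > 0) abs(m[1] - m[2]) / pooled else
    as.numeric(m[1] != m[2]) * Inf
  ovl <- gaussian_overlap(m[1], s[1], m[2], s[2])
  structure(
    list(breaks = breaks,
         counts = rbind(bound = cnt(w1), viscous = cnt(w2)),
         mean = m, sd = s,
         standardized_mean_difference = unname(smd),
         overlap_coefficient = ovl),
    class = "work_histogram_summary"
  )
}

# Overlap coefficient of two normal densities, by quadrature of the pointwise
# minimum; degenerate (zero-SD) populations compare as point masses.
gaussian_overlap <- function(m1, s1, m2, s2) {
  if (s1 == 0 && s2 == 0) return(as.numeric(m1 == m2))
  if (s1 == 0 || s2 == 0) return(0)
  lo <- min(m1 - 9 * s1, m2 - 9 * s2)
  hi <- max(m1 + 9 * s1, m2 + 9 * s2)
  stats::integrate(function(x) pmin(stats::dnorm(x, m1, s1),
                                    stats::dnorm(x, m2, s2)),
                   lo, hi, subdivisions = 1000L, rel.tol = 1e-8,
                   stop.on.error = FALSE)$value
}

#' @export
print.work_histogram_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<work_histogram_summary> %d bins over [%.4g, %.4g]\n",
    "  bound:   mean %.4g, sd %.4g (n = %d)\n",
    "  viscous: mean %.4g, sd %.4g (n = %d)\n",
    "  standardized mean difference %.3g; overlap coefficient %.3g\n"),
    length(x$breaks) - 1L, x$breaks[1], x$breaks[length(x$breaks)],
    x$mean[1], x$sd[1], sum(x$counts["bound", ]),
    x$mean[2], x$sd[2], sum(x$counts["viscous", ]),
    x$standardized_mean_difference, x$overlap_coefficient))
  invisible(x)
}
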