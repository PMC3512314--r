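#' Work averages and the finite-sampling Jarzynski estimator
#'
#' `average_work()` is the plain arithmetic mean of the N_s work values,
#' \deqn{W^a = \frac{1}{N_s}\sum_i W_i,}
#' whose expectation bounds the free-energy difference from above.
#'
#' `jarzynski_work()` is the finite-sampling estimator of the exponential
#' average,
#' \deqn{W^x = -k_B T \,\ln\!\left[\frac{1}{N_s}\sum_i
#'   e^{-W_i/k_B T}\right],}
#' a tighter upper bound: \eqn{\Delta G \le \langle\langle W^x \rangle\rangle
#' \le \langle\langle W^a \rangle\rangle}, with per-sample \eqn{W^x \le W^a}
#' exactly (Jensen). It is evaluated through a shifted log-sum-exp,
#' \eqn{W^x = W_{min} - k_B T \ln[\frac{1}{N_s}\sum_i
#' e^{-(W_i - W_{min})/k_B T}]}, so works of arbitrarily many kBT cannot
#' underflow.
#'
#' Standard errors: `average_work()` reports the sample SD over sqrt(N_s);
#' `jarzynski_work()` a first-order (delta-method) propagation of the SE of
#' the exponential mean. [bootstrap_se()] is the package's primary error
#' estimate for the nonlinear W^x.
#'
#' @param sample a [work_sample()].
#' @return a list with `estimate`, `se`, `n` (class `work_estimate`).
#' @examples
#' s <- work_sample(c(1, 2), temperature_T = 1, units = "reduced")
#' average_work(s)$estimate    # 1.5
#' jarzynski_work(s)$estimate  # -log((exp(-1) + exp(-2))/2) ~= 1.3799
#' @export
average_work <- function(sample) {
  stopifnot(inherits(sample, "work_sample"))
  w <- sample$works
  n <- length(w)
  se <- if (n == 1) {
    warning("N_s = 1: standard error undefined, reporting 0", call. = FALSE)
    0
  } else stats::sd(w) / sqrt(n)
  structure(list(estimate = mean(w), se = se, n = n), class = "work_estimate")
}

#' @rdname average_work
#' @export
jarzynski_work <- function(sample) {
  stopifnot(inherits(sample, "work_sample"))
  w <- sample$works
  n <- length(w)
  kbt <- sample$kbt
  wmin <- min(w)
  e <- exp(-(w - wmin) / kbt)
  m <- mean(e)
  wx <- wmin - kbt * log(m)
  se <- if (n == 1) {
    warning("N_s = 1: standard error undefined, reporting 0", call. = FALSE)
    0
  } else kbt * stats::sd(e) / (sqrt(n) * m)
  structure(list(estimate = wx, se = se, n = n), class = "work_estimate")
}

#' Bootstrap standard error of a work statistic
#'
#' Standard deviation of W^a or W^x over `B` resamples (with replacement) of
#' the work sample. Seeded and reproducible; the RNG state of the session is
#' left untouched.
#'
#' @param sample a [work_sample()] with N_s >= 2.
#' @param statistic `"Wa"` (arithmetic mean) or `"Wx"` (Jarzynski).
#' @param B number of resamples (>= 100).
#' @param seed integer seed.
#' @return the bootstrap standard error (scalar).
#' @export
bootstrap_se <- function(sample, statistic = c("Wa", "Wx"), B = 1000L,
                         seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(sample, "work_sample"))
  w <- sample$works
  n <- length(w)
  if (n < 2) stop("bootstrap is degenerate for N_s = 1", call. = FALSE)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  stats_b <- if (statistic == "Wa") {
    rowMeans(matrix(w[idx], nrow = B))
  } else {
    kbt <- sample$kbt
    wm <- matrix(w[idx], nrow = B)
    wmin <- apply(wm, 1, min)
    wmin - kbt * log(rowMeans(exp(-(wm - wmin) / kbt)))
  }
  stats::sd(stats_b)
}

#' Combined estimator result for one replica set
#'
#' Computes W^a and W^x with bootstrap standard errors (classical SD/sqrt(N)
#' and delta-method errors are retained as cross-checks) and asserts the
#' per-sample Jensen inequality W^x <= W^a — a violation is impossible for
#' correct arithmetic and aborts.
#'
#' @param sample a [work_sample()].
#' @param B bootstrap resamples (used when N_s >= 2).
#' @param seed bootstrap seed.
#' @param label provenance label (`"bound"`, `"viscous"`, `"corrected"`).
#' @return an object of class `estimator_result` with fields `Wa`, `Wx`,
#'   `se_Wa`, `se_Wx`, `se_Wa_classical`, `se_Wx_delta`, `N_s`,
#'   `temperature_T`, `kbt`, `units`, `convention`, `label`.
#' @export
estimate_work <- function(sample, B = 1000L, seed = 1L, label = "bound") {
  stopifnot(inherits(sample, "work_sample"))
  wa <- average_work(sample)
  wx <- jarzynski_work(sample)
  if (wx$estimate > wa$estimate + 1e-9 * max(1, abs(wa$estimate))) {
    stop("impossible result Wx > Wa (Jensen violated): implementation bug",
         call. = FALSE)
  }
  n <- length(sample$works)
  se_wa_b <- if (n >= 2) bootstrap_se(sample, "Wa", B = B, seed = seed) else 0
  se_wx_b <- if (n >= 2) bootstrap_se(sample, "Wx", B = B, seed = seed + 1L)
             else 0
  structure(
    list(Wa = wa$estimate, Wx = wx$estimate,
         se_Wa = se_wa_b, se_Wx = se_wx_b,
         se_Wa_classical = wa$se, se_Wx_delta = wx$se,
         N_s = n, temperature_T = sample$temperature_T, kbt = sample$kbt,
         units = sample$units, convention = sample$convention, label = label),
    class = "estimator_result"
  )
}

#' @rdname estimate_work
#' @param Wa,Wx,se_Wa,se_Wx,N_s,temperature_T,units,convention,label fields
#'   for constructing a result directly — e.g. from published values used as
#'   inputs to [viscous_correction()].
#' @export
estimator_result <- function(Wa, Wx, se_Wa = NA_real_, se_Wx = NA_real_,
                             N_s = NA_integer_, temperature_T = 1,
                             units = c("reduced", "gromacs", "si"),
                             convention = "control_parameter",
                             label = "bound", check_jensen = TRUE) {
  units <- match.arg(units)
  # Jensen binds per-sample estimates; differences of estimates (label
  # "corrected") are exempt
  if (check_jensen && is.finite(Wa) && is.finite(Wx) &&
      Wx > Wa + 1e-9 * max(1, abs(Wa))) {
    stop("Wx must not exceed Wa (Jensen)", call. = FALSE)
  }
  structure(
    list(Wa = Wa, Wx = Wx, se_Wa = se_Wa, se_Wx = se_Wx,
         se_Wa_classical = NA_real_, se_Wx_delta = NA_real_,
         N_s = N_s, temperature_T = temperature_T,
         kbt = kbt_energy(temperature_T, units),
         units = units, convention = convention, label = label),
    class = "estimator_result"
  )
}

#' @export
print.estimator_result <- function(x, ...) {
  fmt <- function(v, s) {
    if (is.finite(s) && s > 0) {
      p <- 10^floor(log10(s))
      sprintf("%g +/- %g", round(v / p) * p, round(s / p) * p)
    } else sprintf("%g", v)
  }
  cat(sprintf("<estimator_result> [%s] N_s = %s, T = %g (%s units)\n",
              x$label, x$N_s, x$temperature_T, x$units))
  cat("  Wa =", fmt(x$Wa, x$se_Wa), "\n")
  cat("  Wx =", fmt(x$Wx, x$se_Wx), "\n")
  invisible(x)
}

#' Ordering report: free energy vs the two work bounds
#'
#' Reports the two inequalities \eqn{\Delta G \le W^x \le W^a} with their
#' margins in kBT. The per-sample Jensen inequality W^x <= W^a must hold
#' unconditionally; \eqn{\Delta G \le W^x} is a statistical statement that an
#' unlucky finite sample may violate, so it is reported, not asserted.
#'
#' @param delta_g reference free-energy difference, in the same energy units
#'   as the estimate (from [analytic_delta_g_spring()] on synthetic systems,
#'   or [delta_g_from_ka()] for experimental comparison).
#' @param bound_result an [estimate_work()] result.
#' @return a list of class `ordering_report`: margins (kBT), pass flags.
#' @export
ordering_check <- function(delta_g, bound_result) {
  stopifnot(inherits(bound_result, "estimator_result"))
  kbt <- bound_result$kbt
  m_dg <- (bound_result$Wx - delta_g) / kbt
  m_jensen <- (bound_result$Wa - bound_result$Wx) / kbt
  structure(
    list(delta_g = delta_g, Wx = bound_result$Wx, Wa = bound_result$Wa,
         margin_dg_kbt = m_dg, margin_jensen_kbt = m_jensen,
         dg_below_wx = m_dg >= 0, wx_below_wa = m_jensen >= -1e-9,
         pass = m_dg >= 0 && m_jensen >= -1e-9),
    class = "ordering_report"
  )
}

#' @export
print.ordering_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<ordering_report> dG <= Wx <= Wa: %s\n",
    "  dG = %.4g, Wx = %.4g, Wa = %.4g\n",
    "  margin Wx - dG = %.3g kBT (%s), margin Wa - Wx = %.3g kBT (%s)\n"),
    if (x$pass) "PASS" else "FAIL", x$delta_g, x$Wx, x$Wa,
    x$margin_dg_kbt, if (x$dg_below_wx) "ok" else "violated",
    x$margin_jensen_kbt, if (x$wx_below_wa) "ok" else "violated"))
  invisible(x)
}

#' Viscous-dissipation correction
#'
#' Subtracts the receptor-free control's work estimates from the bound
#' system's, removing the dissipation spent dragging the ligand through
#' solvent along the same protocol: `Wx_corrected = Wx_bound - Wx_viscous`
#' (and likewise for Wa). Errors propagate in quadrature. For display, value
#' and error are rounded to the coarser input's decimal precision (the raw
#' values are retained in the object).
#'
#' @param bound,viscous `estimator_result` objects sharing temperature,
#'   units and work convention.
#' @return an `estimator_result` labelled `"corrected"`, with extra fields
#'   `display_Wx`, `display_se_Wx` (and the Wa analogues).
#' @export
viscous_correction <- function(bound, viscous) {
  stopifnot(inherits(bound, "estimator_result"),
            inherits(viscous, "estimator_result"))
  if (!isTRUE(all.equal(bound$temperature_T, viscous$temperature_T)) ||
      !identical(bound$units, viscous$units)) {
    stop("bound and viscous results must share temperature and units",
         call. = FALSE)
  }
  if (!identical(bound$convention, viscous$convention)) {
    stop("bound and viscous results must share the work convention",
         call. = FALSE)
  }
  quad <- function(a, b) {
    if (is.na(a) || is.na(b)) NA_real_ else sqrt(a^2 + b^2)
  }
  out <- estimator_result(
    Wa = bound$Wa - viscous$Wa, Wx = bound$Wx - viscous$Wx,
    se_Wa = quad(bound$se_Wa, viscous$se_Wa),
    se_Wx = quad(bound$se_Wx, viscous$se_Wx),
    N_s = bound$N_s, temperature_T = bound$temperature_T,
    units = bound$units, convention = bound$convention, label = "corrected",
    check_jensen = FALSE
  )
  # display precision: one step of the coarser (larger) of the two input
  # error magnitudes, e.g. 0.6e-19 and 0.2e-19 both imply steps of 1e-20
  prec <- function(se) if (is.finite(se) && se > 0) 10^floor(log10(se))
                       else NA_real_
  p <- max(prec(bound$se_Wx), prec(viscous$se_Wx), na.rm = FALSE)
  if (is.finite(p)) {
    out$display_Wx <- round(out$Wx / p) * p
    out$display_se_Wx <- round(out$se_Wx / p) * p
  } else {
    out$display_Wx <- out$Wx
    out$display_se_Wx <- out$se_Wx
  }
  p <- max(prec(bound$se_Wa), prec(viscous$se_Wa), na.rm = FALSE)
  if (is.finite(p)) {
    out$display_Wa <- round(out$Wa / p) * p
    out$display_se_Wa <- round(out$se_Wa / p) * p
  } else {
    out$display_Wa <- out$Wa
    out$display_se_Wa <- out$se_Wa
  }
  out
}

#' Free energy from an experimental affinity constant
#'
#' \deqn{\Delta G = k_B T \ln (K_a c^\circ),}
#' with the affinity constant made dimensionless by the standard
#' concentration c° = 1 M. Reported as a positive magnitude for a binding
#' affinity Ka > 1/c° — the unbinding orientation, matching the positive
#' extraction work it is compared against (the binding free energy is its
#' negative).
#'
#' @param Ka affinity (association) constant, in 1/molar.
#' @param temperature_T temperature in kelvin.
#' @param standard_conc standard concentration c° in molar.
#' @param units unit system of the returned energy (default SI joules).
#' @return energy (scalar).
#' @examples
#' delta_g_from_ka(18.79e3, 300)   # ~4.08e-20 J
#' @export
delta_g_from_ka <- function(Ka, temperature_T, standard_conc = 1,
                            units = c("si", "gromacs", "reduced")) {
  units <- match.arg(units)
  if (!is.finite(Ka) || Ka <= 0) stop("Ka must be > 0", call. = FALSE)
  if (!is.finite(temperature_T) || temperature_T <= 0) {
    stop("temperature_T must be > 0", call. = FALSE)
  }
  kbt_energy(temperature_T, units) * log(Ka * standard_conc)
}

#' @rdname delta_g_from_ka
#' @param delta_g energy, in the units of `units`.
#' @return `ka_from_delta_g()`: the affinity constant in 1/molar.
#' @export
ka_from_delta_g <- function(delta_g, temperature_T, standard_conc = 1,
                            units = c("si", "gromacs", "reduced")) {
  units <- match.arg(units)
  exp(delta_g / kbt_energy(temperature_T, units)) / standard_conc
}
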