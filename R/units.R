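#' Unit systems and physical constants
#'
#' Three unit systems are recognised throughout the package:
#' \describe{
#'   \item{`reduced`}{kB = 1, so energies are in units of kBT at T = 1.
#'     The internal default: exponentials of `-W/kBT` are the central
#'     numerical hazard and reduced units keep them tame.}
#'   \item{`gromacs`}{nm, ps, kJ/mol (and kJ/mol/nm for force); the native
#'     units of MD pull output.}
#'   \item{`si`}{m, s, J, N.}
#' }
#'
#' @param units one of `"reduced"`, `"gromacs"`, `"si"`.
#' @return `boltzmann_constant()`: kB in the energy/temperature units of the
#'   system (1, kJ/(mol K), or J/K).
#' @export
boltzmann_constant <- function(units = c("reduced", "gromacs", "si")) {
  units <- match.arg(units)
  switch(units,
    reduced = 1,
    gromacs = 0.008314462618, # kJ/(mol K)
    si      = 1.380649e-23    # J/K
  )
}

#' @rdname boltzmann_constant
#' @param temperature_T temperature in kelvin (or the reduced temperature).
#' @return `kbt_energy()`: the thermal energy kB*T in the system's energy unit.
#' @export
kbt_energy <- function(temperature_T, units = c("reduced", "gromacs", "si")) {
  boltzmann_constant(units) * temperature_T
}

# Avogadro's number; the single declared point where molar and absolute
# energy scales meet.
.avogadro <- 6.02214076e23

# Multiplicative factors taking gromacs units to SI, per quantity.
.gromacs_to_si <- c(
  length   = 1e-9,                     # nm -> m
  time     = 1e-12,                    # ps -> s
  energy   = 1000 / 6.02214076e23,     # kJ/mol -> J
  force    = 1000 / 6.02214076e23 / 1e-9, # kJ/mol/nm -> N (1.66054e-12)
  velocity = 1e3                       # nm/ps -> m/s
)

#' Convert between the gromacs and SI unit systems
#'
#' Only the two physical systems are interconvertible; reduced units carry no
#' absolute scale and refuse conversion. The conversion is involutive:
#' gromacs -> si -> gromacs is the identity to better than 1e-12 relative.
#'
#' @param x numeric values to convert.
#' @param quantity which physical quantity `x` is (`"length"`, `"time"`,
#'   `"energy"`, `"force"`, `"velocity"`).
#' @param from,to unit systems.
#' @return converted numeric values.
#' @export
convert_quantity <- function(x, quantity, from, to) {
  quantity <- match.arg(quantity, names(.gromacs_to_si))
  from <- match.arg(from, c("reduced", "gromacs", "si"))
  to <- match.arg(to, c("reduced", "gromacs", "si"))
  if (from == to) return(x)
  if (from == "reduced" || to == "reduced") {
    stop("reduced units carry no absolute scale; cannot convert ",
         from, " -> ", to, call. = FALSE)
  }
  f <- .gromacs_to_si[[quantity]]
  if (from == "gromacs") x * f else x / f
}
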