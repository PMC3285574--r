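#' Physical constants used by the electrodiffusion equations
#' @keywords internal
FARADAY <- 96485.33   # C/mol
GAS_CONSTANT <- 8.314 # J/(mol K)

#' Membrane permeability of a species
#'
#' Permeability scales log-linearly with the lipophilicity of the permeating
#' species: `P = alpha * 10^logP`, with a single global scaling constant
#' `alpha` (cm/s at logP = 0).
#'
#' @param logP_species log10 partition coefficient of the species.
#' @param alpha Permeability scaling constant, cm/s.
#' @return Permeability in cm/s.
#' @export
permeability <- function(logP_species, alpha) {
  stopifnot(alpha > 0)
  alpha * 10^logP_species
}

#' Dimensionless electrochemical driving term
#'
#' `N = z F E / (R T)`, the membrane potential expressed in units of the
#' thermal voltage. `E` is defined as inside potential minus outside
#' potential.
#'
#' @param z Valence of the ionized species.
#' @param E Membrane potential in volts (inside - outside).
#' @param T_kelvin Absolute temperature (default 310 K).
#' @return Dimensionless N, same sign as `z * E`.
#' @export
nernst_term <- function(z, E, T_kelvin = 310) {
  stopifnot(T_kelvin > 0)
  z * FARADAY * E / (GAS_CONSTANT * T_kelvin)
}

#' Fick flux of the neutral species
#'
#' @param P_n Permeability of the neutral species, cm/s.
#' @param C_out_free,C_in_free Free aqueous concentrations on the outer and
#'   inner faces, mass/ml.
#' @return Flux in mass/(cm^2 s); positive means net inward.
#' @export
flux_neutral <- function(P_n, C_out_free, C_in_free) {
  P_n * (C_out_free - C_in_free)
}

# N/(expm1(N)) evaluated stably; g(0) = 1, g > 0 everywhere, g(N)->0 as
# N->+Inf and g(N)->|N| as N->-Inf. The inward and outward conductance
# factors of the Goldman flux are g(N) and g(-N).
goldman_g <- function(N) {
  ifelse(abs(N) < 1e-6, 1, N / expm1(N))
}

#' Nernst-Planck (Goldman) flux of the ionized species
#'
#' Constant-field electrodiffusion flux across a membrane held at potential
#' `E` (inside - outside), with `N = zFE/RT`:
#' `J = P_d N (C_out - C_in e^N) / (e^N - 1)`.
#' For `|N| < 1e-6` the Fick limit `P_d (C_out - C_in)` is used. The
#' implementation is numerically stable for large `|N|`. Zero flux occurs at
#' the Nernst equilibrium `C_in = C_out e^(-N)`.
#'
#' @param P_d Permeability of the ionized species, cm/s.
#' @param N Dimensionless electrochemical term from [nernst_term()].
#' @param C_out_free,C_in_free Free aqueous concentrations, mass/ml.
#' @return Flux in mass/(cm^2 s); positive means net inward.
#' @export
flux_ion <- function(P_d, N, C_out_free, C_in_free) {
  if (abs(N) < 1e-6) {
    return(P_d * (C_out_free - C_in_free))
  }
  P_d * (goldman_g(N) * C_out_free - goldman_g(-N) * C_in_free)
}

#' Specify a membrane joining two compartments
#'
#' @param id Label.
#' @param side_out,side_in Compartment ids. `potential_E` is the electrical
#'   potential of `side_in` minus that of `side_out`.
#' @param area Membrane area, cm^2 (> 0).
#' @param potential_E Membrane potential in volts (default 0).
#' @return A one-row data.frame.
#' @export
membrane_spec <- function(id, side_out, side_in, area, potential_E = 0) {
  stopifnot(is.finite(area), area > 0, is.finite(potential_E))
  data.frame(id = id, side_out = side_out, side_in = side_in,
             area = area, potential_E = potential_E,
             stringsAsFactors = FALSE)
}

# Free aqueous concentration of one species given the total compartment mass.
# conc_free = (M * f_species / V) * free_fraction / f_w  (mass per ml water,
# referenced to the aqueous phase as the transport driving force).
free_conc_coefficient <- function(compound, comp, species) {
  f_n <- neutral_fraction(compound, comp$pH)
  f_sp <- if (species == "neutral") f_n else 1 - f_n
  ff <- free_fraction(compound, comp, species)
  f_sp * ff / (comp$f_w * comp$volume)
}

#' Net mass transfer rate across one membrane
#'
#' Combines the Fick flux of the neutral species and the Nernst-Planck flux
#' of the ionized species, each driven by free aqueous concentrations, and
#' scales by membrane area. Permanent cations contribute only the ion term,
#' neutral compounds only the Fick term.
#'
#' @param mem One-row membrane data.frame from [membrane_spec()].
#' @param compound A [compound()].
#' @param state_out,state_in Lists with `C_free_neutral` and `C_free_ion`
#'   (mass/ml; `NA` allowed for absent species).
#' @param alpha Permeability scaling constant, cm/s.
#' @param T_kelvin Temperature, K.
#' @return Net rate in mass/s, positive into `side_in`.
#' @export
membrane_rate <- function(mem, compound, state_out, state_in,
                          alpha = 1e-6, T_kelvin = 310) {
  cc <- compound$charge_class
  if (!cc %in% c("monoprotic_base", "permanent_cation", "neutral")) {
    stop("unknown compound charge_class: ", cc, call. = FALSE)
  }
  J <- 0
  if (cc != "permanent_cation") {
    P_n <- permeability(compound$logPn, alpha)
    J <- J + flux_neutral(P_n, state_out$C_free_neutral, state_in$C_free_neutral)
  }
  if (cc != "neutral") {
    P_d <- permeability(compound$logPd, alpha)
    N <- nernst_term(compound$z, mem$potential_E, T_kelvin)
    J <- J + flux_ion(P_d, N, state_out$C_free_ion, state_in$C_free_ion)
  }
  mem$area * J
}
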