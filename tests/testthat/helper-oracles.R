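# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

default_fixture_lung <- local({
  lung <- NULL
  function() {
    if (is.null(lung)) lung <<- default_lung()
    lung
  }
})

fixture_compounds <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- read_compound_library()
    lib
  }
})

# Integrate a closed two-compartment system joined by a single membrane,
# directly from the package's flux primitives (not the lung assembly), and
# return the final total masses. Used as the electrodiffusion steady-state
# oracle.
integrate_two_compartments <- function(compound, comp1, comp2, area, E,
                                       alpha, M1_0, M2_0, t_end,
                                       T_kelvin = 310) {
  free_conc <- function(M, comp, species) {
    f_n <- neutral_fraction(compound, comp$pH)
    f_sp <- if (species == "neutral") f_n else 1 - f_n
    ff <- free_fraction(compound, comp, species)
    (M * f_sp / comp$volume) * ff / comp$f_w
  }
  mem <- membrane_spec("m", "c1", "c2", area, E)
  deriv <- function(t, y, p) {
    s1 <- list(C_free_neutral = if (compound$charge_class != "permanent_cation")
                 free_conc(y[1], comp1, "neutral") else NA,
               C_free_ion = if (compound$charge_class != "neutral")
                 free_conc(y[1], comp1, "ion") else NA)
    s2 <- list(C_free_neutral = if (compound$charge_class != "permanent_cation")
                 free_conc(y[2], comp2, "neutral") else NA,
               C_free_ion = if (compound$charge_class != "neutral")
                 free_conc(y[2], comp2, "ion") else NA)
    r <- membrane_rate(mem, compound, s1, s2, alpha = alpha,
                       T_kelvin = T_kelvin) * 60 # mass/s -> mass/min
    list(c(-r, r))
  }
  sol <- deSolve::ode(c(M1 = M1_0, M2 = M2_0), c(0, t_end), deriv, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-14)
  sol[nrow(sol), c("M1", "M2")]
}

# Closed-form equilibrium concentration profile of a closed (CL = 0) lung:
# at steady state every membrane carries zero net flux and all blood
# compartments share one concentration, so each compartment's total
# concentration follows from the per-membrane two-species flux balance
#   C_in/C_out = (P_n a_out + P_d g(N) b_out) / (P_n a_in + P_d g(-N) b_in)
# with a = f_neutral * ff_neutral / f_w and b = f_ion * ff_ion / f_w.
# Independent of the rate-matrix assembly and of the ODE solver.
closed_form_equilibrium <- function(lung, compound) {
  comps <- lung$compartments
  alpha <- lung$constants$alpha
  gfun <- function(N) ifelse(abs(N) < 1e-6, 1, N / expm1(N))
  coef_side <- function(comp, g_factor) {
    f_n <- neutral_fraction(compound, comp$pH)
    a <- if (compound$charge_class != "permanent_cation") {
      f_n * free_fraction(compound, comp, "neutral") / comp$f_w *
        permeability(compound$logPn, alpha)
    } else 0
    b <- if (compound$charge_class != "neutral") {
      (1 - f_n) * free_fraction(compound, comp, "ion") / comp$f_w *
        permeability(compound$logPd, alpha) * g_factor
    } else 0
    a + b
  }
  conc <- stats::setNames(rep(NA_real_, nrow(comps)), comps$id)
  conc[c("ven", "art", "aw_blood", "alv_blood")] <- 1
  mems <- lung$membranes
  repeat {
    progressed <- FALSE
    for (m in seq_len(nrow(mems))) {
      out_id <- mems$side_out[m]; in_id <- mems$side_in[m]
      N <- nernst_term(compound$z, mems$potential_E[m],
                       lung$constants$temperature)
      co <- comps[comps$id == out_id, ]
      ci <- comps[comps$id == in_id, ]
      if (is.na(conc[in_id]) && !is.na(conc[out_id])) {
        conc[in_id] <- conc[out_id] * coef_side(co, gfun(N)) /
          coef_side(ci, gfun(-N))
        progressed <- TRUE
      } else if (is.na(conc[out_id]) && !is.na(conc[in_id])) {
        conc[out_id] <- conc[in_id] * coef_side(ci, gfun(-N)) /
          coef_side(co, gfun(N))
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  conc
}
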