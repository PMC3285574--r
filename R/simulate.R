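#' Dosing specification
#'
#' Exactly one of `amount_mg_per_kg` (screening mode), `conc_mM` (probe
#' mode: initial molar concentration in the lining fluid, requires the
#' compound's molecular weight) or `total_mg` (absolute mass) must be given.
#'
#' @param route `"IT"` (intratracheal instillation: dose starts in the
#'   lining fluid) or `"IV"` (bolus: dose starts in venous blood).
#' @param amount_mg_per_kg Dose in mg per kg body weight.
#' @param conc_mM Initial lining-fluid concentration in mmol/l.
#' @param total_mg Absolute dose in mg.
#' @param target For IT: `"airways"`, `"alveoli"` or `"both"`.
#' @param body_weight Body weight in kg; defaults to the lung config value
#'   at simulation time.
#' @return An object of class `"dose_spec"`.
#' @export
dose_spec <- function(route = c("IT", "IV"), amount_mg_per_kg = NULL,
                      conc_mM = NULL, total_mg = NULL,
                      target = c("airways", "alveoli", "both"),
                      body_weight = NULL) {
  route <- match.arg(route)
  target <- match.arg(target)
  modes <- !vapply(list(amount_mg_per_kg, conc_mM, total_mg), is.null,
                   logical(1))
  if (sum(modes) != 1) {
    stop("exactly one of amount_mg_per_kg, conc_mM, total_mg must be set",
         call. = FALSE)
  }
  amount <- c(amount_mg_per_kg, conc_mM, total_mg)
  if (!is.finite(amount) || amount <= 0) {
    stop("dose amounts must be positive and finite", call. = FALSE)
  }
  structure(list(route = route, amount_mg_per_kg = amount_mg_per_kg,
                 conc_mM = conc_mM, total_mg = total_mg, target = target,
                 body_weight = body_weight),
            class = "dose_spec")
}

#' Stiff-solver settings
#'
#' @param rel_tol,abs_tol Relative and absolute integration tolerances
#'   (defaults 1e-12; must lie in (0, 1e-3]).
#' @param t_end Simulation end time in minutes.
#' @param n_output Number of output times, laid out on a hybrid
#'   geometric-plus-linear grid (dense early so trapezoidal AUC captures
#'   fast initial transients).
#' @return An object of class `"solver_spec"`.
#' @export
solver_spec <- function(rel_tol = 1e-12, abs_tol = 1e-12, t_end = 240,
                        n_output = 201) {
  stopifnot(rel_tol > 0, rel_tol <= 1e-3, abs_tol > 0, abs_tol <= 1e-3,
            t_end > 0, n_output >= 2)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, t_end = t_end,
                 n_output = as.integer(n_output)), class = "solver_spec")
}

output_times <- function(solver) {
  n_lin <- ceiling(solver$n_output / 2)
  n_geo <- solver$n_output - n_lin
  t_lin <- seq(0, solver$t_end, length.out = n_lin)
  t_geo <- solver$t_end * 10^seq(-4, 0, length.out = max(n_geo, 2))
  sort(unique(c(0, t_lin, t_geo)))
}

body_weight_of <- function(lung, dose) {
  if (!is.null(dose$body_weight)) dose$body_weight else
    lung$systemic$body_weight
}

dose_mass_for_volume <- function(dose, lung, compound, lining_volume) {
  if (!is.null(dose$amount_mg_per_kg)) {
    dose$amount_mg_per_kg * body_weight_of(lung, dose)
  } else if (!is.null(dose$total_mg)) {
    dose$total_mg
  } else {
    if (!is.finite(compound$mw)) {
      stop("probe-mode dosing (conc_mM) requires the compound's molecular ",
           "weight", call. = FALSE)
    }
    # mM = mmol/l = 1e-3 mmol/ml; mass (mg) = conc * 1e-3 * V_ml * MW
    dose$conc_mM * 1e-3 * lining_volume * compound$mw
  }
}

#' Initial state for intratracheal instillation
#'
#' The entire dose is placed in the lining fluid of the target region(s);
#' every other compartment starts at zero. In screening mode (mg/kg dosing)
#' the airways and alveoli are dosed in separate simulations, so
#' `target = "both"` is rejected; in probe mode (`conc_mM`) each targeted
#' lining fluid is filled to the stated concentration.
#'
#' @param lung A [lung_model()].
#' @param dose A [dose_spec()] with `route = "IT"`.
#' @param compound A [compound()] (needed for molar dosing).
#' @return Named state vector of compartment masses (mg).
#' @export
initial_state_it <- function(lung, dose, compound = NULL) {
  stopifnot(inherits(dose, "dose_spec"), dose$route == "IT")
  if (dose$target == "both" && is.null(dose$conc_mM)) {
    stop("IT screening mode doses one region per simulation; ",
         "target = 'both' is only valid for probe (conc_mM) dosing",
         call. = FALSE)
  }
  y <- stats::setNames(numeric(nrow(lung$compartments)),
                       lung$compartments$id)
  targets <- if (dose$target == "both") c("airways", "alveoli") else
    dose$target
  for (region in targets) {
    id <- if (region == "airways") "aw_lining" else "alv_lining"
    vol <- lung$compartments$volume[lung$compartments$id == id]
    y[id] <- dose_mass_for_volume(dose, lung, compound, vol)
  }
  y
}

#' Initial state for an intravenous bolus
#'
#' The dose is placed in the venous blood compartment (initial concentration
#' `dose x body weight / V_venous`); all lung compartments start at zero.
#' Assumes no significant plasma protein binding and a blood:plasma
#' concentration ratio of 1.
#'
#' @inheritParams initial_state_it
#' @param dose A [dose_spec()] with `route = "IV"`.
#' @return Named state vector of compartment masses (mg).
#' @export
initial_state_iv <- function(lung, dose, compound = NULL) {
  stopifnot(inherits(dose, "dose_spec"), dose$route == "IV")
  y <- stats::setNames(numeric(nrow(lung$compartments)),
                       lung$compartments$id)
  lining <- sum(lung$compartments$volume[lung$compartments$role ==
                                           "lining_fluid"])
  y["ven"] <- dose_mass_for_volume(dose, lung, compound, lining)
  y
}

#' Assemble the linear transport rate matrix of a lung model
#'
#' The model is linear in compartment masses, so the full dynamics are
#' `dM/dt = A M`. Each membrane contributes Fick (neutral species) and
#' Nernst-Planck (ionized species) conductances between its two
#' compartments, each driven by the free aqueous concentration; perfusion
#' couples regional blood to the venous/arterial pools, and systemic
#' clearance drains the venous pool. With `CL = 0` every column of `A` sums
#' to zero (exact mass conservation).
#'
#' @param lung A [lung_model()].
#' @param compound A [compound()].
#' @param clamp Optional character vector of compartment ids whose rows are
#'   zeroed, holding their masses constant (used for fixed-blood-
#'   concentration boundary conditions).
#' @param drop_region Optional region name whose membranes and perfusion are
#'   disconnected, so that region takes no part in transport (used by the
#'   isolated-region screening mode).
#' @return Square matrix (1/min) with dimnames equal to compartment ids.
#' @export
build_rate_matrix <- function(lung, compound, clamp = NULL,
                              drop_region = NULL) {
  comps <- lung$compartments
  n <- nrow(comps)
  A <- matrix(0, n, n, dimnames = list(comps$id, comps$id))
  alpha <- lung$constants$alpha
  T_kelvin <- lung$constants$temperature
  has_neutral <- compound$charge_class != "permanent_cation"
  has_ion <- compound$charge_class != "neutral"

  # per-compartment free aqueous concentration per unit total mass (1/ml)
  kn <- ki <- numeric(n)
  for (i in seq_len(n)) {
    comp <- comps[i, ]
    if (has_neutral) kn[i] <- free_conc_coefficient(compound, comp, "neutral")
    if (has_ion) ki[i] <- free_conc_coefficient(compound, comp, "ion")
  }

  add_edge <- function(A, i, j, G_out, G_in, k) {
    # mass flow into j: G_out * k[i] * M[i] - G_in * k[j] * M[j]
    A[j, i] <- A[j, i] + G_out * k[i]
    A[i, i] <- A[i, i] - G_out * k[i]
    A[i, j] <- A[i, j] + G_in * k[j]
    A[j, j] <- A[j, j] - G_in * k[j]
    A
  }

  dropped_ids <- if (is.null(drop_region)) character(0) else
    comps$id[comps$region == drop_region]

  idx <- stats::setNames(seq_len(n), comps$id)
  for (m in seq_len(nrow(lung$membranes))) {
    mem <- lung$membranes[m, ]
    if (mem$side_out %in% dropped_ids || mem$side_in %in% dropped_ids) next
    i <- idx[[mem$side_out]]
    j <- idx[[mem$side_in]]
    if (has_neutral) {
      G <- 60 * mem$area * permeability(compound$logPn, alpha) # ml/min
      A <- add_edge(A, i, j, G, G, kn)
    }
    if (has_ion) {
      P_d <- permeability(compound$logPd, alpha)
      N <- nernst_term(compound$z, mem$potential_E, T_kelvin)
      G_out <- 60 * mem$area * P_d * goldman_g(N)
      G_in <- 60 * mem$area * P_d * goldman_g(-N)
      A <- add_edge(A, i, j, G_out, G_in, ki)
    }
  }

  # perfusion: arterial -> regional blood -> venous -> arterial;
  # venous->arterial carries the sum of regional flows so the loop conserves
  # mass exactly; clearance drains the venous pool.
  V <- stats::setNames(comps$volume, comps$id)
  Q <- c(aw_blood = lung$config$regions$airways$blood_flow_rate,
         alv_blood = lung$config$regions$alveoli$blood_flow_rate)
  for (rb in names(Q)) {
    if (rb %in% dropped_ids) {
      Q[[rb]] <- 0
      next
    }
    A[rb, "art"] <- A[rb, "art"] + Q[[rb]] / V[["art"]]
    A["art", "art"] <- A["art", "art"] - Q[[rb]] / V[["art"]]
    A["ven", rb] <- A["ven", rb] + Q[[rb]] / V[[rb]]
    A[rb, rb] <- A[rb, rb] - Q[[rb]] / V[[rb]]
  }
  Q_tot <- sum(Q)
  A["art", "ven"] <- A["art", "ven"] + Q_tot / V[["ven"]]
  A["ven", "ven"] <- A["ven", "ven"] - Q_tot / V[["ven"]]
  A["ven", "ven"] <- A["ven", "ven"] - lung$systemic$CL / V[["ven"]]

  if (!is.null(clamp)) {
    bad <- setdiff(clamp, comps$id)
    if (length(bad)) {
      stop("unknown compartment id(s) in clamp: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    A[clamp, ] <- 0
  }
  A
}

#' Mass derivative of the transport system
#'
#' @param t Time (minutes; unused, the system is autonomous).
#' @param state Named vector of compartment masses (mg), in the order of
#'   `lung$compartments$id`.
#' @param lung A [lung_model()].
#' @param compound A [compound()].
#' @param A Optional precomputed matrix from [build_rate_matrix()].
#' @return Derivative vector (mg/min).
#' @export
rhs <- function(t, state, lung, compound, A = NULL) {
  if (length(state) != nrow(lung$compartments)) {
    stop("state length ", length(state), " does not match compartment count ",
         nrow(lung$compartments), call. = FALSE)
  }
  bad <- !is.finite(state)
  if (any(bad)) {
    stop("non-finite state in compartment(s): ",
         paste(lung$compartments$id[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(A)) A <- build_rate_matrix(lung, compound)
  drop(A %*% state)
}

#' Simulate a compound in a lung model
#'
#' Integrates the stiff linear ODE system with `deSolve::lsoda`, using the
#' analytic Jacobian (the constant rate matrix). Tiny negative masses within
#' solver tolerance are clamped to zero; larger negativity signals a
#' mis-assembled model and is an error.
#'
#' @param lung A [lung_model()].
#' @param compound A [compound()].
#' @param dose A [dose_spec()].
#' @param solver A [solver_spec()].
#' @param clamp Optional compartment ids held constant (boundary condition).
#' @param y0 Optional explicit initial state overriding the dose-derived one.
#' @param drop_region Optional region to disconnect from transport; see
#'   [build_rate_matrix()].
#' @return An object of class `"pk_sim"`: `times` (min), `amounts`
#'   (time x compartment matrix, mg), `blood_concentration` (venous, mg/ml),
#'   `compartments`, and metadata (`compound`, `dose`, `solver`,
#'   `lung_fingerprint`).
#' @export
simulate_lung <- function(lung, compound, dose, solver = solver_spec(),
                          clamp = NULL, y0 = NULL, drop_region = NULL) {
  stopifnot(inherits(lung, "lung_model"), inherits(compound, "compound"),
            inherits(solver, "solver_spec"))
  if (is.null(y0)) {
    y0 <- if (dose$route == "IT") initial_state_it(lung, dose, compound) else
      initial_state_iv(lung, dose, compound)
  }
  A <- build_rate_matrix(lung, compound, clamp = clamp,
                         drop_region = drop_region)
  times <- output_times(solver)
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, p) list(drop(p %*% y)),
    parms = A,
    jacfunc = function(t, y, p) p,
    jactype = "fullusr",
    method = "lsoda",
    rtol = solver$rel_tol, atol = solver$abs_tol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("stiff solver failed to converge (istate = ", diagn[1],
         "); step diagnostics: ", paste(diagn[1:5], collapse = " "),
         call. = FALSE)
  }
  amounts <- unclass(sol)[, -1, drop = FALSE]
  neg_tol <- max(100 * solver$abs_tol, 1e-9 * sum(abs(y0)))
  worst <- min(amounts)
  if (worst < -neg_tol) {
    stop("negative compartment mass ", format(worst),
         " mg exceeds solver tolerance; the model graph may be ",
         "mis-assembled", call. = FALSE)
  }
  amounts[amounts < 0] <- 0
  structure(list(
    times = times,
    amounts = amounts,
    blood_concentration = amounts[, "ven"] /
      lung$compartments$volume[lung$compartments$id == "ven"],
    compartments = lung$compartments,
    compound = compound, dose = dose, solver = solver,
    lung_fingerprint = config_fingerprint(lung$config)
  ), class = "pk_sim")
}

#' @export
print.pk_sim <- function(x, ...) {
  cat("<pk_sim> ", x$compound$name, ", route ", x$dose$route, ", ",
      length(x$times), " times to ", max(x$times), " min, ",
      ncol(x$amounts), " compartments\n", sep = "")
  invisible(x)
}

#' Steady-state compartment masses under a fixed-blood boundary condition
#'
#' Holds the venous and arterial pools at a fixed concentration (an infinite
#' reservoir) and solves the linear system for the steady-state masses of
#' all remaining compartments. This is the fixed-blood-concentration reading
#' of IV screening: the lung equilibrates against a constant systemic
#' concentration.
#'
#' @param lung A [lung_model()].
#' @param compound A [compound()].
#' @param C_blood Blood concentration (mg/ml) imposed on venous and arterial
#'   pools.
#' @return Named vector of steady-state masses (mg) for every compartment.
#' @export
steady_state_fixed_blood <- function(lung, compound, C_blood) {
  comps <- lung$compartments
  A <- build_rate_matrix(lung, compound)
  fixed <- c("ven", "art")
  free <- setdiff(comps$id, fixed)
  x_fixed <- C_blood * comps$volume[match(fixed, comps$id)]
  rhs_vec <- -A[free, fixed, drop = FALSE] %*% x_fixed
  x_free <- solve(A[free, free, drop = FALSE], rhs_vec)
  out <- stats::setNames(numeric(nrow(comps)), comps$id)
  out[fixed] <- x_fixed
  out[free] <- drop(x_free)
  out
}
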