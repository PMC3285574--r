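REGION_PARAM_KEYS <- c(
  "epithelium_surface_area", "endothelium_surface_area",
  "lining_fluid_volume", "epithelial_cell_volume", "endothelial_cell_volume",
  "interstitium_volume", "smooth_muscle_volume", "macrophage_volume",
  "immune_cell_volume", "mitochondria_volume", "regional_blood_volume",
  "blood_flow_rate")

SYSTEMIC_KEYS <- c("V_venous", "V_arterial", "CL", "cardiac_output",
                   "body_weight")

COMPARTMENT_ROLES <- c("lining_fluid", "epithelial_cytosol", "mitochondria",
                       "interstitium", "smooth_muscle", "macrophage",
                       "immune_cell", "endothelial_cytosol", "regional_blood",
                       "venous_blood", "arterial_blood")

MEMBRANE_KEYS <- c("alpha", "temperature", "plasma_potential",
                   "mitochondrial_potential", "mito_area_per_ml",
                   "cell_area_per_ml", "sm_mito_fraction")

OPTION_KEYS <- c("clearance_exchange_value", "it_isolated_regions",
                 "screen_it_fixed_blood")

# Names of the exchangeable parameters, as printed in exchange tables,
# mapped to RegionParams keys. "Clearance" is systemic and handled apart.
EXCHANGE_PARAMETERS <- c(
  "Epithelium Surface Area" = "epithelium_surface_area",
  "Smooth Muscle Volume"    = "smooth_muscle_volume",
  "Endothelium Area"        = "endothelium_surface_area",
  "Macrophage Volume"       = "macrophage_volume",
  "Immune Cells Volume"     = "immune_cell_volume",
  "Interstitium Volume"     = "interstitium_volume",
  "Mitochondria Volume"     = "mitochondria_volume",
  "Blood Flow Rate"         = "blood_flow_rate",
  "Clearance"               = "CL")

check_numeric_scalar <- function(value, key, min = 0) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    stop("config key '", key, "' must be a finite numeric scalar",
         call. = FALSE)
  }
  if (value < min) {
    stop("config key '", key, "' must be >= ", min, " (got ", value, ")",
         call. = FALSE)
  }
  invisible(value)
}

validate_lung_config <- function(config) {
  known_top <- c("regions", "systemic", "compartment_defaults", "membranes",
                 "options")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (region in c("airways", "alveoli")) {
    block <- config$regions[[region]]
    unknown <- setdiff(names(block), REGION_PARAM_KEYS)
    if (length(unknown)) {
      stop("unknown config key(s) under regions.", region, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (key in REGION_PARAM_KEYS) {
      check_numeric_scalar(block[[key]], paste0("regions.", region, ".", key))
    }
    for (key in c("lining_fluid_volume", "epithelial_cell_volume",
                  "endothelial_cell_volume", "interstitium_volume",
                  "regional_blood_volume", "blood_flow_rate")) {
      if (block[[key]] <= 0) {
        stop("config key 'regions.", region, ".", key, "' must be > 0",
             call. = FALSE)
      }
    }
    if (block$epithelium_surface_area <= 0) {
      stop("unbuildable region '", region,
           "': regions.", region, ".epithelium_surface_area must be > 0",
           call. = FALSE)
    }
  }
  unknown <- setdiff(names(config$systemic), SYSTEMIC_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s) under systemic: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (key in SYSTEMIC_KEYS) {
    check_numeric_scalar(config$systemic[[key]], paste0("systemic.", key))
  }
  unknown <- setdiff(names(config$compartment_defaults), COMPARTMENT_ROLES)
  if (length(unknown)) {
    stop("unknown config key(s) under compartment_defaults: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (role in setdiff(COMPARTMENT_ROLES, names(config$compartment_defaults))) {
    stop("compartment_defaults lacks role '", role, "'", call. = FALSE)
  }
  for (role in names(config$compartment_defaults)) {
    block <- config$compartment_defaults[[role]]
    unknown <- setdiff(names(block), c("pH", "f_w", "f_l"))
    if (length(unknown)) {
      stop("unknown config key(s) under compartment_defaults.", role, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pH <- check_numeric_scalar(block$pH, paste0("compartment_defaults.", role, ".pH"))
    if (pH < 4 || pH > 9) {
      stop("config key 'compartment_defaults.", role,
           ".pH' must lie in [4, 9]", call. = FALSE)
    }
    f_w <- check_numeric_scalar(block$f_w, paste0("compartment_defaults.", role, ".f_w"))
    f_l <- check_numeric_scalar(block$f_l, paste0("compartment_defaults.", role, ".f_l"))
    if (f_w <= 0 || f_w + f_l > 1) {
      stop("compartment_defaults.", role, ": need f_w > 0 and f_w + f_l <= 1",
           call. = FALSE)
    }
  }
  unknown <- setdiff(names(config$membranes), MEMBRANE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s) under membranes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_numeric_scalar(config$membranes$alpha, "membranes.alpha", min = 1e-300)
  check_numeric_scalar(config$membranes$temperature, "membranes.temperature",
                       min = 1e-6)
  for (key in c("plasma_potential", "mitochondrial_potential")) {
    v <- config$membranes[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("config key 'membranes.", key, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  check_numeric_scalar(config$membranes$mito_area_per_ml,
                       "membranes.mito_area_per_ml", min = 1e-6)
  check_numeric_scalar(config$membranes$cell_area_per_ml,
                       "membranes.cell_area_per_ml", min = 1e-6)
  smf <- check_numeric_scalar(config$membranes$sm_mito_fraction,
                              "membranes.sm_mito_fraction")
  if (smf >= 1) {
    stop("config key 'membranes.sm_mito_fraction' must be < 1", call. = FALSE)
  }
  unknown <- setdiff(names(config$options), OPTION_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s) under options: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_numeric_scalar(config$options$clearance_exchange_value,
                       "options.clearance_exchange_value")
  for (key in c("it_isolated_regions", "screen_it_fixed_blood")) {
    if (!is.logical(config$options[[key]]) ||
        length(config$options[[key]]) != 1) {
      stop("config key 'options.", key, "' must be TRUE or FALSE",
           call. = FALSE)
    }
  }
  invisible(config)
}

comp_row <- function(id, region, role, volume, defaults) {
  d <- defaults[[role]]
  data.frame(id = id, region = region, role = role, volume = volume,
             pH = d$pH, f_w = d$f_w, f_l = d$f_l, stringsAsFactors = FALSE)
}

#' Build the compartment/membrane graph of one lung region
#'
#' Wires the region in series lining fluid <-> epithelium <-> interstitium
#' <-> endothelium <-> regional blood, with smooth muscle, macrophages and
#' immune cells exchanging with the interstitium, and mitochondria nested in
#' the epithelial, endothelial and smooth-muscle cells. The
#' `mitochondria_volume` parameter covers epithelial plus endothelial
#' mitochondria (allocated in proportion to cell volume); smooth-muscle
#' mitochondria are a fixed volume fraction (`sm_mito_fraction`) of the
#' smooth-muscle compartment, so they are added and removed with it.
#'
#' @param params Named list of region parameters (see
#'   `pulmocell:::REGION_PARAM_KEYS`).
#' @param defaults Per-role compartment property table (pH, f_w, f_l).
#' @param region Region label, `"airways"` or `"alveoli"`.
#' @param constants Membrane constants block of the lung config.
#' @return List with `compartments` and `membranes` data.frames.
#' @export
build_region <- function(params, defaults, region, constants) {
  if (!is.finite(params$epithelium_surface_area) ||
      params$epithelium_surface_area <= 0) {
    stop("unbuildable region '", region, "': zero epithelium surface area",
         call. = FALSE)
  }
  pre <- if (region == "airways") "aw" else "alv"
  Ep <- constants$plasma_potential
  Em <- constants$mitochondrial_potential
  mito_total <- params$mitochondria_volume
  v_epi <- params$epithelial_cell_volume
  v_endo <- params$endothelial_cell_volume
  cell_sum <- v_epi + v_endo
  mito_epi <- if (cell_sum > 0) mito_total * v_epi / cell_sum else 0
  mito_endo <- mito_total - mito_epi
  sm_mito <- params$smooth_muscle_volume * constants$sm_mito_fraction
  sm_cyt <- params$smooth_muscle_volume - sm_mito

  comps <- list(
    comp_row(paste0(pre, "_lining"), region, "lining_fluid",
             params$lining_fluid_volume, defaults),
    comp_row(paste0(pre, "_epi"), region, "epithelial_cytosol", v_epi, defaults)
  )
  mems <- list(
    membrane_spec(paste0(pre, "_apical"), paste0(pre, "_lining"),
                  paste0(pre, "_epi"), params$epithelium_surface_area, Ep),
    membrane_spec(paste0(pre, "_basolateral"), paste0(pre, "_interst"),
                  paste0(pre, "_epi"), params$epithelium_surface_area, Ep)
  )
  if (mito_epi > 0) {
    comps <- c(comps, list(comp_row(paste0(pre, "_epi_mito"), region,
                                    "mitochondria", mito_epi, defaults)))
    mems <- c(mems, list(membrane_spec(paste0(pre, "_epi_mito_m"),
                                       paste0(pre, "_epi"),
                                       paste0(pre, "_epi_mito"),
                                       mito_epi * constants$mito_area_per_ml,
                                       Em)))
  }
  comps <- c(comps, list(comp_row(paste0(pre, "_interst"), region,
                                  "interstitium", params$interstitium_volume,
                                  defaults)))
  if (sm_cyt > 0) {
    comps <- c(comps, list(
      comp_row(paste0(pre, "_sm"), region, "smooth_muscle", sm_cyt, defaults)))
    mems <- c(mems, list(
      membrane_spec(paste0(pre, "_sm_pm"), paste0(pre, "_interst"),
                    paste0(pre, "_sm"),
                    params$smooth_muscle_volume * constants$cell_area_per_ml,
                    Ep)))
    if (sm_mito > 0) {
      comps <- c(comps, list(
        comp_row(paste0(pre, "_sm_mito"), region, "mitochondria", sm_mito,
                 defaults)))
      mems <- c(mems, list(
        membrane_spec(paste0(pre, "_sm_mito_m"), paste0(pre, "_sm"),
                      paste0(pre, "_sm_mito"),
                      sm_mito * constants$mito_area_per_ml, Em)))
    }
  }
  for (cell in c("macrophage", "immune_cell")) {
    vol <- params[[if (cell == "macrophage") "macrophage_volume" else
                     "immune_cell_volume"]]
    if (vol > 0) {
      tag <- if (cell == "macrophage") "mac" else "imm"
      comps <- c(comps, list(comp_row(paste0(pre, "_", tag), region, cell,
                                      vol, defaults)))
      mems <- c(mems, list(membrane_spec(paste0(pre, "_", tag, "_pm"),
                                         paste0(pre, "_interst"),
                                         paste0(pre, "_", tag),
                                         vol * constants$cell_area_per_ml,
                                         Ep)))
    }
  }
  comps <- c(comps, list(comp_row(paste0(pre, "_endo"), region,
                                  "endothelial_cytosol", v_endo, defaults)))
  mems <- c(mems, list(
    membrane_spec(paste0(pre, "_endo_baso"), paste0(pre, "_interst"),
                  paste0(pre, "_endo"), params$endothelium_surface_area, Ep),
    membrane_spec(paste0(pre, "_endo_luminal"), paste0(pre, "_blood"),
                  paste0(pre, "_endo"), params$endothelium_surface_area, Ep)))
  if (mito_endo > 0) {
    comps <- c(comps, list(comp_row(paste0(pre, "_endo_mito"), region,
                                    "mitochondria", mito_endo, defaults)))
    mems <- c(mems, list(membrane_spec(paste0(pre, "_endo_mito_m"),
                                       paste0(pre, "_endo"),
                                       paste0(pre, "_endo_mito"),
                                       mito_endo * constants$mito_area_per_ml,
                                       Em)))
  }
  comps <- c(comps, list(comp_row(paste0(pre, "_blood"), region,
                                  "regional_blood",
                                  params$regional_blood_volume, defaults)))
  list(compartments = do.call(rbind, comps), membranes = do.call(rbind, mems))
}

#' Assemble a two-region lung model from a configuration
#'
#' @param config A validated configuration list, as returned by
#'   [load_config()]. Defaults to the configuration shipped with the package.
#' @return An object of class `"lung_model"`: compartment and membrane
#'   tables for airways, alveoli and systemic blood, plus the systemic
#'   parameters, membrane constants, and the originating config.
#' @export
lung_model <- function(config = load_config()) {
  validate_lung_config(config)
  defaults <- config$compartment_defaults
  constants <- config$membranes
  aw <- build_region(config$regions$airways, defaults, "airways", constants)
  alv <- build_region(config$regions$alveoli, defaults, "alveoli", constants)
  systemic <- rbind(
    comp_row("ven", "systemic", "venous_blood", config$systemic$V_venous,
             defaults),
    comp_row("art", "systemic", "arterial_blood", config$systemic$V_arterial,
             defaults))
  structure(list(
    compartments = rbind(aw$compartments, alv$compartments, systemic),
    membranes = rbind(aw$membranes, alv$membranes),
    systemic = config$systemic,
    constants = constants,
    options = config$options,
    config = config
  ), class = "lung_model")
}

#' @rdname lung_model
#' @export
default_lung <- function(config = load_config()) lung_model(config)

#' @export
print.lung_model <- function(x, ...) {
  cat("<lung_model> ", nrow(x$compartments), " compartments, ",
      nrow(x$membranes), " membranes\n", sep = "")
  cat("  airway epithelium ",
      x$config$regions$airways$epithelium_surface_area, " cm^2, alveolar ",
      x$config$regions$alveoli$epithelium_surface_area, " cm^2\n", sep = "")
  cat("  CL = ", x$systemic$CL, " ml/min, cardiac output = ",
      x$systemic$cardiac_output, " ml/min\n", sep = "")
  invisible(x)
}

#' Exchange one parameter between the airway and alveolar regions
#'
#' Swaps the named parameter's airway and alveolar values and rebuilds the
#' model; all other parameters are untouched. `"Clearance"` is systemic and
#' is instead multiplied by `cl_factor` (when the baseline clearance is zero
#' the configured `options.clearance_exchange_value` is used, since scaling
#' zero has no effect).
#'
#' @param lung A [lung_model()].
#' @param name One of the exchangeable parameter labels (see
#'   [exchange_parameter_names()]); RegionParams keys are also accepted.
#' @param cl_factor Multiplier applied for the clearance perturbation
#'   (default 10).
#' @return A new `lung_model`.
#' @export
exchange_parameter <- function(lung, name, cl_factor = 10) {
  key <- if (name %in% names(EXCHANGE_PARAMETERS)) {
    EXCHANGE_PARAMETERS[[name]]
  } else if (name %in% EXCHANGE_PARAMETERS) {
    name
  } else {
    stop("unknown exchangeable parameter: '", name, "'", call. = FALSE)
  }
  config <- lung$config
  if (key == "CL") {
    config$systemic$CL <- if (config$systemic$CL > 0) {
      config$systemic$CL * cl_factor
    } else {
      config$options$clearance_exchange_value
    }
  } else {
    tmp <- config$regions$airways[[key]]
    config$regions$airways[[key]] <- config$regions$alveoli[[key]]
    config$regions$alveoli[[key]] <- tmp
  }
  lung_model(config)
}

#' Labels of the exchangeable parameters
#' @return Character vector of parameter labels.
#' @export
exchange_parameter_names <- function() names(EXCHANGE_PARAMETERS)

#' Swap every region parameter between airways and alveoli
#'
#' Utility for symmetry checks: exchanges the complete RegionParams blocks,
#' so the rebuilt airways are parameterized exactly as the baseline alveoli
#' and vice versa.
#'
#' @param lung A [lung_model()].
#' @return A new `lung_model`.
#' @export
exchange_all_parameters <- function(lung) {
  config <- lung$config
  tmp <- config$regions$airways
  config$regions$airways <- config$regions$alveoli
  config$regions$alveoli <- tmp
  lung_model(config)
}
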