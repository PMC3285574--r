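#' Virtual screening grid over logPn and pKa
#'
#' @param logPn_min,logPn_max,logPn_step Range and step of the neutral-form
#'   partition coefficient (defaults -2 to 4 by 0.1).
#' @param pKa_min,pKa_max,pKa_step Range and step of pKa (defaults 5 to 14 by
#'   0.2).
#' @return An object of class `"screen_grid"` with `logPn` and `pKa` vectors.
#' @export
screen_grid <- function(logPn_min = -2, logPn_max = 4, logPn_step = 0.1,
                        pKa_min = 5, pKa_max = 14, pKa_step = 0.2) {
  stopifnot(logPn_step > 0, pKa_step > 0, logPn_max > logPn_min,
            pKa_max > pKa_min)
  structure(list(logPn = seq(logPn_min, logPn_max, by = logPn_step),
                 pKa = seq(pKa_min, pKa_max, by = pKa_step)),
            class = "screen_grid")
}

#' @export
print.screen_grid <- function(x, ...) {
  cat("<screen_grid> ", length(x$logPn), " logPn x ", length(x$pKa),
      " pKa = ", length(x$logPn) * length(x$pKa), " points\n", sep = "")
  invisible(x)
}

with_clearance <- function(lung, CL) {
  config <- lung$config
  config$systemic$CL <- CL
  lung_model(config)
}

screen_point_it <- function(lung, cmpd, dose, solver, isolated, fixed_blood) {
  clamp <- if (fixed_blood) c("ven", "art") else NULL
  sims <- lapply(c("airways", "alveoli"), function(target) {
    d <- dose
    d$target <- target
    drop <- if (isolated) setdiff(c("airways", "alveoli"), target) else NULL
    simulate_lung(lung, cmpd, d, solver, clamp = clamp, drop_region = drop)
  })
  names(sims) <- c("airways", "alveoli")
  auc_aw <- auc_trapezoid(sims$airways$times,
                          region_tissue_concentration(sims$airways, "airways"))
  auc_alv <- auc_trapezoid(sims$alveoli$times,
                           region_tissue_concentration(sims$alveoli, "alveoli"))
  t_end <- max(sims$airways$times)
  # under the fixed-blood boundary the lung can empty completely within the
  # horizon, leaving the terminal mass split undefined
  mp_aw <- tryCatch(mass_percent(sims$airways, "airways", t_end),
                    error = function(e) NA_real_)
  c(auc_airways = auc_aw, auc_alveoli = auc_alv,
    auc_ratio = auc_aw / auc_alv,
    mass_percent_airways = mp_aw, mass_percent_alveoli = 100 - mp_aw,
    mass_ratio_alveoli_to_airways = (100 - mp_aw) / mp_aw)
}

screen_point_iv <- function(lung, cmpd, dose, solver) {
  bw <- body_weight_of(lung, dose)
  C0 <- dose$amount_mg_per_kg * bw / lung$systemic$V_venous
  ss <- steady_state_fixed_blood(lung, cmpd, C0)
  comps <- lung$compartments
  m_aw <- sum(ss[comps$id[comps$region == "airways"]])
  m_alv <- sum(ss[comps$id[comps$region == "alveoli"]])
  mp_aw <- 100 * m_aw / (m_aw + m_alv)
  y0 <- stats::setNames(numeric(nrow(comps)), comps$id)
  y0["ven"] <- C0 * comps$volume[comps$id == "ven"]
  y0["art"] <- C0 * comps$volume[comps$id == "art"]
  sim <- simulate_lung(lung, cmpd, dose, solver, clamp = c("ven", "art"),
                       y0 = y0)
  auc_aw <- auc_trapezoid(sim$times, region_tissue_concentration(sim, "airways"))
  auc_alv <- auc_trapezoid(sim$times, region_tissue_concentration(sim, "alveoli"))
  c(auc_airways = auc_aw, auc_alveoli = auc_alv,
    auc_ratio = auc_aw / auc_alv,
    mass_percent_airways = mp_aw, mass_percent_alveoli = 100 - mp_aw,
    mass_ratio_alveoli_to_airways = (100 - mp_aw) / mp_aw)
}

#' Run the virtual screen over a property grid
#'
#' For every `(logPn, pKa)` combination a monoprotic-base compound is built
#' (logPd derived from logPn) and simulated. Systemic clearance is set to
#' zero for screening. For IT the airways and alveoli are dosed in separate
#' simulations and the AUC ratio divides the airway AUC of the airway-dosed
#' run by the alveolar AUC of the alveoli-dosed run; mass percentages follow
#' the fate of the airway-dosed dose at the end of the horizon. By default
#' (`options.screen_it_fixed_blood`) the systemic blood concentration is
#' held fixed at zero during IT screening, so the screen measures absorption
#' into an effectively infinite systemic pool; set the option to `FALSE` for
#' a fully closed recirculating system. For IV the blood concentration is
#' held fixed (infinite reservoir) and steady-state masses are reported,
#' with AUCs accumulated over the same horizon.
#'
#' Individual grid-point failures are recorded (as `NA` rows with a message
#' in `attr(result, "failures")`) rather than aborting the screen.
#'
#' @param lung A [lung_model()].
#' @param grid A [screen_grid()].
#' @param dose A [dose_spec()] in mg/kg (default 1 mg/kg).
#' @param route `"IT"` or `"IV"`.
#' @param solver A [solver_spec()]; the screening default integrates to
#'   140 min, long enough for the fast-draining corner of the grid to clear
#'   while slowly-released compounds remain region-bound.
#' @param logPd_offset Offset for deriving logPd (default 3.5).
#' @return data.frame of class `"screen_result"`: one row per grid point
#'   with the six regional exposure metrics.
#' @export
run_screen <- function(lung, grid = screen_grid(),
                       dose = dose_spec("IT", amount_mg_per_kg = 1),
                       route = c("IT", "IV"),
                       solver = solver_spec(t_end = 140, n_output = 161),
                       logPd_offset = 3.5) {
  route <- match.arg(route)
  stopifnot(inherits(grid, "screen_grid"))
  lung0 <- with_clearance(lung, 0)
  isolated <- isTRUE(lung$options$it_isolated_regions)
  fixed_blood <- isTRUE(lung$options$screen_it_fixed_blood)
  pts <- expand.grid(logPn = grid$logPn, pKa = grid$pKa,
                     KEEP.OUT.ATTRS = FALSE)
  failures <- character(0)
  metrics <- matrix(NA_real_, nrow(pts), 6)
  colnames(metrics) <- c("auc_airways", "auc_alveoli", "auc_ratio",
                         "mass_percent_airways", "mass_percent_alveoli",
                         "mass_ratio_alveoli_to_airways")
  for (k in seq_len(nrow(pts))) {
    cmpd <- compound(sprintf("grid_%g_%g", pts$logPn[k], pts$pKa[k]),
                     "monoprotic_base", logPn = pts$logPn[k],
                     pKa = pts$pKa[k], logPd_offset = logPd_offset)
    res <- tryCatch({
      d <- dose
      d$route <- route
      if (route == "IT") {
        screen_point_it(lung0, cmpd, d, solver, isolated, fixed_blood)
      } else {
        screen_point_iv(lung0, cmpd, d, solver)
      }
    }, error = function(e) {
      failures <<- c(failures, sprintf("logPn=%g pKa=%g: %s", pts$logPn[k],
                                       pts$pKa[k], conditionMessage(e)))
      rep(NA_real_, 6)
    })
    metrics[k, ] <- res
  }
  out <- cbind(pts, as.data.frame(metrics))
  attr(out, "route") <- route
  attr(out, "failures") <- failures
  class(out) <- c("screen_result", class(out))
  out
}

#' Classify an AUC fold change into exchange-table categories
#'
#' Fold changes below 1.1 are "unaffected"; 1.1-1.5 one sign; 1.5-2 two
#' signs; above 5 three signs. The 2-5 band is not assigned a symbol and is
#' flagged explicitly as `"two-to-five"`.
#'
#' @param fold Fold change expressed as `max(x, 1/x)` of the AUC ratio
#'   (>= 1).
#' @param direction `"increase"` or `"decrease"`.
#' @return Category string: `"unaffected"`, a run of `+`/`-` signs, or a
#'   flagged `"two-to-five (increase|decrease)"`.
#' @export
classify_fold_change <- function(fold, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(fold), fold >= 1)
  sign_chr <- if (direction == "increase") "+" else "-"
  if (fold < 1.1) "unaffected"
  else if (fold < 1.5) sign_chr
  else if (fold < 2) strrep(sign_chr, 2)
  else if (fold < 5) paste0("two-to-five (", direction, ")")
  else strrep(sign_chr, 3)
}

fold_and_category <- function(ratio) {
  if (!is.finite(ratio) || ratio <= 0) {
    return(list(fold = NA_real_, category = NA_character_))
  }
  direction <- if (ratio >= 1) "increase" else "decrease"
  fold <- max(ratio, 1 / ratio)
  list(fold = fold, category = classify_fold_change(fold, direction))
}

#' One-at-a-time airway/alveoli parameter exchange analysis
#'
#' Re-simulates the probe protocol after swapping each exchangeable
#' parameter between the two regions (clearance is instead increased; see
#' [exchange_parameter()]) and reports the fold change of the regional AUC
#' relative to baseline, classified with [classify_fold_change()].
#'
#' @param lung A [lung_model()].
#' @param compound A [compound()]; defaults to the MTR fixture from the
#'   shipped library.
#' @param dose A [dose_spec()]; defaults to the probe protocol (IT, 1 mM in
#'   both lining fluids).
#' @param solver A [solver_spec()].
#' @param cl_factor Clearance multiplier (default 10).
#' @return data.frame of class `"exchange_table"`: parameter, AUC ratio to
#'   baseline, fold change and category, per region. The first row is the
#'   baseline itself (fold 1, "unaffected").
#' @export
parameter_exchange_analysis <- function(lung, compound = NULL,
                                        dose = dose_spec("IT", conc_mM = 1,
                                                         target = "both"),
                                        solver = solver_spec(),
                                        cl_factor = 10) {
  if (is.null(compound)) compound <- read_compound_library()$MTR
  probe_aucs <- function(model) {
    sim <- simulate_lung(model, compound, dose, solver)
    c(airways = auc_trapezoid(sim$times,
                              region_tissue_concentration(sim, "airways")),
      alveoli = auc_trapezoid(sim$times,
                              region_tissue_concentration(sim, "alveoli")))
  }
  base <- probe_aucs(lung)
  rows <- lapply(exchange_parameter_names(), function(param) {
    swapped <- exchange_parameter(lung, param, cl_factor = cl_factor)
    aucs <- probe_aucs(swapped)
    fa <- fold_and_category(aucs[["airways"]] / base[["airways"]])
    fv <- fold_and_category(aucs[["alveoli"]] / base[["alveoli"]])
    data.frame(parameter = param,
               auc_ratio_airways = aucs[["airways"]] / base[["airways"]],
               fold_airways = fa$fold, category_airways = fa$category,
               auc_ratio_alveoli = aucs[["alveoli"]] / base[["alveoli"]],
               fold_alveoli = fv$fold, category_alveoli = fv$category,
               stringsAsFactors = FALSE)
  })
  baseline_row <- data.frame(parameter = "Baseline",
                             auc_ratio_airways = 1, fold_airways = 1,
                             category_airways = "unaffected",
                             auc_ratio_alveoli = 1, fold_alveoli = 1,
                             category_alveoli = "unaffected",
                             stringsAsFactors = FALSE)
  out <- rbind(baseline_row, do.call(rbind, rows))
  class(out) <- c("exchange_table", class(out))
  out
}
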