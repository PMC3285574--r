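#' Trapezoidal area under a curve
#'
#' @param times Strictly increasing time points (min).
#' @param values Series values (e.g. tissue concentration, mg/ml).
#' @return AUC in value units x min.
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) < 2) {
    stop("insufficient data: AUC needs at least 2 points", call. = FALSE)
  }
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  dt <- diff(times)
  sum(0.5 * (values[-length(values)] + values[-1]) * dt)
}

region_ids <- function(result, region) {
  result$compartments$id[result$compartments$region == region]
}

#' Regional tissue concentration time series
#'
#' At each output time, the summed mass of every compartment anatomically in
#' the region (lining fluid, cells, mitochondria, interstitium and regional
#' blood) divided by the summed volume of those compartments. Systemic
#' venous/arterial blood is excluded.
#'
#' @param result A `pk_sim` from [simulate_lung()].
#' @param region `"airways"` or `"alveoli"`.
#' @return Numeric vector (mg/ml) along `result$times`.
#' @export
region_tissue_concentration <- function(result, region = c("airways", "alveoli")) {
  region <- match.arg(region)
  ids <- region_ids(result, region)
  vol <- sum(result$compartments$volume[result$compartments$id %in% ids])
  rowSums(result$amounts[, ids, drop = FALSE]) / vol
}

#' Percentage of whole-lung mass in one region
#'
#' `100 x region mass / (airway + alveolar mass)` at time `t`; systemic
#' blood is excluded from the denominator.
#'
#' @inheritParams region_tissue_concentration
#' @param t Time (min) within the simulated range.
#' @return Percentage in `[0, 100]`.
#' @export
mass_percent <- function(result, region = c("airways", "alveoli"), t) {
  region <- match.arg(region)
  stopifnot(t >= min(result$times), t <= max(result$times))
  masses <- vapply(c("airways", "alveoli"), function(r) {
    ids <- region_ids(result, r)
    series <- rowSums(result$amounts[, ids, drop = FALSE])
    stats::approx(result$times, series, xout = t)$y
  }, numeric(1))
  total <- sum(masses)
  if (total <= 0) {
    stop("whole-lung mass is zero at t = ", t, "; mass percent undefined",
         call. = FALSE)
  }
  100 * masses[[region]] / total
}

#' Airway-to-alveoli AUC ratio
#'
#' @param airway_result,alveoli_result `pk_sim` objects simulated over the
#'   same time horizon (for inhalation screening: the airway-dosed and
#'   alveoli-dosed runs).
#' @return `AUC_airways / AUC_alveoli` of the regional tissue concentration.
#' @export
auc_ratio <- function(airway_result, alveoli_result) {
  stopifnot(isTRUE(all.equal(range(airway_result$times),
                             range(alveoli_result$times))))
  auc_aw <- auc_trapezoid(airway_result$times,
                          region_tissue_concentration(airway_result, "airways"))
  auc_alv <- auc_trapezoid(alveoli_result$times,
                           region_tissue_concentration(alveoli_result, "alveoli"))
  if (auc_alv <= 0) {
    stop("degenerate simulation: alveolar AUC is zero", call. = FALSE)
  }
  auc_aw / auc_alv
}

#' Time to reach steady state
#'
#' First time after which the series stays within `(1 - fraction)` (relative)
#' of its terminal value. The convergence criterion requires the relative
#' drift over the last tenth of the series to be below `drift_tol`.
#'
#' @param times Time points (min).
#' @param values Series values.
#' @param fraction Steady-state fraction (default 0.95).
#' @param drift_tol Maximum relative drift of the tail (default 0.02).
#' @return Time in minutes.
#' @export
time_to_steady_state <- function(times, values, fraction = 0.95,
                                 drift_tol = 0.02) {
  stopifnot(length(times) == length(values), fraction > 0, fraction < 1)
  terminal <- values[length(values)]
  scale <- max(abs(values))
  if (scale == 0) return(times[1])
  tail_idx <- times >= times[1] + 0.9 * (times[length(times)] - times[1])
  drift <- max(abs(values[tail_idx] - terminal))
  if (drift > drift_tol * scale) {
    stop("series has not converged (tail drift ",
         format(drift / scale, digits = 3), " relative); no Tss",
         call. = FALSE)
  }
  band <- (1 - fraction) * max(abs(terminal), drift_tol * scale)
  outside <- abs(values - terminal) > band
  if (!any(outside)) return(times[1])
  last_out <- max(which(outside))
  if (last_out == length(times)) {
    stop("series has not entered the steady-state band; no Tss",
         call. = FALSE)
  }
  times[last_out + 1]
}

#' Summarize regional pharmacokinetic indexes of one simulation
#'
#' @param result A `pk_sim`.
#' @param fraction Steady-state fraction for Tss (default 0.95).
#' @return data.frame with one row per region: AUC over the simulated
#'   horizon, the horizon itself, final tissue concentration, mass percent at
#'   the end time, and Tss when the series has converged (`NA` otherwise).
#' @export
region_metrics <- function(result, fraction = 0.95) {
  t_end <- max(result$times)
  do.call(rbind, lapply(c("airways", "alveoli"), function(r) {
    conc <- region_tissue_concentration(result, r)
    tss <- tryCatch(time_to_steady_state(result$times, conc, fraction),
                    error = function(e) NA_real_)
    data.frame(
      region = r,
      auc = auc_trapezoid(result$times, conc),
      auc_horizon = t_end,
      final_concentration = conc[length(conc)],
      mass_percent_end = mass_percent(result, r, t_end),
      t_ss = tss,
      stringsAsFactors = FALSE)
  }))
}
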