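#' Define a solute for lung transport simulation
#'
#' A compound is described by its charge class and the physicochemical
#' properties that drive cellular pharmacokinetics: the octanol:water
#' partition coefficients of the neutral (`logPn`) and ionized (`logPd`)
#' species and, for monoprotic bases, the `pKa` of the conjugate acid.
#'
#' @param name Character label.
#' @param charge_class One of `"monoprotic_base"`, `"permanent_cation"`,
#'   `"neutral"`.
#' @param logPn log10 octanol:water partition coefficient of the neutral
#'   species. Unused (may be `NA`) for permanent cations.
#' @param logPd log10 partition coefficient of the ionized species. If `NA`
#'   for a base it is derived as `logPn - logPd_offset` (see
#'   [derive_logPd()]). Required for permanent cations.
#' @param pKa Acid dissociation constant of the conjugate acid. Required for
#'   monoprotic bases, ignored otherwise.
#' @param z Valence of the ionized species (default +1).
#' @param mw Molecular weight in mg/mmol; only needed for dosing modes that
#'   specify a molar concentration.
#' @param logPd_offset Offset used when `logPd` must be derived (default 3.5).
#'
#' @return An object of class `"compound"`.
#' @examples
#' hoe <- compound("Hoe", "monoprotic_base", logPn = 4.49, pKa = 7.8)
#' mtr <- compound("MTR", "permanent_cation", logPd = 0.16)
#' @export
compound <- function(name, charge_class = c("monoprotic_base",
                                            "permanent_cation", "neutral"),
                     logPn = NA_real_, logPd = NA_real_, pKa = NA_real_,
                     z = 1L, mw = NA_real_, logPd_offset = 3.5) {
  charge_class <- match.arg(charge_class)
  if (charge_class == "monoprotic_base") {
    if (!is.finite(pKa)) {
      stop("invalid compound '", name, "': a monoprotic base requires a ",
           "finite pKa", call. = FALSE)
    }
    if (!is.finite(logPn)) {
      stop("invalid compound '", name, "': a monoprotic base requires a ",
           "finite logPn", call. = FALSE)
    }
    if (!is.finite(logPd)) logPd <- derive_logPd(logPn, logPd_offset)
    if (logPd > logPn + 1e-12) {
      stop("invalid compound '", name, "': logPd must not exceed logPn",
           call. = FALSE)
    }
  } else if (charge_class == "permanent_cation") {
    if (!is.finite(logPd)) {
      stop("invalid compound '", name, "': a permanent cation requires a ",
           "finite logPd", call. = FALSE)
    }
    logPn <- NA_real_
    pKa <- NA_real_
  } else { # neutral
    if (!is.finite(logPn)) {
      stop("invalid compound '", name, "': a neutral compound requires a ",
           "finite logPn", call. = FALSE)
    }
    logPd <- NA_real_
    pKa <- NA_real_
    z <- 0L
  }
  structure(list(name = as.character(name), charge_class = charge_class,
                 logPn = logPn, logPd = logPd, pKa = pKa,
                 z = as.integer(z), mw = mw),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat("<compound> ", x$name, " (", x$charge_class, ")\n", sep = "")
  cat("  logPn = ", format(x$logPn), ", logPd = ", format(x$logPd),
      ", pKa = ", format(x$pKa), ", z = ", x$z, "\n", sep = "")
  invisible(x)
}

#' Fraction of a compound in the neutral form at a given pH
#'
#' Henderson-Hasselbalch partition between the neutral and protonated
#' species. Permanent cations have no neutral species (fraction 0); neutral
#' compounds have no ionized species (fraction 1).
#'
#' @param compound A [compound()].
#' @param pH Compartment pH (0-14).
#' @return Fraction in `[0, 1]`.
#' @export
neutral_fraction <- function(compound, pH) {
  stopifnot(all(pH >= 0 & pH <= 14))
  switch(compound$charge_class,
    monoprotic_base = {
      if (!is.finite(compound$pKa)) {
        stop("invalid compound: monoprotic base without pKa", call. = FALSE)
      }
      1 / (1 + 10^(compound$pKa - pH))
    },
    permanent_cation = rep(0, length(pH)),
    neutral = rep(1, length(pH))
  )
}

#' Derive logPd of the ionized species from logPn
#'
#' The partition coefficient of a monovalent ionized species is taken as a
#' fixed offset below that of the neutral species, the standard assumption in
#' cell-based partitioning models when no measured value is supplied.
#'
#' @param logPn log10 partition coefficient of the neutral species.
#' @param offset Offset in log10 units (default 3.5).
#' @return `logPn - offset`.
#' @export
derive_logPd <- function(logPn, offset = 3.5) {
  stopifnot(is.finite(logPn))
  logPn - offset
}

#' Free (unbound aqueous) fraction of a species in a compartment
#'
#' Lipid binding is modeled as an instantaneous equilibrium between the
#' aqueous and lipid sub-volumes of a compartment, so the fraction of a
#' species dissolved free in water is `f_w / (f_w + f_l * 10^logP)`.
#'
#' @param compound A [compound()].
#' @param compartment A list or one-row data.frame with `f_w` (aqueous
#'   fraction, > 0) and `f_l` (lipid fraction, >= 0).
#' @param species `"neutral"` or `"ion"`.
#' @return Fraction in `(0, 1]`.
#' @export
free_fraction <- function(compound, compartment, species = c("neutral", "ion")) {
  species <- match.arg(species)
  f_w <- compartment$f_w
  f_l <- compartment$f_l
  if (any(!is.finite(f_w)) || any(f_w <= 0)) {
    stop("invalid compartment: aqueous fraction f_w must be > 0",
         call. = FALSE)
  }
  stopifnot(all(f_l >= 0), all(f_w + f_l <= 1 + 1e-9))
  logP <- if (species == "neutral") compound$logPn else compound$logPd
  if (!is.finite(logP)) {
    stop("compound '", compound$name, "' has no ", species, " species",
         call. = FALSE)
  }
  f_w / (f_w + f_l * 10^logP)
}

#' Species partition of a compound in a compartment
#'
#' Combines the Henderson-Hasselbalch ionization equilibrium with the
#' free-fraction binding equilibrium of each species.
#'
#' @inheritParams free_fraction
#' @param pH Compartment pH; defaults to `compartment$pH`.
#' @return A list with `f_neutral`, `f_ion`, `f_free_neutral`, `f_free_ion`
#'   (the latter two are `NA` for species that do not exist).
#' @export
species_partition <- function(compound, compartment, pH = compartment$pH) {
  f_n <- neutral_fraction(compound, pH)
  has_n <- compound$charge_class != "permanent_cation"
  has_i <- compound$charge_class != "neutral"
  list(
    f_neutral = f_n,
    f_ion = 1 - f_n,
    f_free_neutral = if (has_n) free_fraction(compound, compartment, "neutral") else NA_real_,
    f_free_ion = if (has_i) free_fraction(compound, compartment, "ion") else NA_real_
  )
}

#' Read a compound library from CSV
#'
#' The CSV must have columns `name`, `charge_class`, `logPn`, `logPd`,
#' `pKa`, `z` and optionally `mw`. Blank `logPd` for a base means "derive
#' from logPn"; blank `pKa` is allowed for non-bases.
#'
#' @param path Path to a CSV file. Defaults to the library shipped with the
#'   package, which contains the two fluorescent-probe fixtures: MTR
#'   (MitoTracker-like permanent cation, logPd 0.16) and Hoe (Hoechst-like
#'   lipophilic base, logPn 4.49, pKa 7.8).
#' @param logPd_offset Passed to [compound()].
#' @return Named list of [compound()] objects.
#' @export
read_compound_library <- function(path = system.file("extdata", "compounds.csv",
                                                     package = "pulmocell"),
                                  logPd_offset = 3.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "charge_class", "logPn", "logPd", "pKa", "z")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("compound library ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"mw" %in% names(df)) df$mw <- NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    compound(df$name[i], df$charge_class[i],
             logPn = as.numeric(df$logPn[i]), logPd = as.numeric(df$logPd[i]),
             pKa = as.numeric(df$pKa[i]), z = as.integer(df$z[i]),
             mw = as.numeric(df$mw[i]), logPd_offset = logPd_offset)
  })
  names(out) <- df$name
  out
}
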