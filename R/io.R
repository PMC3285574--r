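default_config_path <- function() {
  system.file("extdata", "lung_default.yaml", package = "pulmocell")
}

deep_merge <- function(base, override) {
  if (is.null(override)) return(base)
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- deep_merge(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load and validate a lung configuration
#'
#' Reads the shipped default configuration and, when `path` is given, merges
#' the user's YAML document over it (an empty file yields the complete
#' defaults). Unknown keys, wrong types and inconsistent values are rejected
#' with the offending key named.
#'
#' @param path Optional path to a YAML (or JSON) configuration file.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  config <- yaml::read_yaml(default_config_path())
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (!is.null(user) && !is.list(user)) {
      stop("config file ", path, " does not parse to a mapping",
           call. = FALSE)
    }
    config <- deep_merge(config, user)
  }
  validate_lung_config(config)
  config
}

#' Write a configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Stable fingerprint of a configuration
#'
#' MD5 digest of the canonical YAML serialization; identical configurations
#' always yield identical fingerprints, providing provenance for result
#' files.
#'
#' @param config Configuration list.
#' @return Character scalar (32 hex digits).
#' @export
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

#' Write a simulation result as tidy CSV with a JSON metadata sidecar
#'
#' One row per (time, compartment) with region, role, mass and
#' concentration; the sidecar (`<path>.json`) records compound, dose, solver
#' settings and the lung config fingerprint.
#'
#' @param result A `pk_sim` from [simulate_lung()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  comps <- result$compartments
  long <- do.call(rbind, lapply(seq_len(nrow(comps)), function(i) {
    data.frame(time = result$times,
               compartment = comps$id[i],
               region = comps$region[i],
               role = comps$role[i],
               amount_mg = result$amounts[, comps$id[i]],
               concentration_mg_per_ml = result$amounts[, comps$id[i]] /
                 comps$volume[i],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$time, match(long$compartment, comps$id)), ]
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(
    compound = result$compound[c("name", "charge_class", "logPn", "logPd",
                                 "pKa", "z", "mw")],
    dose = unclass(result$dose),
    solver = unclass(result$solver),
    lung_fingerprint = result$lung_fingerprint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a screen result as long-format CSV
#'
#' @param screen A `screen_result` from [run_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  metric_cols <- setdiff(names(screen), c("logPn", "pKa"))
  long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(logPn = screen$logPn, pKa = screen$pKa, metric = mc,
               value = screen[[mc]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      stop("malformed argument: ", a, call. = FALSE)
    }
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      flags[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  flags
}

cli_usage <- function() {
  paste(
    "usage: pulmocell <mode> [flags]",
    "  simulate --compound NAME --route IT|IV [--config FILE] [--out DIR]",
    "           [--target airways|alveoli|both] [--conc-mM X | --dose-mg-kg X]",
    "           [--t-end MIN]",
    "  screen   --route IT|IV [--grid lmin,lmax,lstep,pmin,pmax,pstep]",
    "           [--config FILE] [--out DIR] [--t-end MIN]",
    "  exchange [--compound NAME] [--config FILE] [--out DIR] [--t-end MIN]",
    sep = "\n")
}

#' Command-line entry point
#'
#' Thin shell over the package functions; see `inst/scripts/pulmocell` for
#' the Rscript wrapper. Writes CSV results with JSON sidecars plus a run log
#' into the output directory.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) < 1 ||
        !argv[1] %in% c("simulate", "screen", "exchange")) {
      message(cli_usage())
      return(invisible(1L))
    }
    mode <- argv[1]
    flags <- parse_cli_flags(argv[-1])
    config <- load_config(flags$config)
    lung <- lung_model(config)
    out_dir <- if (is.null(flags$out)) "." else flags$out
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    t_end <- if (is.null(flags[["t-end"]])) 240 else
      as.numeric(flags[["t-end"]])
    solver <- solver_spec(t_end = t_end)
    t0 <- proc.time()[["elapsed"]]
    log_lines <- c(sprintf("mode: %s", mode),
                   sprintf("config fingerprint: %s",
                           config_fingerprint(config)))

    if (mode == "simulate") {
      lib <- read_compound_library()
      if (is.null(flags$compound) || !flags$compound %in% names(lib)) {
        message("unknown compound: ", flags$compound %||% "<missing>",
                "\n", cli_usage())
        return(invisible(1L))
      }
      cmpd <- lib[[flags$compound]]
      route <- match.arg(flags$route %||% "IT", c("IT", "IV"))
      dose <- if (!is.null(flags[["dose-mg-kg"]])) {
        dose_spec(route, amount_mg_per_kg = as.numeric(flags[["dose-mg-kg"]]),
                  target = flags$target %||% "both")
      } else {
        dose_spec(route, conc_mM = as.numeric(flags[["conc-mM"]] %||% "1"),
                  target = flags$target %||% "both")
      }
      sim <- simulate_lung(lung, cmpd, dose, solver)
      out_csv <- file.path(out_dir,
                           sprintf("simulate_%s_%s.csv", cmpd$name, route))
      write_result_csv(sim, out_csv)
      utils::write.csv(region_metrics(sim),
                       file.path(out_dir, sprintf("metrics_%s_%s.csv",
                                                  cmpd$name, route)),
                       row.names = FALSE)
      log_lines <- c(log_lines, sprintf("wrote %s", out_csv))
    } else if (mode == "screen") {
      route <- match.arg(flags$route %||% "IT", c("IT", "IV"))
      grid <- if (is.null(flags$grid)) screen_grid() else {
        g <- as.numeric(strsplit(flags$grid, ",")[[1]])
        if (length(g) != 6 || anyNA(g)) {
          message("malformed --grid (need 6 numbers)\n", cli_usage())
          return(invisible(1L))
        }
        screen_grid(g[1], g[2], g[3], g[4], g[5], g[6])
      }
      scr <- run_screen(lung, grid, route = route, solver = solver)
      out_csv <- file.path(out_dir, sprintf("screen_%s.csv", route))
      write_screen_csv(scr, out_csv)
      log_lines <- c(log_lines,
                     sprintf("screen points: %d", nrow(scr)),
                     sprintf("failures: %d",
                             length(attr(scr, "failures"))),
                     sprintf("wrote %s", out_csv))
    } else { # exchange
      lib <- read_compound_library()
      cmpd <- lib[[flags$compound %||% "MTR"]]
      if (is.null(cmpd)) {
        message("unknown compound: ", flags$compound, "\n", cli_usage())
        return(invisible(1L))
      }
      tab <- parameter_exchange_analysis(lung, cmpd, solver = solver)
      out_csv <- file.path(out_dir, "exchange_table.csv")
      utils::write.csv(tab, out_csv, row.names = FALSE)
      log_lines <- c(log_lines, sprintf("wrote %s", out_csv))
    }

    log_lines <- c(log_lines,
                   sprintf("elapsed_s: %.2f",
                           proc.time()[["elapsed"]] - t0))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    message(paste(log_lines, collapse = "\n"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e), "\n", cli_usage())
    1L
  })
  invisible(as.integer(status))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
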