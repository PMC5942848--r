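#' Run configuration
#'
#' A validated bundle of every tunable the analysis pipeline takes, with
#' defaults at the package's standard values (K_T = 1 uM, TRD_max = 0.4
#' pgN um^-2 d^-1, KQ = 10, KT_con = 0.1, N:C 0.05-0.18 gN gC^-1,
#' G_max = 0.693 d^-1, and the standard seawater constants). Configurations
#' can be read from and written to JSON or YAML files; unknown keys are
#' rejected so that typos fail loudly rather than silently reverting to
#' defaults.
#'
#' @param organism named list: `ESD` (um), `carbon_model` (preset name),
#'   `motion`, `tmax_mode`.
#' @param stoichiometry named list: `NC_max`, `NC_min`, `KQ`, `G_max`.
#' @param transporter named list: `K_T`, `TRD_max`, `KT_con`.
#' @param environment named list: `D`, `eta`, `rho_org`, `rho_w`, `g`,
#'   `molar_mass_N`.
#' @param scan named list: `esd_min`, `esd_max`, `n`.
#' @param seed integer seed for the synthetic generators.
#' @return An object of class `nutrikin_config` (a nested named list).
#' @examples
#' cfg <- run_config(organism = list(ESD = 10, carbon_model = "C150"))
#' cfg$transporter$K_T
#' @export
run_config <- function(organism = list(), stoichiometry = list(),
                       transporter = list(), environment = list(),
                       scan = list(), seed = 1L) {
  defaults <- list(
    organism = list(ESD = 10, carbon_model = "Cprot", motion = "none",
                    tmax_mode = "eq5"),
    stoichiometry = list(NC_max = 0.18, NC_min = 0.05, KQ = 10,
                         G_max = 0.693),
    transporter = list(K_T = 1, TRD_max = 0.4, KT_con = 0.1),
    environment = list(D = 1.5e-9, eta = 1.0846e-3, rho_org = 1.0634,
                       rho_w = 1.033, g = 9.8, molar_mass_N = 14),
    scan = list(esd_min = 2, esd_max = 80, n = 25)
  )
  user <- list(organism = organism, stoichiometry = stoichiometry,
               transporter = transporter, environment = environment,
               scan = scan)
  cfg <- purrr::imap(defaults, function(block, name) {
    u <- user[[name]]
    unknown <- setdiff(names(u), names(block))
    if (length(unknown) > 0) {
      abort(sprintf("run_config: unknown key(s) in '%s' block: %s",
                    name, paste(unknown, collapse = ", ")))
    }
    utils::modifyList(block, u)
  })
  cfg$seed <- as.integer(seed)
  cfg <- validate_config(cfg)
  structure(cfg, class = "nutrikin_config")
}

validate_config <- function(cfg) {
  # constructors are the schema: they raise on invalid values
  as_environment(cfg)
  quota_params(NC_max = cfg$stoichiometry$NC_max,
               NC_min = cfg$stoichiometry$NC_min,
               KQ = cfg$stoichiometry$KQ,
               G_max = cfg$stoichiometry$G_max)
  transporter_params(K_T = cfg$transporter$K_T,
                     TRD_max = cfg$transporter$TRD_max,
                     KT_con = cfg$transporter$KT_con)
  if (cfg$organism$ESD <= 0) abort("run_config: organism ESD must be > 0.")
  if (!cfg$organism$carbon_model %in% c("C150", "Cprot", "Cdiat")) {
    abort("run_config: carbon_model must be one of C150, Cprot, Cdiat.")
  }
  if (!cfg$organism$motion %in% c("none", "swim", "sink")) {
    abort("run_config: motion must be one of none, swim, sink.")
  }
  if (!cfg$organism$tmax_mode %in% c("eq5", "flat")) {
    abort("run_config: tmax_mode must be 'eq5' or 'flat' in a config file.")
  }
  with(cfg$scan, {
    if (!(esd_min > 0 && esd_max > esd_min && n >= 2)) {
      abort("run_config: scan requires 0 < esd_min < esd_max and n >= 2.")
    }
  })
  cfg
}

#' @export
print.nutrikin_config <- function(x, ...) {
  cat("<run config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read / write run configurations
#'
#' `read_run_config()` loads a JSON or YAML configuration file (dispatch on
#' file extension), validates it against the schema and fills unset keys with
#' the package defaults; an empty file yields the all-defaults configuration.
#' `write_run_config()` serializes a configuration to JSON (or YAML), such
#' that `read_run_config(write_run_config(cfg, path))` round-trips exactly.
#'
#' @param path file path; extension `.json`, `.yaml` or `.yml`.
#' @return `read_run_config()`: a [run_config()] object.
#'   `write_run_config()`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort("read_run_config: expected a .json, .yaml or .yml file.")
  }
  if (is.null(raw) || length(raw) == 0) return(run_config())
  known <- c("organism", "stoichiometry", "transporter", "environment",
             "scan", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("read_run_config: unknown top-level key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  run_config(organism = raw$organism %||% list(),
             stoichiometry = raw$stoichiometry %||% list(),
             transporter = raw$transporter %||% list(),
             environment = raw$environment %||% list(),
             scan = raw$scan %||% list(),
             seed = raw$seed %||% 1L)
}

#' @rdname read_run_config
#' @param cfg a [run_config()] object.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "nutrikin_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize configuration blocks
#'
#' Helpers turning a [run_config()] into the package's working objects.
#'
#' @param cfg a [run_config()] object (or the equivalent named list).
#' @return `as_environment()`: a [marine_environment()];
#'   `as_organism()`: an [organism()].
#' @examples
#' cfg <- run_config(organism = list(ESD = 10, carbon_model = "C150"))
#' as_organism(cfg)
#' @export
as_environment <- function(cfg) {
  do.call(marine_environment, cfg$environment)
}

#' @rdname as_environment
#' @export
as_organism <- function(cfg) {
  organism(ESD = cfg$organism$ESD,
           carbon = carbon_model(cfg$organism$carbon_model),
           motion = cfg$organism$motion,
           quota = quota_params(NC_max = cfg$stoichiometry$NC_max,
                                NC_min = cfg$stoichiometry$NC_min,
                                KQ = cfg$stoichiometry$KQ,
                                G_max = cfg$stoichiometry$G_max),
           transporter = transporter_params(K_T = cfg$transporter$K_T,
                                            TRD_max = cfg$transporter$TRD_max,
                                            KT_con = cfg$transporter$KT_con),
           tmax_mode = cfg$organism$tmax_mode,
           env = as_environment(cfg))
}
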