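#' Default assessment configuration
#'
#' The full configuration as a plain list, mirroring the YAML schema read by
#' [read_config()]. Top-level keys: `screening_value` (mg/kg),
#' `toxic_response_coefficient` (Tn), `background` (`national_default`,
#' `per_province`), `area_map` (province -> area; empty means the shipped
#' [default_area_map()]), `receptors` (per-group exposure parameters),
#' `toxicity` (reference doses), `pathways`, `mc` (`n_iter`, `seed`,
#' `params` of distribution specs), `trend` (`degree`, `log_base`).
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    screening_value = 2500,
    toxic_response_coefficient = 2,
    background = list(national_default = 61,
                      per_province = list()),
    area_map = list(),
    receptors = lapply(default_receptors(), function(p)
      unclass(p)[setdiff(names(unclass(p)), "group")]),
    toxicity = unclass(toxicity_params()),
    pathways = c("ing", "derm", "inh"),
    mc = list(n_iter = 10000, seed = 1, params = list()),
    trend = list(degree = 2, log_base = "log10")
  )
}

.modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- .modify_list(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

.parse_dist <- function(x, name) {
  if (inherits(x, "cr_dist")) return(x)
  if (!is.list(x) || is.null(x$kind)) {
    stop_config("mc parameter '%s' must have a 'kind' field", name)
  }
  trunc <- if (!is.null(x$truncation)) unlist(x$truncation)
  args <- x[setdiff(names(x), c("kind", "truncation"))]
  do.call(dist_spec, c(list(kind = x$kind), args, list(truncation = trunc)))
}

#' Read (or assemble) an assessment configuration
#'
#' Reads a YAML config document, fills every omitted field from
#' [default_config()] (noting on stderr when the screening value falls back
#' to the 2500 mg/kg default), validates it, and materialises the typed
#' sub-objects used by the pipeline.
#'
#' @param path Path to a YAML file, a named list (already-parsed config), or
#'   `NULL` for the pure defaults.
#' @return Object of class `cr_config`: list with `screening_value`, `tn`,
#'   `background` ([background_table()]), `area_map`, `receptors`,
#'   `toxicity`, `pathways`, `mc` ([mc_spec()]), `trend`, and `raw` (the
#'   merged plain list).
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else if (is.character(path)) {
    if (!file.exists(path)) stop_config("config file not found: %s", path)
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop_config("cannot parse config YAML: %s",
                                             conditionMessage(e)))
  } else if (is.list(path)) {
    path
  } else {
    stop_config("config must be a YAML path, a list, or NULL")
  }
  if (is.null(user)) user <- list()
  if (is.null(user$screening_value) && length(user) > 0) {
    message("config: no screening_value given; using the 2500 mg/kg default")
  }
  cfg <- .modify_list(default_config(), user)

  if (!is.numeric(cfg$screening_value) || cfg$screening_value <= 0) {
    stop_config("screening_value must be positive")
  }
  if (!is.numeric(cfg$toxic_response_coefficient) ||
      cfg$toxic_response_coefficient <= 0) {
    stop_config("toxic_response_coefficient must be positive")
  }
  background <- background_table(
    per_province = unlist(cfg$background$per_province),
    national_default = cfg$background$national_default)

  area_map <- if (length(cfg$area_map) > 0) {
    unlist(cfg$area_map)
  } else {
    default_area_map()
  }
  bad <- setdiff(unique(area_map), hotspot_areas)
  if (length(bad) > 0) {
    stop_config("area_map contains unknown area label(s): %s",
                paste(bad, collapse = ", "))
  }

  receptors <- lapply(names(cfg$receptors), function(g)
    do.call(receptor_profile, c(list(group = g), cfg$receptors[[g]])))
  names(receptors) <- names(cfg$receptors)

  toxicity <- do.call(toxicity_params, cfg$toxicity[c("rfd_ing", "rfd_derm",
                                                      "rfd_inh")])
  pathways <- match.arg(cfg$pathways, c("ing", "derm", "inh"),
                        several.ok = TRUE)
  mc_params <- lapply(names(cfg$mc$params), function(nm)
    .parse_dist(cfg$mc$params[[nm]], nm))
  names(mc_params) <- names(cfg$mc$params)
  mc <- mc_spec(n_iter = cfg$mc$n_iter, seed = cfg$mc$seed,
                params = mc_params)

  structure(list(
    screening_value = cfg$screening_value,
    tn = cfg$toxic_response_coefficient,
    background = background,
    area_map = area_map,
    receptors = receptors,
    toxicity = toxicity,
    pathways = pathways,
    mc = mc,
    trend = cfg$trend,
    raw = cfg
  ), class = "cr_config")
}

#' @export
print.cr_config <- function(x, ...) {
  cat("crsoil assessment configuration\n")
  cat(sprintf("  screening value: %g mg/kg; Tn = %g\n",
              x$screening_value, x$tn))
  print(x$background)
  cat(sprintf("  receptors: %s\n", paste(names(x$receptors), collapse = ", ")))
  cat(sprintf("  MC: %d iterations, seed %d, %d stochastic parameter(s)\n",
              x$mc$n_iter, x$mc$seed, length(x$mc$params)))
  invisible(x)
}
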