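# Config (de)serialization as flat dotted key-value files (YAML or JSON)
# and result writing with a reproducibility sidecar.

#' Flatten a parameter set to dotted keys
#'
#' @param params A [cii_parameters()] object.
#' @return Named list of scalars with keys like `k.1`, `keq.8a`,
#'   `em.fes3`, `pool.q`, `clamp.fum`, `mode.direction`,
#'   `flags.linked_q_binding`.
#' @export
flatten_parameters <- function(params) {
  p <- unclass(params)
  out <- list()
  for (grp in c("k", "keq", "em")) {
    v <- p[[grp]]
    out[paste0(grp, ".", names(v))] <- as.list(unname(v))
  }
  out[paste0("pool.", names(p$pools))] <- as.list(unname(p$pools))
  out[paste0("clamp.", names(p$clamp))] <- as.list(unname(p$clamp))
  out$vmax27 <- p$vmax27
  out$km27 <- p$km27
  out$rt_over_f <- p$rt_over_f
  out$keq1_keq11_product <- p$keq1_keq11_product
  out$mode.direction <- p$mode$direction
  out$mode.quinone <- p$mode$quinone
  out$flags.linked_q_binding <- p$flags$linked_q_binding
  out$flags.thermo_validated <- p$flags$thermo_validated
  out$meta.preset <- p$meta$preset
  out
}

unflatten_parameters <- function(flat) {
  values <- list(k = c(), keq = c(), em = c(), pools = c(), clamp = c(),
                 mode = list(), flags = list(), meta = list())
  for (key in names(flat)) {
    val <- flat[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    grp <- parts[1]
    sub <- if (length(parts) > 1) paste(parts[-1], collapse = ".") else NA
    if (grp %in% c("k", "keq", "em") && !is.na(sub)) {
      values[[grp]][sub] <- as.numeric(val)
    } else if (grp == "pool" && !is.na(sub)) {
      values$pools[sub] <- as.numeric(val)
    } else if (grp == "clamp" && !is.na(sub)) {
      values$clamp[sub] <- as.numeric(val)
    } else if (grp == "mode" && !is.na(sub)) {
      values$mode[[sub]] <- val
    } else if (grp == "flags" && !is.na(sub)) {
      values$flags[[sub]] <- isTRUE(val) || identical(val, "true")
    } else if (grp == "meta" && !is.na(sub)) {
      values$meta[[sub]] <- val
    } else if (key %in% c("vmax27", "km27", "rt_over_f",
                          "keq1_keq11_product")) {
      values[[key]] <- as.numeric(val)
    } else {
      stop("unknown key '", key, "' in parameter config")
    }
  }
  values[vapply(values, length, integer(1)) > 0]
}

#' Load a parameter set from a preset name or config file
#'
#' A bare preset name resolves through [cii_preset()]; a path ending in
#' `.yaml`/`.yml`/`.json` is parsed as a flat dotted-key config (see
#' [flatten_parameters()]).  A config may carry `meta.preset`; explicit
#' keys override the preset's values, and any derived equilibrium
#' constants not present in the file are filled by thermodynamic-cycle
#' closure.  Unknown keys are errors naming the key.
#'
#' @param source Preset name or file path.
#' @param overrides Optional override list applied last: either the nested
#'   structure of [modify_parameters()] or a flat dotted-key list
#'   (`list("keq.1" = 10, "clamp.fum" = 1000)`).
#' @return A `cii_parameters` object.
#' @export
load_parameters <- function(source, overrides = NULL) {
  if (!is.null(overrides) && any(grepl(".", names(overrides), fixed = TRUE)))
    overrides <- unflatten_parameters(overrides)
  if (!grepl("\\.(ya?ml|json)$", source)) {
    p <- cii_preset(source)
  } else {
    if (!file.exists(source)) stop("config file not found: ", source)
    flat <- if (grepl("\\.json$", source))
      jsonlite::read_json(source, simplifyVector = FALSE)
    else
      yaml::read_yaml(source)
    values <- unflatten_parameters(flat)
    p <- cii_parameters(values)
    if (!is.null(values$flags$linked_q_binding) &&
        values$flags$linked_q_binding)
      p <- set_keq1(p, p$keq[["1"]])
  }
  if (!is.null(overrides)) p <- modify_parameters(p, overrides)
  p
}

#' Save a parameter set to a config file
#'
#' @param params A `cii_parameters` object.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  flat <- flatten_parameters(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path, precision = 17)
  }
  invisible(path)
}

#' Write result tables with a reproducibility sidecar
#'
#' Writes each table as CSV (fixed column order, full-precision floats)
#' and a JSON sidecar recording the exactly resolved parameter set and the
#' package version, so the run can be reproduced bit-identically.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @param params The resolved `cii_parameters` used for the run.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, path, params = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  sidecar <- list(
    package = "sdhkin",
    version = as.character(utils::packageVersion("sdhkin")),
    parameters = if (is.null(params)) NULL else flatten_parameters(params))
  f <- file.path(path, "run_manifest.json")
  jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, f))
}
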