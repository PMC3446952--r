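#' Parameter registry for the retinol carrier-protein system
#'
#' A `parameter_set` collects the concentrations and dissociation constants
#' that drive every stage of the analysis.  All concentrations are in
#' micromolar (umol/L); Kd4/Kd5 carry an explicit unit field because the
#' literature reports them both in umol/L and in nmol/L (see
#' [set_kd45_unit()]).
#'
#' Default values (cytoplasmic/plasma pools):
#' \describe{
#'   \item{rt_total}{total retinol, 1.73 (SD 0.34) umol/L}
#'   \item{p1_total}{total RBP4, 3.23 (SD 0.62) umol/L}
#'   \item{p2_total}{total prealbumin (transthyretin, TTR), 4.91 (SD 1.27) umol/L}
#'   \item{p3_total, p4_total, ra_total}{CRABP1, CRABP2 and retinoic-acid
#'     totals; no literature defaults exist, so they default to `NA` and must
#'     be supplied by the user before the RA side of the network is built}
#'   \item{kd1}{retinol-RBP4 dissociation, 0.664 umol/L (alternate 0.20,
#'     recombinant protein)}
#'   \item{kd2}{holo-RBP-TTR dissociation, 0.075 (SD 0.015) umol/L}
#'   \item{kd3}{apo-RBP-TTR dissociation, 0.33 (SD 0.11) umol/L (alternate
#'     0.4, recombinant TTR)}
#'   \item{kd4, kd5}{retinoic acid vs CRABP1/CRABP2, 0.06 and 0.13; unit
#'     switchable between umol/L (default) and nmol/L}
#' }
#'
#' Molecular weights are stored in Da (the source table prints "kDa" where Da
#' is chemically required, e.g. retinol at 286 Da, and the values are kept as
#' daltons here).
#'
#' @param ... named numeric overrides of the defaults, e.g. `p1_total = 2.26`.
#' @param alternates character vector of constants to switch to their named
#'   literature alternate; currently `"kd1"` (0.20, recombinant RBP) and
#'   `"kd3"` (0.4, recombinant TTR).
#' @return an object of class `parameter_set`.
#' @examples
#' p <- parameter_set()
#' p$rt_total              # 1.73
#' parameter_set(p1_total = 2.26)$p1_total
#' parameter_set(alternates = "kd1")$kd1   # 0.20
#' @seealso [load_parameters()] for reading overrides from JSON/YAML,
#'   [dump_registry()] for a machine-readable export.
#' @export
parameter_set <- function(..., alternates = character()) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  defaults <- list(
    rt_total = 1.73, p1_total = 3.23, p2_total = 4.91,
    p3_total = NA_real_, p4_total = NA_real_, ra_total = NA_real_,
    kd1 = 0.664, kd2 = 0.075, kd3 = 0.33, kd4 = 0.06, kd5 = 0.13
  )
  sds <- c(rt_total = 0.34, p1_total = 0.62, p2_total = 1.27,
           kd2 = 0.015, kd3 = 0.11)
  alternate_values <- c(kd1 = 0.20, kd3 = 0.4)

  bad_alt <- setdiff(alternates, names(alternate_values))
  if (length(bad_alt)) {
    abort_validation(sprintf(
      "no literature alternate for: %s (available: %s)",
      paste(bad_alt, collapse = ", "),
      paste(names(alternate_values), collapse = ", ")))
  }

  values <- defaults
  provenance <- stats::setNames(rep("table4-default", length(defaults)),
                                names(defaults))
  for (nm in alternates) {
    values[[nm]] <- alternate_values[[nm]]
    provenance[[nm]] <- "table4-alternate"
  }

  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort_validation(sprintf(
      "unknown parameter(s): %s\nvalid keys: %s",
      paste(unknown, collapse = ", "),
      paste(names(defaults), collapse = ", ")))
  }
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1L) {
      abort_validation(sprintf("'%s' must be a single number", nm))
    }
    values[[nm]] <- as.numeric(v)
    provenance[[nm]] <- "user"
  }

  obj <- structure(
    c(values, list(
      sd = sds,
      mw = c(retinol = 286, rbp4 = 21000, ttr = 55000, ternary = 55286),
      kd45_unit = "umol/L",
      provenance = provenance
    )),
    class = "parameter_set"
  )
  validate_parameters(obj)
  obj
}

numeric_parameter_names <- function() {
  c("rt_total", "p1_total", "p2_total", "p3_total", "p4_total", "ra_total",
    "kd1", "kd2", "kd3", "kd4", "kd5")
}

#' Validate a parameter set
#'
#' Checks non-negativity of all concentrations, dissociation constants and
#' standard deviations.  Called by every constructor; exported so that
#' hand-edited objects can be re-checked.
#'
#' @param params a `parameter_set`.
#' @return `params`, invisibly, if valid; otherwise a validation error naming
#'   the offending field.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "parameter_set")) {
    abort_validation("expected a 'parameter_set' object")
  }
  for (nm in numeric_parameter_names()) {
    v <- params[[nm]]
    if (is.na(v)) next  # absent optional totals
    if (!is.numeric(v) || v < 0) {
      abort_validation(sprintf("parameter '%s' must be >= 0, got %s",
                               nm, format(v)))
    }
  }
  if (any(params$sd < 0, na.rm = TRUE)) {
    abort_validation("standard deviations must be >= 0")
  }
  if (!params$kd45_unit %in% c("umol/L", "nmol/L")) {
    abort_validation("kd45_unit must be 'umol/L' or 'nmol/L'")
  }
  invisible(params)
}

#' Load parameters, optionally overridden from a JSON or YAML config file
#'
#' The config is a flat name->value map; unknown keys are hard errors so that
#' a typo cannot silently leave a constant at its default.
#'
#' @param source path to a `.json`, `.yaml`/`.yml` file, or `NULL` for pure
#'   defaults.
#' @param alternates passed to [parameter_set()].
#' @return a `parameter_set`.
#' @examples
#' load_parameters()$kd3   # 0.33
#' @export
load_parameters <- function(source = NULL, alternates = character()) {
  overrides <- list()
  if (!is.null(source)) {
    if (!file.exists(source)) {
      abort_validation(sprintf("config file not found: %s", source))
    }
    ext <- tolower(tools::file_ext(source))
    overrides <- switch(ext,
      json = jsonlite::read_json(source, simplifyVector = TRUE),
      yaml = ,
      yml = {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          abort_validation("the 'yaml' package is required for YAML configs")
        }
        yaml::read_yaml(source)
      },
      abort_validation(sprintf("unsupported config format '.%s' (use .json/.yaml)",
                               ext))
    )
    if (is.null(overrides)) overrides <- list()
    overrides <- as.list(overrides)
  }
  do.call(parameter_set, c(overrides, list(alternates = alternates)))
}

#' Flat key->value view of a parameter set
#'
#' Returns the numeric fields as a named list suitable for serialising back
#' to a config file; `load_parameters()` of the written file reproduces the
#' object (round trip).
#'
#' @param params a `parameter_set`.
#' @param drop_na drop the optional absent totals (default `TRUE`).
#' @export
as_config <- function(params, drop_na = TRUE) {
  validate_parameters(params)
  out <- params[numeric_parameter_names()]
  if (drop_na) out <- out[!vapply(out, is.na, logical(1))]
  out
}

#' Write a parameter set to a JSON config file
#'
#' @param params a `parameter_set`.
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(as_config(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the registry as a machine-readable table
#'
#' One row per constant with columns `name,value,sd,units,source`.
#'
#' @param params a `parameter_set`.
#' @param path optional CSV output path; if `NULL` the data frame is returned
#'   without writing.
#' @return the data frame, invisibly when `path` is given.
#' @export
dump_registry <- function(params, path = NULL) {
  validate_parameters(params)
  nms <- numeric_parameter_names()
  units <- ifelse(nms %in% c("kd4", "kd5"), params$kd45_unit, "umol/L")
  df <- data.frame(
    name = nms,
    value = vapply(nms, function(n) params[[n]], numeric(1)),
    sd = unname(params$sd[nms]),
    units = units,
    source = unname(params$provenance[nms]),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Switch the unit convention for the CRABP dissociation constants
#'
#' The CRABP constants are reported as 0.06 / 0.13 in umol/L in one place and
#' in nmol/L in another; both conventions are supported.  Switching rescales
#' the stored values so that [kd_umol()] always returns umol/L.
#'
#' @param params a `parameter_set`.
#' @param unit `"umol/L"` (default convention) or `"nmol/L"`.
#' @export
set_kd45_unit <- function(params, unit = c("umol/L", "nmol/L")) {
  unit <- match.arg(unit)
  validate_parameters(params)
  params$kd45_unit <- unit
  params
}

#' Dissociation constant in umol/L regardless of stored unit
#'
#' @param params a `parameter_set`.
#' @param name one of `"kd1"` ... `"kd5"`.
#' @export
kd_umol <- function(params, name) {
  stopifnot(name %in% paste0("kd", 1:5))
  v <- params[[name]]
  if (name %in% c("kd4", "kd5") && params$kd45_unit == "nmol/L") {
    v <- v / 1000
  }
  v
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> (umol/L; kd4/kd5 in", x$kd45_unit, ")\n")
  df <- dump_registry(x)
  print(df, row.names = FALSE)
  invisible(x)
}
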