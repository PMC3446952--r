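# The literature's stepwise approximation of the carrier-protein equilibrium.
# It is reproduced verbatim as a reference procedure, including its known
# shortcuts (free retinol neglected; holo-complex and ternary complex both
# set to total retinol; the apo-RBP-TTR complex taken at its ceiling).  Each
# shortcut is recorded in the result's `assumptions` so downstream reports
# can display them; the exact solver in solver.R is the package's own
# alternative.

#' Free prealbumin at the ternary-complex equilibrium (chain step 1)
#'
#' Under the approximation that the holo-RBP complex and the ternary complex
#' are both at (approximately) total retinol, the ternary mass-action
#' relation collapses to free TTR = Kd x (complex ratio), with the ratio of
#' the two complexes defaulting to 1.
#'
#' @param rt_total total retinol, umol/L (only used for validation; the
#'   approximation cancels it).
#' @param kd_ternary holo-RBP / TTR dissociation constant, umol/L.
#' @param complex_ratio ratio holo-RBP : ternary complex, dimensionless, > 0.
#' @return free prealbumin, umol/L.
#' @examples
#' ternary_step(1.73, 0.075)   # 0.075
#' @export
ternary_step <- function(rt_total, kd_ternary, complex_ratio = 1) {
  check_nonneg(rt_total, "rt_total")
  check_nonneg(kd_ternary, "kd_ternary")
  check_pos(complex_ratio, "complex_ratio")
  kd_ternary * complex_ratio
}

#' Residual prealbumin after the ternary step (chain step 2)
#'
#' @param p2_total total prealbumin, umol/L.
#' @param ternary_free_p2 free prealbumin engaged at the ternary equilibrium.
#' @return `p2_total - ternary_free_p2`, umol/L.
#' @examples
#' residual_prealbumin(4.91, 0.075)   # 4.835
#' @export
residual_prealbumin <- function(p2_total, ternary_free_p2) {
  check_nonneg(p2_total, "p2_total")
  check_nonneg(ternary_free_p2, "ternary_free_p2")
  out <- p2_total - ternary_free_p2
  if (out < 0) {
    abort_chain_breakdown(sprintf(
      "residual prealbumin is negative (%.4g - %.4g = %.4g umol/L)",
      p2_total, ternary_free_p2, out), step = "residual_prealbumin")
  }
  out
}

#' Free prealbumin and free RBP4 from the apo-RBP step (chain step 3)
#'
#' The apo-RBP-TTR complex is taken at its ceiling (total RBP4); the free
#' prealbumin left over is `residual_p2 - p1_total` and mass action then
#' gives free RBP4 = Kd3 x p1_total / free prealbumin.  When total RBP4
#' exceeds the residual prealbumin the approximation produces a non-physical
#' negative concentration; that is a chain breakdown, raised as a typed
#' error, never clamped.
#'
#' @param p1_total total RBP4, umol/L.
#' @param residual_p2 residual prealbumin from [residual_prealbumin()].
#' @param kd3 apo-RBP / TTR dissociation constant, umol/L.
#' @return list with `free_p2` and `free_p1`, umol/L.
#' @examples
#' apo_step(3.23, 4.835, 0.33)   # free_p2 1.605, free_p1 0.664
#' @export
apo_step <- function(p1_total, residual_p2, kd3) {
  check_nonneg(p1_total, "p1_total")
  check_nonneg(residual_p2, "residual_p2")
  check_nonneg(kd3, "kd3")
  free_p2 <- residual_p2 - p1_total
  if (free_p2 <= 0) {
    abort_chain_breakdown(sprintf(
      paste0("total RBP4 (%.4g umol/L) meets or exceeds the residual ",
             "prealbumin (%.4g umol/L): the ceiling approximation leaves no ",
             "free prealbumin and the stepwise chain breaks down"),
      p1_total, residual_p2), step = "apo_step")
  }
  list(free_p2 = free_p2, free_p1 = kd3 * p1_total / free_p2)
}

#' Inferred retinol-RBP4 dissociation constant (chain step 4)
#'
#' Kd1 = free retinol x free RBP4 / holo complex.  The reference procedure
#' sets free retinol and the holo complex both to total retinol, so the two
#' cancel and the inferred Kd1 equals the free RBP4 from the apo step.
#'
#' @param rt_free free retinol, umol/L.
#' @param holo_complex holo-RBP complex concentration, umol/L, > 0.
#' @param free_p1 free RBP4, umol/L.
#' @return inferred Kd1, umol/L.
#' @examples
#' infer_kd1(1.73, 1.73, 0.664)   # 0.664
#' @export
infer_kd1 <- function(rt_free, holo_complex, free_p1) {
  check_nonneg(rt_free, "rt_free")
  check_nonneg(free_p1, "free_p1")
  check_nonneg(holo_complex, "holo_complex")
  if (holo_complex == 0) {
    abort_validation("holo_complex must be > 0 to infer Kd1")
  }
  rt_free * free_p1 / holo_complex
}

#' Run the full stepwise approximation chain
#'
#' Composes [ternary_step()], [residual_prealbumin()], [apo_step()] and
#' [infer_kd1()] on a parameter set.  With the default registry this
#' reproduces the published sequence 0.075, 4.835, 1.605, 0.664, 0.664
#' (umol/L) exactly.  A breakdown in any step propagates as a
#' `retikin_chain_breakdown` condition annotated with the failing step.
#'
#' @param params a `parameter_set`.
#' @return an object of class `chain_result` with fields `ternary_free_p2`,
#'   `residual_p2`, `free_p2_for_apo`, `free_p1`, `inferred_kd1` and an
#'   `assumptions` character vector recording each approximation applied.
#' @examples
#' run_chain(parameter_set())
#' @export
run_chain <- function(params) {
  validate_parameters(params)
  assumptions <- c(
    "free unbound retinol neglected",
    "holo-RBP complex set to total retinol",
    "ternary complex set equal to holo-RBP complex (ratio 1)",
    "apo-RBP-TTR complex taken at its ceiling, total RBP4",
    "Kd1 inferred with free retinol = holo complex (terms cancel)"
  )
  ternary_free_p2 <- ternary_step(params$rt_total, params$kd2)
  residual_p2 <- residual_prealbumin(params$p2_total, ternary_free_p2)
  apo <- apo_step(params$p1_total, residual_p2, params$kd3)
  kd1 <- infer_kd1(rt_free = params$rt_total, holo_complex = params$rt_total,
                   free_p1 = apo$free_p1)
  structure(list(
    ternary_free_p2 = ternary_free_p2,
    residual_p2 = residual_p2,
    free_p2_for_apo = apo$free_p2,
    free_p1 = apo$free_p1,
    inferred_kd1 = kd1,
    assumptions = assumptions
  ), class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat("<chain_result> (umol/L)\n")
  v <- unlist(x[c("ternary_free_p2", "residual_p2", "free_p2_for_apo",
                  "free_p1", "inferred_kd1")])
  print(v)
  cat("assumptions:\n")
  cat(paste0("  - ", x$assumptions, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a chain result
#'
#' @param x a `chain_result`.
#' @param path output path; extension `.json` or `.csv` selects the format.
#' @return `path`, invisibly.
#' @export
write_chain_result <- function(x, path) {
  stopifnot(inherits(x, "chain_result"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    nm <- c("ternary_free_p2", "residual_p2", "free_p2_for_apo", "free_p1",
            "inferred_kd1")
    utils::write.csv(
      data.frame(quantity = nm, value = unlist(x[nm]), row.names = NULL),
      path, row.names = FALSE)
  } else {
    abort_validation("unsupported extension (use .json or .csv)")
  }
  invisible(path)
}
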