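#' Published reference table of free/bound retinol vs RBP4 level
#'
#' The seven-row reference table relating the RBP4 level (signed percent of
#' the normal total) to calculated bound and free retinol, shipped as a
#' read-only fixture.  The generating procedure behind its bound/free columns
#' is not recoverable from the source (the implied per-row constants are
#' mutually inconsistent with a single Kd1), so the table is never
#' re-derived: it is the comparison target for [compare_to_table5()] and the
#' source of the headline +39.3 percent metric.  Every row satisfies
#' `rt_bound + rt_free = 1.73` exactly.
#'
#' @return data frame with columns `level_percent`, `p1_total`, `rt_bound`,
#'   `rt_free` (umol/L except the level).
#' @export
reference_table5 <- function() {
  data.frame(
    level_percent = c(50, 40, 30, 0, -30, -40, -50),
    p1_total = c(4.85, 4.52, 4.20, 3.23, 2.26, 1.94, 1.62),
    rt_bound = c(1.50, 1.43, 1.37, 1.17, 0.95, 0.85, 0.75),
    rt_free  = c(0.23, 0.30, 0.36, 0.56, 0.78, 0.88, 0.98)
  )
}

#' Signed percent change relative to a reference value
#'
#' @param reference reference value, non-zero.
#' @param new new value.
#' @return `(new - reference) / reference * 100`.
#' @examples
#' percent_change(0.56, 0.78)   # +39.3 (1 dp)
#' @export
percent_change <- function(reference, new) {
  if (!is.numeric(reference) || !is.numeric(new)) {
    abort_validation("percent_change() needs numeric inputs")
  }
  if (any(reference == 0)) {
    abort_validation("reference value must be non-zero")
  }
  (new - reference) / reference * 100
}

#' Convert a signed fold change to a signed percent change
#'
#' Two conventions are supported.  `"paper"` reads a signed fold f (|f| >= 1)
#' as a symmetric percent: sign(f) x (|f| - 1) x 100, so -1.32 maps to -32.
#' `"ratio"` interprets a negative fold -f as the ratio 1/f, giving
#' (1/|f| - 1) x 100 for downregulation (so -1.32 maps to about -24.2) and
#' (|f| - 1) x 100 for upregulation.
#'
#' @param fold signed fold change, non-zero; |fold| >= 1 under `"paper"`.
#' @param convention `"paper"` or `"ratio"`.
#' @return signed percent change.
#' @examples
#' fold_to_percent(-1.32)            # -32
#' fold_to_percent(-1.32, "ratio")   # -24.24...
#' @export
fold_to_percent <- function(fold, convention = c("paper", "ratio")) {
  convention <- match.arg(convention)
  if (!is.numeric(fold) || length(fold) != 1L || fold == 0) {
    abort_validation("'fold' must be a single non-zero number")
  }
  if (convention == "paper") {
    if (abs(fold) < 1) {
      abort_validation("|fold| must be >= 1 under the 'paper' convention")
    }
    return(sign(fold) * (abs(fold) - 1) * 100)
  }
  if (fold < 0) (1 / abs(fold) - 1) * 100 else (abs(fold) - 1) * 100
}

#' Inverse of [fold_to_percent()] under the symmetric convention
#'
#' @param pct signed percent change.
#' @return signed fold change with |fold| >= 1.
#' @export
percent_to_fold <- function(pct) {
  if (!is.numeric(pct) || length(pct) != 1L) {
    abort_validation("'pct' must be a single number")
  }
  if (pct >= 0) 1 + pct / 100 else -(1 + abs(pct) / 100)
}

#' Scan free and bound retinol across RBP4 levels
#'
#' For each signed percent level the total RBP4 is scaled to
#' `p1_total x (1 + level/100)` and the retinol partition recomputed, either
#' with the exact coupled equilibrium solver on the three-species network
#' (`method = "exact"`) or with the stepwise reference chain
#' (`method = "chain"`, partitioning retinol by
#' `rt_free / rt_bound = kd1 / free_p1` under conservation).  Levels at which
#' the chain breaks down are flagged in the `status` column, never
#' fabricated.
#'
#' @param params a `parameter_set`.
#' @param levels signed percent changes of total RBP4; must include 0 (the
#'   reference for the percent-change column).
#' @param method `"exact"` or `"chain"`.
#' @param tolerance solver tolerance (exact method).
#' @return data frame of class `perturbation_scan` with columns
#'   `level_percent`, `p1_total`, `rt_bound`, `rt_free`,
#'   `pct_change_free_vs_reference`, `method`, `status`.
#' @examples
#' scan_rbp4(parameter_set(), levels = c(-30, 0, 30))
#' @export
scan_rbp4 <- function(params, levels = c(50, 40, 30, 0, -30, -40, -50),
                      method = c("exact", "chain"), tolerance = 1e-10) {
  method <- match.arg(method)
  validate_parameters(params)
  if (!0 %in% levels) {
    abort_validation("'levels' must include 0 (the reference level)")
  }
  rows <- lapply(levels, function(lv) {
    p <- params
    p$p1_total <- params$p1_total * (1 + lv / 100)
    p$provenance[["p1_total"]] <- "scan"
    row <- list(level_percent = lv, p1_total = p$p1_total,
                rt_bound = NA_real_, rt_free = NA_real_,
                method = method, status = "ok")
    if (method == "exact") {
      st <- solve_equilibrium(build_network(p), tolerance = tolerance)
      row$rt_free <- unname(st$free["Rt"])
      row$rt_bound <- params$rt_total - row$rt_free
    } else {
      res <- tryCatch(run_chain(p), retikin_chain_breakdown = function(e) e)
      if (inherits(res, "retikin_chain_breakdown")) {
        row$status <- "chain-breakdown"
      } else {
        # rt_free/rt_bound = kd1/free_p1 with rt_free + rt_bound = rt_total
        kd1 <- params$kd1
        row$rt_free <- params$rt_total * kd1 / (kd1 + res$free_p1)
        row$rt_bound <- params$rt_total - row$rt_free
      }
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  ref_free <- out$rt_free[out$level_percent == 0][1]
  out$pct_change_free_vs_reference <- NA_real_
  if (!is.na(ref_free)) {  # reference row itself can be a chain breakdown
    ok <- !is.na(out$rt_free)
    out$pct_change_free_vs_reference[ok] <-
      ifelse(out$level_percent[ok] == 0, 0,
             percent_change(ref_free, out$rt_free[ok]))
  }
  out <- out[, c("level_percent", "p1_total", "rt_bound", "rt_free",
                 "pct_change_free_vs_reference", "method", "status")]
  class(out) <- c("perturbation_scan", "data.frame")
  out
}

#' Compare a scan against the published reference table
#'
#' Reports, per level, the absolute and relative differences of bound and
#' free retinol between a [scan_rbp4()] result and [reference_table5()],
#' together with the fixture's own mass-balance self-test.  The published
#' bound/free columns are not reproducible from a single mass-action
#' relation, so this function documents the discrepancy; it never asserts
#' agreement.
#'
#' @param scan a `perturbation_scan` whose levels are a subset of the
#'   fixture's.
#' @return list with `comparison` (per-row differences),
#'   `fixture_mass_balance` (rt_bound + rt_free per fixture row) and
#'   `rt_total` (the fixture's stated total, 1.73).
#' @export
compare_to_table5 <- function(scan) {
  ref <- reference_table5()
  missing_lv <- setdiff(scan$level_percent, ref$level_percent)
  if (length(missing_lv)) {
    abort_validation(sprintf(
      "scan levels not in the reference table: %s",
      paste(missing_lv, collapse = ", ")))
  }
  idx <- match(scan$level_percent, ref$level_percent)
  cmp <- data.frame(
    level_percent = scan$level_percent,
    rt_bound_scan = scan$rt_bound,
    rt_bound_ref = ref$rt_bound[idx],
    rt_free_scan = scan$rt_free,
    rt_free_ref = ref$rt_free[idx]
  )
  cmp$diff_bound <- cmp$rt_bound_scan - cmp$rt_bound_ref
  cmp$diff_free <- cmp$rt_free_scan - cmp$rt_free_ref
  cmp$rel_diff_free <- cmp$diff_free / cmp$rt_free_ref
  list(
    comparison = cmp,
    fixture_mass_balance = ref$rt_bound + ref$rt_free,
    rt_total = 1.73
  )
}

#' Headline percent change of free retinol from the reference table
#'
#' The published argument maps a measured RBP4 downregulation to the nearest
#' tabulated level (a -32 percent knockdown is read against the -30 percent
#' row) and quotes the percent rise of free retinol relative to the normal
#' row.  With the default fixture this is +39.3 percent.
#'
#' @param level_percent tabulated RBP4 level to compare against the normal
#'   (0) row; default -30.
#' @return signed percent change of free retinol.
#' @examples
#' headline_free_retinol_change()   # 39.28...
#' @export
headline_free_retinol_change <- function(level_percent = -30) {
  ref <- reference_table5()
  if (!level_percent %in% ref$level_percent) {
    abort_validation("level_percent must be one of the tabulated levels")
  }
  percent_change(ref$rt_free[ref$level_percent == 0],
                 ref$rt_free[ref$level_percent == level_percent])
}
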