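#' Competitive partitioning of retinoic acid between CRABP1 and CRABP2
#'
#' Retinoic acid (RA) distributes between the constitutive CRABP1 pool
#' (non-RAR tissue) and the RAR-responsive CRABP2 pool by simple competition
#' of two 1:1 binding reactions.  Solved exactly with the coupled
#' equilibrium solver -- no excess-protein approximation.
#'
#' All inputs must share one concentration unit; the result is in that unit.
#' (The registry stores the CRABP constants as printed, 0.06 / 0.13, with a
#' switchable umol/L vs nmol/L convention -- see [set_kd45_unit()].)
#'
#' @param ra_total total retinoic acid.
#' @param p3_total,p4_total total CRABP1 / CRABP2.
#' @param kd4,kd5 dissociation constants of RA-CRABP1 / RA-CRABP2.
#' @param tolerance solver tolerance.
#' @return list of class `ra_partition`: `ra_free`, `ra_p3`, `ra_p4`,
#'   `fraction_rar_responsive` (ra_p4 / ra_total; `NA` when ra_total = 0).
#' @examples
#' partition_ra(0.1, 1, 1, 0.06, 0.13)
#' @export
partition_ra <- function(ra_total, p3_total, p4_total, kd4, kd5,
                         tolerance = 1e-12) {
  check_nonneg(ra_total, "ra_total")
  check_nonneg(p3_total, "p3_total")
  check_nonneg(p4_total, "p4_total")
  check_pos(kd4, "kd4")
  check_pos(kd5, "kd5")
  net <- binding_network(
    species = data.frame(name = c("RA", "P3", "P4"),
                         total = c(ra_total, p3_total, p4_total)),
    reactions = data.frame(lhs = c("RA", "RA"), rhs = c("P3", "P4"),
                           complex = c("RA.P3", "RA.P4"),
                           kd = c(kd4, kd5))
  )
  st <- solve_equilibrium(net, tolerance = tolerance)
  structure(list(
    ra_free = unname(st$free["RA"]),
    ra_p3 = unname(st$complexes["RA.P3"]),
    ra_p4 = unname(st$complexes["RA.P4"]),
    fraction_rar_responsive =
      if (ra_total > 0) unname(st$complexes["RA.P4"]) / ra_total else NA_real_
  ), class = "ra_partition")
}

#' Michaelis-Menten parameter pairs for retinol oxidation
#'
#' Defaults are the published cytochrome-P450 retinol-to-RA oxidation
#' parameters: NADP-dependent Km 19.4 mM, Vmax 52 pmol/min/mg protein;
#' NAD-dependent Km 41.5 mM, Vmax 280 pmol/min/mg protein.
#'
#' @param km Michaelis constant, mM, > 0.
#' @param vmax maximal rate, pmol/min/mg protein, > 0.
#' @param label cofactor label.
#' @return list of class `mm_params`.
#' @export
mm_params <- function(km, vmax, label = "custom") {
  check_pos(km, "km")
  check_pos(vmax, "vmax")
  structure(list(km = km, vmax = vmax, label = label), class = "mm_params")
}

#' @rdname mm_params
#' @export
mm_defaults <- function() {
  list(NADP = mm_params(19.4, 52, "NADP"),
       NAD = mm_params(41.5, 280, "NAD"))
}

#' Michaelis-Menten rate
#'
#' @param substrate substrate concentration (same unit as `params$km`), >= 0.
#' @param params an [mm_params()] object.
#' @return rate `vmax * s / (km + s)`; vectorised over `substrate`.
#' @examples
#' mm_rate(19.4, mm_defaults()$NADP)   # half of Vmax = 26
#' @export
mm_rate <- function(substrate, params) {
  stopifnot(inherits(params, "mm_params"))
  if (any(substrate < 0)) abort_validation("substrate must be >= 0")
  params$vmax * substrate / (params$km + substrate)
}

#' Which oxidation pathway dominates across a substrate grid
#'
#' Labels each grid point by the faster of two Michaelis-Menten pathways and
#' locates any rate crossover by bisection.  With the published NADP/NAD
#' parameter pairs the NAD-dependent rate is faster at every positive
#' substrate concentration (it has both the larger Vmax and the larger
#' Vmax/Km), so no crossover exists; the report says so explicitly rather
#' than reconciling it with the qualitative claim that the NADP pathway
#' dominates at low retinol.
#'
#' @param substrate_grid non-negative concentrations (mM); may be empty.
#' @param params_a,params_b the two pathways (defaults: NADP, NAD).
#' @return list with `table` (substrate, both rates, `dominant` label) and
#'   `crossover` (concentration where the rates cross, or `NA` if none in
#'   the grid range).
#' @export
oxidation_dominance <- function(substrate_grid,
                                params_a = mm_defaults()$NADP,
                                params_b = mm_defaults()$NAD) {
  if (length(substrate_grid) == 0) {
    return(list(table = data.frame(substrate = numeric(),
                                   rate_a = numeric(), rate_b = numeric(),
                                   dominant = character()),
                crossover = NA_real_))
  }
  if (any(substrate_grid < 0)) abort_validation("grid must be non-negative")
  ra <- mm_rate(substrate_grid, params_a)
  rb <- mm_rate(substrate_grid, params_b)
  dom <- ifelse(ra == rb, "tie", ifelse(ra > rb, params_a$label,
                                        params_b$label))
  diff_fun <- function(s) mm_rate(s, params_a) - mm_rate(s, params_b)
  crossover <- NA_real_
  pos <- substrate_grid[substrate_grid > 0]
  if (length(pos) >= 2) {
    d <- diff_fun(pos)
    exact <- which(d == 0)
    flip <- which(d[-1] * d[-length(d)] < 0)
    if (length(exact)) {
      crossover <- pos[exact[1]]   # crossover sits on a grid point
    } else if (length(flip)) {
      crossover <- stats::uniroot(diff_fun, c(pos[flip[1]], pos[flip[1] + 1]),
                                  tol = 1e-12)$root
    }
  }
  list(table = data.frame(substrate = substrate_grid, rate_a = ra,
                          rate_b = rb, dominant = dom),
       crossover = crossover)
}
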