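# Closed-form radical kinetics.  Superoxide self-dismutation is second order
# (rate k[O2-]^2, k ~ 1e5 M^-1 s^-1 at pH 7), so its half-life scales
# inversely with the starting concentration; SOD-catalysed decomposition is
# pseudo-first order in superoxide with effective constant (kcat/Km)[SOD].

#' Half-life of a species decaying by a second-order self-reaction
#'
#' t_1/2 = 1 / (k c0).  At k = 1e5 M^-1 s^-1 this gives 0.05 s at
#' c0 = 2e-4 M and about 14 h at c0 ~ 2e-10 M -- the short-vs-long half-life
#' contrast quoted for superoxide at high vs low concentration.
#'
#' @param k second-order rate constant, M^-1 s^-1, > 0.
#' @param c0 initial concentration, mol/L, > 0.
#' @return half-life in seconds.
#' @examples
#' second_order_halflife(1e5, 2e-4)   # 0.05
#' @export
second_order_halflife <- function(k, c0) {
  check_pos(k, "k")
  check_pos(c0, "c0")
  1 / (k * c0)
}

#' Concentration where spontaneous dismutation matches enzymatic removal
#'
#' The spontaneous second-order rate `k [S]^2` equals the pseudo-first-order
#' enzymatic rate `(kcat/Km) [E] [S]` at
#' `[S] = (kcat/Km) [E] / k`.  Above the crossover the spontaneous pathway
#' is faster; below it the enzyme dominates (down to arbitrarily low
#' substrate, which is why a diffusion-limited kcat/Km ~ 7e9 M^-1 s^-1
#' matters at subnanomolar superoxide).
#'
#' @param k_dismutation second-order constant, M^-1 s^-1, > 0.
#' @param kcat_over_km enzyme specificity constant, M^-1 s^-1, > 0.
#' @param enzyme_conc enzyme concentration, mol/L, >= 0.
#' @return crossover substrate concentration, mol/L (0 when no enzyme).
#' @examples
#' dismutation_vs_enzyme(1e5, 7e9, 1e-9)   # 7e-5 M
#' @export
dismutation_vs_enzyme <- function(k_dismutation, kcat_over_km, enzyme_conc) {
  check_pos(k_dismutation, "k_dismutation")
  check_pos(kcat_over_km, "kcat_over_km")
  check_nonneg(enzyme_conc, "enzyme_conc")
  kcat_over_km * enzyme_conc / k_dismutation
}
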