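---
title: "Retinol carrier-protein speciation: model, approximations, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinol carrier-protein speciation: model, approximations, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retikin)
```

## The biological question

Retinol (vitamin A) circulates and is stored almost entirely protein-bound:
retinol-binding protein 4 (RBP4, written $P_1$) binds it 1:1 as the
holo-RBP complex, transthyretin (prealbumin, $P_2$) binds holo-RBP into a
ternary complex, and transthyretin also binds ligand-free apo-RBP.  The
unbound ("free") retinol pool is small, and it is the teratogenically
active one: elevated free retinol is hypervitaminosis A.  A knockdown of
RBP4 therefore does not reduce retinol exposure — it removes carrier
capacity and *raises* the free fraction.  This package quantifies that
effect with equilibrium binding kinetics, both in the stepwise approximate
form used in the clinical literature and with an exact coupled solver.

## The model

The core network has three species and three 1:1 association equilibria,
each parameterised by a dissociation constant (µmol/L):

$$R_t + P_1 \rightleftharpoons [R_t{-}P_1] \quad (K_{d1})$$
$$[R_t{-}P_1] + P_2 \rightleftharpoons [[R_t{-}P_1]{-}P_2] \quad (K_{d2})$$
$$P_1 + P_2 \rightleftharpoons [P_1{-}P_2] \quad (K_{d3})$$

with conservation of each species total.  Optionally retinoic acid competes
between the two cellular retinoic-acid binding proteins (CRABP1 at
$K_{d4}$, CRABP2 at $K_{d5}$); only the CRABP2-bound pool is
RAR-responsive.  Default parameter values and their reported standard
deviations live in `parameter_set()` / `dump_registry()`; every value
carries a provenance tag so user overrides are distinguishable from
registry defaults.

Two unit quirks are handled explicitly rather than silently: molecular
weights are stored in daltons although the source table prints "kDa" where
Da is chemically required; and the CRABP constants are printed as µmol/L in
the parameter table but quoted as nmol/L in the surrounding text, so the
registry stores the numbers with a switchable unit convention
(`set_kd45_unit()`) and leaves the choice to the user.

## The stepwise reference chain

The literature derivation (`run_chain()`) proceeds by four approximations,
each recorded in the result's `assumptions` field:

1. free retinol is neglected and both retinol-containing complexes are set
   to total retinol, so the ternary equilibrium collapses to
   free $P_2 = K_{d2}$ (0.075 µmol/L);
2. residual prealbumin is $[P_2]_t - 0.075 = 4.835$ µmol/L;
3. the apo-RBP–TTR complex is taken at its ceiling, total RBP4, leaving
   free $P_2 = 4.835 - 3.23 = 1.605$ µmol/L and, by mass action, free
   $P_1 = K_{d3} \cdot [P_1]_t / 1.605 = 0.664$ µmol/L;
4. $K_{d1}$ is inferred with free retinol and the holo complex both set to
   total retinol, so they cancel and $K_{d1}$ = free $P_1$ = 0.664 µmol/L.

The chain is reproduced verbatim, circularity included, because it is a
reference procedure: reports display its assumptions next to its numbers.
When total RBP4 meets or exceeds the residual prealbumin (the +50 % RBP4
scenario: 4.85 > 4.835) step 3 yields a non-physical negative
concentration.  That raises a typed `retikin_chain_breakdown` condition —
never a clamped value — and perturbation scans record it as a row status.

```{r chain}
run_chain(parameter_set())
```

## The exact solver and its oracle

`solve_equilibrium()` solves the coupled conservation equations exactly.
Each complex concentration is a monomial in the free species concentrations
divided by the product of the dissociation constants along its formation
path (valid because every reaction is 1:1 and may reference only species or
previously defined complexes — the acyclicity rule enforced by
`binding_network()`).  Root finding is damped Newton iteration on
log-transformed free concentrations: the log transform guarantees
positivity, the damping (step halving against the residual norm) handles
the stiff $K_{d2}/K_{d1}$ ratio, and a monotone per-species bisection sweep
is the fallback when a Newton step fails to improve.  The method is
deterministic; identical inputs give bit-identical output.

Numerical defaults: absolute conservation tolerance $10^{-10}$ µmol/L
(three orders below the 3-decimal precision of every literature value) and
200 iterations.  Uniqueness of the positive equilibrium is not proven in
code; it is evidenced by agreement, from different starting points, between
the Newton solver and `oracle_bisection()` — an independent Gauss–Seidel
bisection solver that shares only the residual evaluator — and against the
closed-form binary quadratic (`solve_binary()`) where applicable.  The test
suite asserts these cross-checks to $10^{-9}$ on randomized networks.
Degenerate inputs are defined, not errors: a species with zero total stays
at zero, a network without reactions returns totals as free, and
$K_d \to \infty$ recovers the no-binding limit.

One modelling simplification: transthyretin is treated as a single RBP
site, following the source algebra, although the protein has two roughly
equivalent sites (reported $K_d \approx 0.4$ µmol/L each).  Modelling two
sites would roughly double the effective $P_2$ capacity; users can emulate
this by doubling `p2_total`.

## Perturbation scans and the published table

`scan_rbp4()` scales total RBP4 by a signed percentage and recomputes the
free/bound retinol partition, either exactly or through the chain (which
partitions retinol by $[R_t]_f/[R_t]_b = K_{d1}/[P_1]_f$ under
conservation).  The published seven-row table of calculated bound/free
retinol cannot be regenerated from any single mass-action relation with
$K_{d1} = 0.664$ — the per-row implied constants are mutually inconsistent,
and the two equations said to generate it are not recoverable from the text
— so the table ships as a read-only fixture (`reference_table5()`), the
headline +39.3 % free-retinol rise is computed *from* the fixture
(`headline_free_retinol_change()`), and `compare_to_table5()` reports the
exact solver's disagreement with sign and magnitude instead of asserting
agreement.  At the normal level the exact solver puts free retinol at
0.160 µmol/L against the fixture's 0.56 µmol/L; the discrepancy section of
every report keeps that visible.

The measured RBP4 knockdown (fold change −1.32, i.e. −32 % under the
symmetric fold convention implemented in `fold_to_percent()`) is mapped to
the fixture's −30 % row for the headline metric, as the source argument
does; the exact solver additionally evaluates the −32 % level itself.

## Synthetic data and uncertainty propagation

`sample_parameter_sets()` draws parameters from zero-truncated normal
distributions around the registry means.  Truncation at zero was chosen
because several reported SDs are large relative to their means
($K_{d3} = 0.33 \pm 0.11$) and negative concentrations are meaningless.
Constants published without an SD ($K_{d1}$, $K_{d4}$, $K_{d5}$) use a
coefficient of variation `default_cv = 0.10`; the choice is echoed in every
summary rather than buried.  `propagate_uncertainty()` turns the point
prediction of the free-retinol rise into a distribution; with the chain
method, draws where the chain breaks down are counted and excluded, never
imputed.  All randomness is seeded, and the samplers restore the caller's
RNG stream.

`generate_titration()` and `fit_kd()` emulate the experiment that the
source replaces with algebra: a noisy 1:1 binding titration with known
$K_d$, fitted by least squares on $\log K_d$.  The generator mimics
Gaussian measurement noise on bound concentrations, clipped at zero; it
does not emulate instrument drift, pipetting correlation, or ligand
depletion artefacts, so a green recovery test establishes statistical
identifiability of $K_d$ under idealised noise, not assay robustness.

## What a green suite does and does not establish

The tests prove: the chain reproduces the printed arithmetic exactly; the
exact solver satisfies conservation and mass action to $10^{-10}$ and
agrees with two independent oracles; scans are monotone and conserve
retinol; the headline percent metrics match the printed values; seeded
Monte-Carlo runs are reproducible with the expected $1/\sqrt{n}$ error
scaling; and $K_d$ is recoverable from synthetic titrations.  They cannot
certify the biological parameter values themselves, the unrecoverable
procedure behind the published bound/free table, or the physiological
realism of treating the cytoplasmic pool as a single well-mixed
equilibrium compartment.

A further documented inconsistency is preserved rather than repaired: the
published Michaelis–Menten pairs for retinol oxidation (NADP: $K_m$ 19.4
mM, $V_{max}$ 52; NAD: 41.5 mM, 280 pmol/min/mg) imply the NAD-dependent
pathway is faster at *every* substrate concentration, contradicting the
qualitative claim that the NADP pathway dominates at low retinol.
`oxidation_dominance()` reports what the numbers imply and finds no
crossover with the defaults.
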