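#' Closed-form bound concentration for a single 1:1 binding reaction
#'
#' The textbook quadratic: for ligand total `l_total`, protein total
#' `p_total` and dissociation constant `kd`, the complex concentration is
#' \deqn{b = \frac{(l + p + K_d) - \sqrt{(l + p + K_d)^2 - 4 l p}}{2}.}
#' Symmetric in ligand and protein; `kd = 0` returns `min(l, p)`.
#'
#' @param l_total,p_total totals, umol/L, >= 0.
#' @param kd dissociation constant, umol/L, >= 0.
#' @return bound (complex) concentration, umol/L.
#' @examples
#' solve_binary(1.73, 3.23, 0.664)
#' @export
solve_binary <- function(l_total, p_total, kd) {
  check_nonneg(l_total, "l_total")
  check_nonneg(p_total, "p_total")
  check_nonneg(kd, "kd")
  s <- l_total + p_total + kd
  disc <- s^2 - 4 * l_total * p_total
  # disc >= (l - p)^2 + kd^2 >= 0 analytically; clamp rounding noise
  disc <- max(disc, 0)
  b <- (s - sqrt(disc)) / 2
  min(max(b, 0), l_total, p_total)
}

new_equilibrium_state <- function(free, complexes, residuals, converged,
                                  iterations, tolerance) {
  structure(list(free = free, complexes = complexes, residuals = residuals,
                 converged = converged, iterations = iterations,
                 tolerance = tolerance),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> converged=%s iterations=%d max|residual|=%.3g\n",
              x$converged, x$iterations, max(abs(x$residuals), 0)))
  cat("free (umol/L):\n")
  print(x$free)
  if (length(x$complexes)) {
    cat("complexes (umol/L):\n")
    print(x$complexes)
  }
  invisible(x)
}

# Evaluate complexes and conservation residuals at a vector of free
# concentrations (named by species).
eval_network <- function(mono, free, totals) {
  if (length(mono$complexes)) {
    # complex_c = prod_k free_k^m[c,k] / kprod_c, in log space; a species at
    # free = 0 zeroes every complex containing it (sentinel log ~ -745 keeps
    # the matrix product finite and underflows exp() to exactly 0)
    logf <- ifelse(free > 0, log(free), -745)
    lc <- as.vector(mono$expo %*% logf) - log(mono$kprod)
    cx <- stats::setNames(exp(lc), mono$complexes)
    bound <- as.vector(t(mono$expo) %*% cx)
  } else {
    cx <- stats::setNames(numeric(0), character(0))
    bound <- rep(0, length(free))
  }
  res <- free + bound - totals
  list(complexes = cx, residuals = stats::setNames(res, mono$species))
}

#' Exact simultaneous mass-action equilibrium of a binding network
#'
#' Solves the coupled conservation equations of a [binding_network()] for the
#' free concentration of every species; complexes follow by mass action.
#' Root finding is a damped Newton iteration on log-transformed free
#' concentrations (guaranteeing positivity) with a monotone bisection sweep
#' as fallback, so stiff Kd ratios converge without tuning.  Deterministic:
#' identical inputs give bit-identical output.
#'
#' @param network a `binding_network`.
#' @param tolerance absolute tolerance on each species' conservation
#'   residual, umol/L.  Default 1e-10, far below the 3-decimal precision of
#'   the literature values.
#' @param max_iterations Newton iteration cap.
#' @return an `equilibrium_state`: named vectors `free`, `complexes`,
#'   `residuals`, plus `converged`, `iterations`, `tolerance`.
#' @examples
#' st <- solve_equilibrium(build_network(parameter_set()))
#' st$free["Rt"]    # free retinol
#' @export
solve_equilibrium <- function(network, tolerance = 1e-10,
                              max_iterations = 200L) {
  stopifnot(inherits(network, "binding_network"))
  check_pos(tolerance, "tolerance")
  mono <- network_monomials(network)
  totals <- stats::setNames(network$species$total, network$species$name)
  n <- length(totals)

  if (!length(mono$complexes)) {
    ev <- eval_network(mono, totals, totals)
    return(new_equilibrium_state(totals, ev$complexes,
                                 ev$residuals, TRUE, 0L, tolerance))
  }

  active <- totals > 0  # zero-total species stay at free = 0
  free <- ifelse(active, totals / 2, 0)
  ev <- eval_network(mono, free, totals)
  best_norm <- max(abs(ev$residuals[active]))
  iter <- 0L

  while (best_norm > tolerance && iter < max_iterations) {
    iter <- iter + 1L
    # Jacobian wrt u = log(free), active species only
    cx <- ev$complexes
    J <- diag(free[active], sum(active))
    m <- mono$expo[, active, drop = FALSE]
    if (length(cx)) {
      J <- J + t(m) %*% (m * cx)
    }
    g <- ev$residuals[active]
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      # damped line search in log space
      alpha <- 1
      u <- log(free[active])
      for (h in 1:50) {
        cand <- free
        cand[active] <- exp(u + alpha * pmax(pmin(step, 30), -30))
        evc <- eval_network(mono, cand, totals)
        norm_c <- max(abs(evc$residuals[active]))
        if (is.finite(norm_c) && norm_c < best_norm) {
          free <- cand; ev <- evc; best_norm <- norm_c; improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
    }
    if (!improved) {
      # monotone fallback: one Gauss-Seidel sweep of per-species bisection
      free <- bisection_sweep(mono, free, totals, active)
      ev <- eval_network(mono, free, totals)
      best_norm <- max(abs(ev$residuals[active]))
    }
  }

  if (best_norm > tolerance) {
    abort_retikin(
      sprintf("equilibrium solver did not converge in %d iterations (max residual %.3g)",
              max_iterations, best_norm),
      class = "retikin_convergence_error",
      state = new_equilibrium_state(free, ev$complexes, ev$residuals,
                                    FALSE, iter, tolerance))
  }
  new_equilibrium_state(free, ev$complexes, ev$residuals, TRUE, iter,
                        tolerance)
}

# For each active species in turn, bisect its free concentration on
# [0, total] to zero its own conservation residual, holding the others fixed.
# Residual_i is strictly increasing in free_i (all complexes containing i
# grow with free_i), so the bracket is valid.
bisection_sweep <- function(mono, free, totals, active, n_bisect = 80L) {
  for (i in which(active)) {
    lo <- 0; hi <- totals[i]
    for (b in seq_len(n_bisect)) {
      mid <- (lo + hi) / 2
      free[i] <- mid
      ri <- eval_network(mono, free, totals)$residuals[i]
      if (ri > 0) hi <- mid else lo <- mid
    }
    free[i] <- (lo + hi) / 2
  }
  free
}

#' Independent bisection oracle for the same equilibrium problem
#'
#' Solves the identical problem as [solve_equilibrium()] but by repeated
#' Gauss-Seidel sweeps of per-species interval bisection -- no derivatives,
#' no shared code path with the Newton solver beyond residual evaluation.
#' Intended as the cross-check in tests; slower than the main solver.
#'
#' @inheritParams solve_equilibrium
#' @param max_sweeps cap on full bisection sweeps.
#' @return an `equilibrium_state`.
#' @export
oracle_bisection <- function(network, tolerance = 1e-10, max_sweeps = 500L) {
  stopifnot(inherits(network, "binding_network"))
  check_pos(tolerance, "tolerance")
  mono <- network_monomials(network)
  totals <- stats::setNames(network$species$total, network$species$name)

  if (!length(mono$complexes)) {
    ev <- eval_network(mono, totals, totals)
    return(new_equilibrium_state(totals, ev$complexes, ev$residuals,
                                 TRUE, 0L, tolerance))
  }
  active <- totals > 0
  free <- ifelse(active, totals, 0)
  sweep <- 0L
  repeat {
    sweep <- sweep + 1L
    free <- bisection_sweep(mono, free, totals, active)
    ev <- eval_network(mono, free, totals)
    norm <- max(abs(ev$residuals[active]), 0)
    if (norm <= tolerance || sweep >= max_sweeps) break
  }
  if (norm > tolerance) {
    abort_retikin(
      sprintf("bisection oracle did not converge in %d sweeps (max residual %.3g)",
              max_sweeps, norm),
      class = "retikin_convergence_error",
      state = new_equilibrium_state(free, ev$complexes, ev$residuals,
                                    FALSE, sweep, tolerance))
  }
  new_equilibrium_state(free, ev$complexes, ev$residuals, TRUE, sweep,
                        tolerance)
}

#' Dump an equilibrium state to CSV
#'
#' Two stacked blocks: per-species rows (`species,free,total,residual`) then
#' per-complex rows (`complex,concentration`).
#'
#' @param state an `equilibrium_state`.
#' @param network the network it was solved from (for totals).
#' @param path CSV output path.
#' @return the combined data frame, invisibly if written.
#' @export
state_to_csv <- function(state, network, path = NULL) {
  sp <- data.frame(kind = "species", name = names(state$free),
                   concentration = unname(state$free),
                   total = network$species$total[
                     match(names(state$free), network$species$name)],
                   residual = unname(state$residuals),
                   stringsAsFactors = FALSE)
  cx <- if (length(state$complexes)) {
    data.frame(kind = "complex", name = names(state$complexes),
               concentration = unname(state$complexes),
               total = NA_real_, residual = NA_real_,
               stringsAsFactors = FALSE)
  } else NULL
  df <- rbind(sp, cx)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
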