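# Synthetic statistical inputs: parameter draws around the registry means
# with their reported SDs, and noisy binding titrations with a known Kd.
# Everything is seeded; the package contains no unseeded randomness.

#' Monte-Carlo configuration
#'
#' @param n_draws number of parameter draws, >= 1.
#' @param seed integer RNG seed.
#' @param default_cv coefficient of variation applied to constants that have
#'   no reported SD (kd1, kd4, kd5).  Default 0.10; the choice is surfaced in
#'   every summary rather than buried.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_draws = 2000L, seed = 1L, default_cv = 0.10) {
  if (!is.numeric(n_draws) || n_draws < 1) {
    abort_validation("n_draws must be >= 1")
  }
  check_nonneg(default_cv, "default_cv")
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 distribution = "truncated-normal-at-zero",
                 default_cv = default_cv),
            class = "mc_config")
}

# Truncated-normal (at zero) sampler via inverse CDF; sd = 0 degenerates to
# the mean.  Chosen because several reported SDs are large relative to their
# means and negative concentrations are meaningless.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

# Evaluate fn() under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw parameter sets around the registry means
#'
#' Each numeric field with a reported SD is drawn from a zero-truncated
#' normal with that SD; kd1, kd4 and kd5 (no reported SD) use
#' `cfg$default_cv x mean`.  Absent optional totals stay absent.  Identical
#' `(params, cfg)` give bit-identical draws.
#'
#' @param params a `parameter_set` of means.
#' @param cfg an [mc_config()].
#' @return list of `cfg$n_draws` parameter sets.
#' @examples
#' draws <- sample_parameter_sets(parameter_set(), mc_config(5, seed = 7))
#' @export
sample_parameter_sets <- function(params, cfg) {
  validate_parameters(params)
  stopifnot(inherits(cfg, "mc_config"))
  nms <- numeric_parameter_names()
  means <- vapply(nms, function(n) params[[n]], numeric(1))
  sds <- params$sd[nms]
  sds[is.na(sds)] <- cfg$default_cv * means[is.na(sds)]
  names(sds) <- nms
  drawable <- nms[!is.na(means)]
  with_seed(cfg$seed, function() {
    draws <- lapply(seq_len(cfg$n_draws), function(i) {
      vals <- lapply(drawable, function(n) rtruncnorm0(1, means[[n]], sds[[n]]))
      names(vals) <- drawable
      do.call(parameter_set, vals)
    })
    draws
  })
}

#' Propagate parameter uncertainty to the free-retinol percent change
#'
#' For each Monte-Carlo draw, free retinol is computed at the reference RBP4
#' level and at `scenario` percent, and the percent change recorded.  With
#' `method = "chain"` draws for which the stepwise chain breaks down are
#' counted as infeasible and excluded (the exact method is always feasible).
#'
#' @param params a `parameter_set` of means.
#' @param cfg an [mc_config()].
#' @param scenario signed percent change of total RBP4 (default -30).
#' @param method `"exact"` or `"chain"`.
#' @return list of class `mc_summary`: `mean`, `sd`, `q025`, `q975`,
#'   `median`, `n_ok`, `n_infeasible`, `default_cv`, `scenario`, `method`,
#'   `seed` and the per-draw table `draws`.
#' @export
propagate_uncertainty <- function(params, cfg, scenario = -30,
                                  method = c("exact", "chain")) {
  method <- match.arg(method)
  sets <- sample_parameter_sets(params, cfg)
  one <- function(p) {
    sc <- tryCatch(
      scan_rbp4(p, levels = c(0, scenario), method = method),
      retikin_error = function(e) NULL)
    if (is.null(sc)) return(NA_real_)
    row <- sc[sc$level_percent == scenario, ]
    if (row$status != "ok" || sc$status[sc$level_percent == 0] != "ok") {
      return(NA_real_)
    }
    row$pct_change_free_vs_reference
  }
  pct <- vapply(sets, one, numeric(1))
  ok <- pct[!is.na(pct)]
  if (!length(ok)) {
    abort_retikin("all Monte-Carlo draws were infeasible",
                  class = "retikin_mc_error")
  }
  structure(list(
    mean = mean(ok), sd = stats::sd(ok),
    median = stats::median(ok),
    q025 = unname(stats::quantile(ok, 0.025)),
    q975 = unname(stats::quantile(ok, 0.975)),
    n_ok = length(ok), n_infeasible = sum(is.na(pct)),
    default_cv = cfg$default_cv, scenario = scenario, method = method,
    seed = cfg$seed,
    draws = data.frame(draw = seq_along(pct), pct_change_free = pct)
  ), class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf(
    "<mc_summary> scenario %+g%% RBP4, method %s, n_ok %d (infeasible %d)\n",
    x$scenario, x$method, x$n_ok, x$n_infeasible))
  cat(sprintf("  %% change free retinol: mean %.2f sd %.2f [%.2f, %.2f]\n",
              x$mean, x$sd, x$q025, x$q975))
  cat(sprintf("  default_cv for constants without reported SD: %g\n",
              x$default_cv))
  invisible(x)
}

#' Generate a synthetic 1:1 binding titration
#'
#' Bound concentrations follow the closed-form binary model
#' ([solve_binary()]) at each ligand total, plus seeded Gaussian noise,
#' clipped at zero.  Purely synthetic: no raw titration data exist in the
#' source literature.
#'
#' @param true_kd true dissociation constant, umol/L.
#' @param protein_total protein total, umol/L.
#' @param ligand_grid ligand totals, umol/L; may be empty.
#' @param noise_sd Gaussian noise SD on bound, umol/L.
#' @param seed integer RNG seed.
#' @return list of class `titration_dataset` recording grid, observed bound,
#'   truth, noise level and seed.
#' @export
generate_titration <- function(true_kd, protein_total, ligand_grid,
                               noise_sd = 0, seed = 1L) {
  check_nonneg(true_kd, "true_kd")
  check_nonneg(protein_total, "protein_total")
  check_nonneg(noise_sd, "noise_sd")
  if (any(ligand_grid < 0)) abort_validation("ligand_grid must be >= 0")
  truth <- vapply(ligand_grid, solve_binary, numeric(1),
                  p_total = protein_total, kd = true_kd)
  observed <- with_seed(seed, function() {
    pmax(truth + stats::rnorm(length(truth), 0, noise_sd), 0)
  })
  structure(list(protein_total = protein_total, ligand_grid = ligand_grid,
                 observed = observed, noise_sd = noise_sd,
                 true_kd = true_kd, seed = as.integer(seed)),
            class = "titration_dataset")
}

#' Least-squares Kd estimate from a titration dataset
#'
#' Fits the closed-form binary binding curve by 1-D least squares on log(Kd)
#' (golden-section search; deterministic given the data).  The standard
#' error comes from the usual linearisation,
#' `se^2 = sigma^2 / sum(db/dKd)^2` with `sigma^2` the residual variance.
#'
#' @param data a [generate_titration()] dataset (or any list with the same
#'   fields) with at least 3 grid points spanning both sides of
#'   `protein_total`.
#' @return list with `kd_estimate` and `se`.
#' @examples
#' d <- generate_titration(0.664, 3.23, seq(0.2, 5, length.out = 10))
#' fit_kd(d)$kd_estimate   # 0.664
#' @export
fit_kd <- function(data) {
  g <- data$ligand_grid
  if (length(g) < 3 || min(g) >= data$protein_total ||
      max(g) <= data$protein_total) {
    abort_validation(paste0(
      "degenerate titration grid: need >= 3 points spanning below and ",
      "above protein_total"))
  }
  obs <- data$observed
  pt <- data$protein_total
  ss <- function(logkd) {
    pred <- vapply(g, solve_binary, numeric(1), p_total = pt,
                   kd = exp(logkd))
    sum((obs - pred)^2)
  }
  opt <- stats::optimize(ss, interval = log(c(1e-9, 1e6)), tol = 1e-12)
  kd <- exp(opt$minimum)
  # linearised SE: residual variance over squared gradient norm
  h <- max(kd * 1e-6, 1e-12)
  grad <- (vapply(g, solve_binary, numeric(1), p_total = pt, kd = kd + h) -
           vapply(g, solve_binary, numeric(1), p_total = pt,
                  kd = max(kd - h, 0))) / (h + min(kd, h))
  pred <- vapply(g, solve_binary, numeric(1), p_total = pt, kd = kd)
  dof <- max(length(g) - 1L, 1L)
  sigma2 <- sum((obs - pred)^2) / dof
  denom <- sum(grad^2)
  se <- if (denom > 0) sqrt(sigma2 / denom) else NA_real_
  list(kd_estimate = kd, se = se)
}
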