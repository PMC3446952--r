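# Independent oracles used across the suite.  Deliberately share no code
# with the package's solvers beyond the network container.

# 1:1 binding by scalar root finding on the mass-action residual
# f(b) = b*kd - (l-b)(p-b), strictly increasing on [0, min(l,p)].
binary_uniroot <- function(l, p, kd) {
  if (l == 0 || p == 0) return(0)
  if (kd == 0) return(min(l, p))
  f <- function(b) b * kd - (l - b) * (p - b)
  stats::uniroot(f, c(0, min(l, p)), tol = 1e-14)$root
}

# Random acyclic 1:1 networks of three shapes, drawn under the caller's seed.
random_network <- function() {
  shape <- sample(c("binary", "competitive", "ternary"), 1)
  tot <- function() stats::runif(1, 0.05, 5)
  kd <- function() exp(stats::runif(1, log(0.01), log(10)))
  if (shape == "binary") {
    binding_network(
      data.frame(name = c("L", "P"), total = c(tot(), tot())),
      data.frame(lhs = "L", rhs = "P", complex = "L.P", kd = kd()))
  } else if (shape == "competitive") {
    binding_network(
      data.frame(name = c("L", "A", "B"), total = c(tot(), tot(), tot())),
      data.frame(lhs = c("L", "L"), rhs = c("A", "B"),
                 complex = c("L.A", "L.B"), kd = c(kd(), kd())))
  } else {
    binding_network(
      data.frame(name = c("L", "P", "Q"), total = c(tot(), tot(), tot())),
      data.frame(lhs = c("L", "L.P", "P"), rhs = c("P", "Q", "Q"),
                 complex = c("L.P", "L.P.Q", "P.Q"),
                 kd = c(kd(), kd(), kd())))
  }
}

# Mass-action consistency of a solved state: for every reaction,
# [lhs]_free x [rhs]_free vs [complex] x Kd, relative scale.
mass_action_rel_error <- function(net, st) {
  conc <- c(st$free, st$complexes)
  errs <- vapply(seq_len(nrow(net$reactions)), function(i) {
    r <- net$reactions[i, ]
    lhsv <- conc[[r$lhs]]; rhsv <- conc[[r$rhs]]; cx <- conc[[r$complex]]
    abs(cx * r$kd - lhsv * rhsv) / max(1, cx * r$kd)
  }, numeric(1))
  if (length(errs)) max(errs) else 0
}

default_params <- parameter_set()
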