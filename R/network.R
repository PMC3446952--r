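#' Construct a 1:1 binding network
#'
#' A `binding_network` is the computable form of the carrier-protein wiring
#' diagram: a set of species with total concentrations and a list of 1:1
#' association reactions, each of which may consume a species or a complex
#' defined by an earlier reaction (so a ternary assembly is two stacked 1:1
#' steps).  The "defined earlier" rule makes the network acyclic, which in
#' turn makes every species' conservation residual monotone in its own free
#' concentration -- the property both solvers rely on.
#'
#' @param species data frame with columns `name`, `total` (umol/L).
#' @param reactions data frame with columns `lhs`, `rhs` (species or
#'   previously defined complex names), `complex` (product name) and `kd`
#'   (dissociation constant, umol/L, > 0).  May have zero rows.
#' @return an object of class `binding_network`.
#' @examples
#' binding_network(
#'   species = data.frame(name = c("L", "P"), total = c(1, 2)),
#'   reactions = data.frame(lhs = "L", rhs = "P", complex = "L.P", kd = 0.5)
#' )
#' @export
binding_network <- function(species, reactions = NULL) {
  if (is.null(reactions)) {
    reactions <- data.frame(lhs = character(), rhs = character(),
                            complex = character(), kd = numeric())
  }
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "total") %in% names(species)),
            all(c("lhs", "rhs", "complex", "kd") %in% names(reactions)))
  if (anyDuplicated(species$name)) {
    abort_validation("duplicate species names")
  }
  if (any(!is.finite(species$total) | species$total < 0)) {
    abort_validation("species totals must be finite and >= 0")
  }
  if (nrow(reactions) && any(!is.finite(reactions$kd) | reactions$kd <= 0)) {
    abort_validation("every reaction Kd must be finite and > 0")
  }

  defined <- species$name
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    if (!(r$lhs %in% defined) || !(r$rhs %in% defined)) {
      abort_validation(sprintf(
        "reaction %d ('%s'): both sides must be species or previously defined complexes",
        i, r$complex))
    }
    if (r$complex %in% defined) {
      abort_validation(sprintf("complex name '%s' already defined", r$complex))
    }
    defined <- c(defined, r$complex)
  }

  structure(list(species = species, reactions = reactions),
            class = "binding_network")
}

#' Default retinol carrier network from a parameter set
#'
#' Builds the three-reaction core -- retinol + RBP4 (Kd1), holo-RBP + TTR
#' (Kd2), apo-RBP + TTR (Kd3) -- and optionally the retinoic-acid side
#' (RA + CRABP1 at Kd4, RA + CRABP2 at Kd5, converted to umol/L per the
#' registry's unit setting).
#'
#' @param params a `parameter_set`.
#' @param include_ra add the retinoic-acid reactions; requires `ra_total`,
#'   `p3_total` and `p4_total` to be set.
#' @return a `binding_network`.
#' @examples
#' net <- build_network(parameter_set())
#' net$species$name   # Rt, P1, P2
#' @export
build_network <- function(params, include_ra = FALSE) {
  validate_parameters(params)
  species <- data.frame(
    name = c("Rt", "P1", "P2"),
    total = c(params$rt_total, params$p1_total, params$p2_total),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    lhs = c("Rt", "Rt.P1", "P1"),
    rhs = c("P1", "P2", "P2"),
    complex = c("Rt.P1", "Rt.P1.P2", "P1.P2"),
    kd = c(kd_umol(params, "kd1"), kd_umol(params, "kd2"),
           kd_umol(params, "kd3")),
    stringsAsFactors = FALSE
  )
  if (include_ra) {
    ra_side <- c(ra = params$ra_total, p3 = params$p3_total,
                 p4 = params$p4_total)
    if (anyNA(ra_side)) {
      abort_validation(
        "include_ra = TRUE requires ra_total, p3_total and p4_total to be set")
    }
    species <- rbind(species, data.frame(
      name = c("RA", "P3", "P4"),
      total = unname(ra_side),
      stringsAsFactors = FALSE
    ))
    reactions <- rbind(reactions, data.frame(
      lhs = c("RA", "RA"),
      rhs = c("P3", "P4"),
      complex = c("RA.P3", "RA.P4"),
      kd = c(kd_umol(params, "kd4"), kd_umol(params, "kd5")),
      stringsAsFactors = FALSE
    ))
  }
  binding_network(species, reactions)
}

# Expand complexes into monomials of the free species concentrations:
# [complex c] = prod_k free_k ^ m[c, k] / Kprod_c, where Kprod_c multiplies
# the Kds along the complex's formation path.  Valid because each reaction is
# 1:1 and references only earlier definitions.
network_monomials <- function(net) {
  sp <- net$species$name
  expo <- list()
  kprod <- numeric()
  for (s in sp) {
    e <- stats::setNames(rep(0, length(sp)), sp)
    e[s] <- 1
    expo[[s]] <- e
    kprod[s] <- 1
  }
  cx <- character()
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    expo[[r$complex]] <- expo[[r$lhs]] + expo[[r$rhs]]
    kprod[r$complex] <- kprod[r$lhs] * kprod[r$rhs] * r$kd
    cx <- c(cx, r$complex)
  }
  list(species = sp, complexes = cx,
       expo = do.call(rbind, expo[cx]),                     # cx x sp matrix
       kprod = kprod[cx])
}

#' Read / write a binding network as JSON
#'
#' @param net a `binding_network`.
#' @param path file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `binding_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "binding_network"))
  jsonlite::write_json(list(species = net$species, reactions = net$reactions),
                       path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  binding_network(x$species, x$reactions)
}

#' @export
print.binding_network <- function(x, ...) {
  cat(sprintf("<binding_network> %d species, %d reactions\n",
              nrow(x$species), nrow(x$reactions)))
  print(x$species, row.names = FALSE)
  if (nrow(x$reactions)) print(x$reactions, row.names = FALSE)
  invisible(x)
}
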