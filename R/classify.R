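# Geometric classification of binding geometries and adjustment of
# near-cyclic geometries to exact ring symmetry.

#' Classify the regular assembly implied by a binding geometry
#'
#' Pure function of (N, P, R_M) with precedence Filament, Cyclic,
#' NearCyclic, NearHelical:
#' Filament if P > 2 R_M (no cross-turn contact possible); Cyclic if N is
#' within 0.1 of an integer and |P| <= 0.5 Angstrom; NearCyclic if the ring
#' almost closes, accepting an axial error of up to 5 Angstrom per
#' interface, i.e. P < (N - 1) * 5; everything else NearHelical (subject to
#' the cross-turn steric screen).
#'
#' @param hp HelixParams (or a list with `N` and `P`).
#' @param R_M maximum monomer radius about its centroid, Angstrom (see
#'   [monomer_radius()]).
#' @return object of class `GeometryCategory`: list with `label`, `N`, `P`,
#'   `R_M`, `k` (nearest ring size), `closure_defect` (= P, the axial
#'   defect over a full turn).
#' @export
classify_geometry <- function(hp, R_M) {
  stopifnot(R_M > 0)
  N <- hp$N; P <- abs(hp$P)
  if (!is.finite(N) || P > 2 * R_M) {
    lab <- "Filament"
  } else if (abs(N - round(N)) <= 0.1 && P <= 0.5) {
    lab <- "Cyclic"
  } else if (P < (N - 1) * 5) {
    lab <- "NearCyclic"
  } else {
    lab <- "NearHelical"
  }
  structure(list(label = lab, N = N, P = P, R_M = R_M,
                 k = if (is.finite(N)) as.integer(round(N)) else NA_integer_,
                 closure_defect = P),
            class = "GeometryCategory")
}

#' @export
print.GeometryCategory <- function(x, ...) {
  cat(sprintf("<GeometryCategory %s: N=%.2f P=%.2f A (R_M=%.1f)>\n",
              x$label, x$N, x$P, x$R_M))
  invisible(x)
}

# exact projection of a transform onto the C_k manifold: keep the axis and
# axis point, set theta = 360/k (sign of rotation preserved) and trans = 0
.project_cyclic <- function(tr, k) {
  s <- screw_from_transform(tr)
  transform_from_screw(screw(s$O, s$axis, 360 / k, 0))
}

#' Adjust a near-cyclic pose to exact C_k ring symmetry
#'
#' Low-temperature Metropolis minimization of the interaction energy plus
#' ramped harmonic symmetry restraints w_theta (theta - 360/k)^2 +
#' w_t trans^2, followed by exact projection of the final screw onto the
#' cyclic manifold (theta = 360/k, trans = 0), so the post-condition holds
#' exactly: building k monomers from the adjusted pose closes the ring.
#'
#' @param pose a pose (list with `transform`, `energy`).
#' @param receptor,ligand ReducedStructures the pose relates.
#' @param k target ring size; the driver normally tries floor(N) and
#'   ceil(N).
#' @param ff ForceFieldParams.
#' @param steps Monte-Carlo steps per ramp stage.
#' @param seed RNG seed (deterministic given the seed).
#' @return adjusted pose with `energy_before`, `energy` (after),
#'   `adjusted = TRUE` and the enforced `k`.
#' @export
adjust_to_cyclic <- function(pose, receptor, ligand, k, ff,
                             steps = 300, seed = 1) {
  stopifnot(k >= 2)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  e_before <- pose$energy %||%
    as.numeric(interaction_energy(receptor, ligand, ff,
                                  pose = pose$transform))
  target <- 360 / k
  penal <- function(tr, w) {
    s <- screw_from_transform(tr)
    w[1] * (s$theta - target)^2 + w[2] * s$trans^2
  }
  efun <- function(tr)
    as.numeric(interaction_energy(receptor, ligand, ff, pose = tr))
  cur <- pose$transform
  ecur <- efun(cur)
  kT <- 0.1
  for (w in list(c(0.5, 0.5), c(5, 5), c(50, 50))) {
    pcur <- penal(cur, w)
    for (i in seq_len(steps)) {
      dx <- stats::runif(3, -0.3, 0.3)
      da <- stats::runif(3, -0.5, 0.5)        # degrees
      ang <- sqrt(sum(da^2))
      Rd <- if (ang < 1e-12) diag(3) else .rotmat(da / ang, ang)
      cand <- rigid_transform(Rd %*% cur$R, as.numeric(Rd %*% cur$t) + dx)
      ec <- efun(cand); pc <- penal(cand, w)
      if ((ec + pc) - (ecur + pcur) <= 0 ||
          stats::runif(1) < exp(-((ec + pc) - (ecur + pcur)) / kT)) {
        cur <- cand; ecur <- ec; pcur <- pc
      }
    }
  }
  adj <- .project_cyclic(cur, k)
  sfin <- screw_from_transform(adj)
  ok <- abs(sfin$theta - target) <= 0.01 && abs(sfin$trans) <= 0.01
  list(transform = adj, energy = efun(adj), energy_before = e_before,
       adjusted = ok, k = k,
       start_id = pose$start_id %||% NA_integer_)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
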