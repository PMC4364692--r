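# Deterministic synthetic-structure generator: pseudo-protein monomers and
# assemblies with known ground-truth screw parameters, so every stage of
# the pipeline is testable without downloading real structures.

.FIX_RESNAMES <- c("ALA", "ARG", "ASP", "LEU", "SER", "GLU", "LYS", "PHE",
                   "THR", "VAL", "GLY", "ASN")

#' Generate a deterministic toy monomer
#'
#' Builds a self-avoiding pseudo-protein with backbone-like atoms (N, CA,
#' C, O) plus 1-2 side-chain pseudo-atoms per residue, following one of
#' three backbone shapes: a compact `blob` (perturbed space-filling
#' spiral), a straight `rod`, or a `horseshoe` arc (which yields a nonzero
#' inner radius when assembled into a ring).  Residue names cycle through a
#' fixed set including charged types, so coarse-graining produces charged
#' beads.  Identical seeds reproduce identical coordinates.
#'
#' @param n_residues number of residues (>= 3).
#' @param shape `"blob"`, `"rod"` or `"horseshoe"`.
#' @param seed RNG seed.
#' @param chain chain id.
#' @param resnames optional residue-name vector (recycled), overriding the
#'   default cycle — e.g. to engineer charge placement.
#' @return a Structure.
#' @export
make_toy_monomer <- function(n_residues, shape = c("blob", "rod", "horseshoe"),
                             seed = 1, chain = "A", resnames = NULL) {
  stopifnot(n_residues >= 3)
  shape <- match.arg(shape)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  i <- seq_len(n_residues)
  ca <- switch(shape,
    rod = cbind(3.2 * i, 1.5 * cos(i * 100 * pi / 180),
                1.5 * sin(i * 100 * pi / 180)),
    horseshoe = {
      # arc spanning ~200 degrees, radius scaled so consecutive Calpha are
      # ~3.8 A apart
      span <- 200 * pi / 180
      rad <- 3.8 * (n_residues - 1) / span
      ang <- span * (i - 1) / (n_residues - 1)
      cbind(rad * cos(ang), rad * sin(ang),
            1.2 * sin(i * 140 * pi / 180))
    },
    blob = {
      # compact solenoid: Calpha wound on a cylinder (3.8 A along the
      # coil, 4.2 A between turns) — globular and self-avoiding by
      # construction
      rad <- 11
      ang <- 3.8 / rad * (i - 1)
      cbind(rad * cos(ang), rad * sin(ang), 4.5 * ang / (2 * pi))
    })
  ca <- ca + matrix(stats::runif(3 * n_residues, -0.3, 0.3), ncol = 3)
  # local frame per residue for the satellite atoms
  atoms <- vector("list", n_residues)
  for (j in i) {
    tvec <- if (j < n_residues) ca[min(j + 1, n_residues), ] - ca[j, ]
            else ca[j, ] - ca[j - 1, ]
    tvec <- tvec / sqrt(sum(tvec^2))
    a <- c(0, 0, 1); if (abs(sum(a * tvec)) > 0.9) a <- c(1, 0, 0)
    n1 <- a - sum(a * tvec) * tvec; n1 <- n1 / sqrt(sum(n1^2))
    n2 <- .cross(tvec, n1)
    rn <- if (is.null(resnames)) .FIX_RESNAMES[((j - 1) %% length(.FIX_RESNAMES)) + 1]
          else resnames[((j - 1) %% length(resnames)) + 1]
    pos <- rbind(N  = ca[j, ] - 1.45 * tvec + 0.4 * n1,
                 CA = ca[j, ],
                 C  = ca[j, ] + 1.52 * tvec - 0.4 * n1,
                 O  = ca[j, ] + 1.6 * tvec + 0.9 * n2,
                 CB = ca[j, ] + 1.6 * n1,
                 CG = ca[j, ] + 2.9 * n1 + 0.5 * n2)
    nm <- rownames(pos)
    if (rn == "GLY") { pos <- pos[1:4, , drop = FALSE]; nm <- nm[1:4] }
    if (rn == "ALA" || rn == "SER" || rn == "THR" || rn == "VAL") {
      pos <- pos[1:5, , drop = FALSE]; nm <- nm[1:5]
    }
    atoms[[j]] <- data.frame(
      atom = nm, element = substr(nm, 1, 1), resid = j, ins = "",
      resname = rn, chain = chain,
      x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, atoms); rownames(at) <- NULL
  structure_new(at, label = sprintf("toy_%s%d_s%d", shape, n_residues, seed))
}

#' Build an assembly fixture with known ground truth
#'
#' Places `n` copies of the monomer by repeated application of the screw;
#' optional per-interface jitter (axial translation in Angstrom and
#' rotation in degrees about a random axis) perturbs each step
#' independently, emulating near-cyclic defects.  The generating truth is
#' returned alongside the structure.
#'
#' @param monomer Structure.
#' @param s Screw.
#' @param n copies.
#' @param jitter_trans axial jitter per interface, Angstrom.
#' @param jitter_rot rotational jitter per interface, degrees.
#' @param seed RNG seed for the jitter.
#' @return list with `structure` (n chains) and `truth` (class
#'   `FixtureTruth`: the screw, monomer label, jitter sizes, seed).
#' @export
make_assembly_fixture <- function(monomer, s, n, jitter_trans = 0,
                                  jitter_rot = 0, seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  base <- transform_from_screw(s)
  copies <- vector("list", n)
  copies[[1]] <- monomer
  cur <- rigid_transform()
  for (i in 2:n) {
    step <- base
    if (jitter_trans > 0 || jitter_rot > 0) {
      dz <- stats::runif(1, -1, 1) * jitter_trans * s$axis
      axr <- stats::rnorm(3); axr <- axr / sqrt(sum(axr^2))
      dR <- .rotmat(axr, stats::runif(1, -1, 1) * jitter_rot)
      step <- compose_transforms(step, rigid_transform(dR, dz))
    }
    cur <- compose_transforms(cur, step)
    copies[[i]] <- apply_transform(monomer, cur)
  }
  truth <- structure(list(screw = s, monomer = monomer$label, n = n,
                          jitter_trans = jitter_trans,
                          jitter_rot = jitter_rot, seed = seed),
                     class = "FixtureTruth")
  list(structure = .stack_chains(copies, sprintf("%s_fx%d", monomer$label, n)),
       truth = truth)
}

#' Extract one chain of a multi-chain structure as a monomer
#' @param s Structure.
#' @param chain chain id.
#' @export
get_chain <- function(s, chain) {
  out <- subset_atoms(s, s$atoms$chain == chain)
  if (!nrow(out$atoms)) stop("selection error: no such chain ", chain)
  out
}
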