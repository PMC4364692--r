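# Contact-constrained Metropolis Monte Carlo exploration of a binding-mode
# family, recording helical morphology descriptors at every step.

#' Monte-Carlo exploration configuration
#'
#' Defaults follow the standard protocol: 1e5 steps at 300 K (energies in
#' RT), uniform proposals within +/- 5 degrees per rotational variable and
#' +/- 3 Angstrom per translation, trajectory confined to f_NAT > 0.5
#' versus the reference contact set.
#'
#' @param steps number of MC steps.
#' @param temperature Kelvin; the Metropolis factor is exp(-dE / (T/300))
#'   with E in RT at 300 K.  0 gives a pure quench.
#' @param rot_width rotational proposal half-width, degrees.
#' @param trans_width translational proposal half-width, Angstrom.
#' @param fnat_min hard lower bound on f_NAT for accepted states.
#' @param contact_cutoff contact criterion (same convention as
#'   [contacts()]), applied to the representation being sampled.
#' @param seed RNG seed.
#' @return object of class `McConfig`.
#' @export
mc_config <- function(steps = 1e5, temperature = 300, rot_width = 5,
                      trans_width = 3, fnat_min = 0.5, contact_cutoff = 7,
                      seed = 1) {
  stopifnot(steps >= 1, rot_width > 0, trans_width > 0)
  structure(list(steps = as.integer(steps), temperature = temperature,
                 rot_width = rot_width, trans_width = trans_width,
                 fnat_min = fnat_min, contact_cutoff = contact_cutoff,
                 seed = as.integer(seed)), class = "McConfig")
}

#' Contact-constrained Metropolis exploration of a binding mode
#'
#' Rigid-body MC of the ligand relative to the fixed receptor.  Proposals
#' violating the f_NAT constraint are rejected outright (and counted as
#' rejections in the acceptance rate); otherwise standard Metropolis
#' acceptance on the interaction energy.  One record is emitted per step:
#' energy, N, P, dir, ligand RMSD versus the start, f_NAT, f_IR and the
#' accepted flag.
#'
#' @param receptor,ligand ReducedStructures.
#' @param start pose (list with `transform`) satisfying the constraint.
#' @param ref_contacts reference ContactSet (same representation/cutoff as
#'   `cfg$contact_cutoff` sampling).
#' @param cfg McConfig.
#' @param ff ForceFieldParams.
#' @return data.frame of class `McTrajectory` (one row per step) with
#'   attribute `acceptance_rate`; the final transform is attached as
#'   attribute `final`.
#' @export
explore <- function(receptor, ligand, start, ref_contacts, cfg, ff) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  lig0 <- coords(ligand)
  ref_res_b <- interface_residues(ref_contacts, "b")
  eval_state <- function(tr) {
    placed <- set_coords(ligand, apply_transform(lig0, tr))
    cs <- contacts(receptor, placed, cutoff = cfg$contact_cutoff)
    fn <- if (nrow(cs)) fnat(ref_contacts, cs) else 0
    list(cs = cs, fnat = fn)
  }
  cur <- start$transform
  st <- eval_state(cur)
  if (st$fnat <= cfg$fnat_min)
    stop("precondition error: start pose violates the f_NAT constraint")
  ecur <- as.numeric(interaction_energy(receptor, ligand, ff, pose = cur))
  ref_xyz <- apply_transform(lig0, cur)
  kT <- cfg$temperature / 300
  n <- cfg$steps
  rec <- data.frame(step = seq_len(n), energy = NA_real_, N = NA_real_,
                    P = NA_real_, dir = NA_character_, rmsd = NA_real_,
                    fnat = NA_real_, fir = NA_real_, accepted = FALSE)
  n_acc <- 0
  fcur <- st$fnat
  fircur <- if (length(ref_res_b)) fir(ref_res_b,
                                       interface_residues(st$cs, "b")) else NA
  for (i in seq_len(n)) {
    da <- stats::runif(3, -cfg$rot_width, cfg$rot_width)
    dx <- stats::runif(3, -cfg$trans_width, cfg$trans_width)
    ang <- sqrt(sum(da^2))
    Rd <- if (ang < 1e-12) diag(3) else .rotmat(da / ang, ang)
    # rotate about the current ligand centroid, then translate
    ctr <- colMeans(apply_transform(lig0, cur))
    cand <- rigid_transform(Rd %*% cur$R,
                            as.numeric(Rd %*% (cur$t - ctr)) + ctr + dx)
    stc <- eval_state(cand)
    acc <- FALSE
    if (stc$fnat > cfg$fnat_min) {
      ec <- as.numeric(interaction_energy(receptor, ligand, ff, pose = cand))
      dE <- ec - ecur
      if (dE <= 0 || (kT > 0 && stats::runif(1) < exp(-dE / kT))) {
        cur <- cand; ecur <- ec; fcur <- stc$fnat
        fircur <- if (length(ref_res_b))
          fir(ref_res_b, interface_residues(stc$cs, "b")) else NA
        acc <- TRUE
      }
    }
    if (acc) n_acc <- n_acc + 1
    s <- screw_from_transform(cur)
    hp <- helix_params(s, ligand)
    rec$energy[i] <- ecur; rec$N[i] <- hp$N; rec$P[i] <- hp$P
    rec$dir[i] <- hp$dir
    rec$rmsd[i] <- sqrt(mean(rowSums((apply_transform(lig0, cur) - ref_xyz)^2)))
    rec$fnat[i] <- fcur; rec$fir[i] <- fircur; rec$accepted[i] <- acc
  }
  attr(rec, "acceptance_rate") <- n_acc / n
  attr(rec, "final") <- cur
  class(rec) <- c("McTrajectory", "data.frame")
  rec
}

#' Select MC starting poses from a targeted docking run
#'
#' Retains poses with f_NAT above `fnat_min`, interface Calpha/bead RMSD
#' below `irmsd_max` and energy below `e_ref + e_window` (the reference
#' energy defaults to the best energy in the run).
#'
#' @param result DockResult.
#' @param ref_pose RigidTransform of the reference binding mode.
#' @param ref_contacts reference ContactSet.
#' @param fnat_min,irmsd_max,e_window thresholds (defaults 0.5, 3.5
#'   Angstrom, 5 RT).
#' @param e_ref reference energy, RT.
#' @param contact_cutoff cutoff used when recomputing pose contacts.
#' @return list of poses (possibly empty), each annotated with `fnat` and
#'   `irmsd`.
#' @export
select_mc_starts <- function(result, ref_pose, ref_contacts,
                             fnat_min = 0.5, irmsd_max = 3.5, e_window = 5,
                             e_ref = NULL, contact_cutoff = 7) {
  poses <- result$poses
  if (!length(poses)) return(list())
  e <- vapply(poses, `[[`, numeric(1), "energy")
  e_ref <- e_ref %||% min(e)
  lig <- result$ligand
  ref_placed <- set_coords(lig, apply_transform(coords(lig), ref_pose))
  out <- list()
  for (p in poses) {
    if (p$energy > e_ref + e_window) next
    placed <- set_coords(lig, apply_transform(coords(lig), p$transform))
    cs <- contacts(result$receptor, placed, cutoff = contact_cutoff)
    fn <- if (nrow(cs)) fnat(ref_contacts, cs) else 0
    if (fn <= fnat_min) next
    ir <- tryCatch(
      rmsd(result$receptor, result$receptor, selection = NULL,
           mode = "interface", A_lig = ref_placed, B_lig = placed,
           ref_contacts = ref_contacts),
      error = function(e) Inf)
    if (ir >= irmsd_max) next
    p$fnat <- fn; p$irmsd <- ir
    out[[length(out) + 1]] <- p
  }
  out
}
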