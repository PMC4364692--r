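# Reduced-representation interaction energy: smooth 6-8 van der Waals term
# plus a Coulomb term screened by a distance-dependent dielectric
# eps(r) = eps0 * r.  All energies are in RT at 300 K.

# Coulomb prefactor q1 q2 / r in RT*Angstrom for unit charges:
# 332.0636 kcal/(mol Angstrom) / 0.59248 kcal/mol (RT at 300 K)
.COUL_RT <- 332.0636 / 0.59248

#' Reduced force-field parameters
#'
#' Per bead-class radius (Angstrom) and well depth (RT); pair coefficients
#' are combined Lorentz-Berthelot style, rm_ij = R_i + R_j and
#' eps_ij = sqrt(eps_i eps_j), then A_ij = 3 eps rm^8, B_ij = 4 eps rm^6 so
#' the 6-8 well E = A/r^8 - B/r^6 has depth eps at its minimum
#' r = rm = sqrt(4A/3B).  Pairs listed in `repulsive` get the sign of B
#' flipped (purely repulsive interaction).
#'
#' @param radius named numeric, per-class bead radius.
#' @param eps named numeric, per-class well depth (RT).
#' @param eps0 distance-dependent dielectric scale (eps(r) = eps0 r).
#' @param cutoff nonbonded cutoff, Angstrom.
#' @param repulsive character vector of "CLASS1:CLASS2" pairs.
#' @param clash_energy pair-energy threshold (RT) above which the steric
#'   screen reports a clash.
#' @return object of class `ForceFieldParams`.
#' @export
forcefield_params <- function(radius = c(BB = 2.0, SCA = 2.2, SCP = 2.2,
                                         SCC = 2.4),
                              eps = c(BB = 0.20, SCA = 0.45, SCP = 0.30,
                                      SCC = 0.30),
                              eps0 = 15, cutoff = 20, repulsive = character(),
                              clash_energy = 5) {
  stopifnot(all(radius > 0), all(eps >= 0), cutoff >= 2 * max(radius))
  structure(list(radius = radius, eps = eps, eps0 = eps0, cutoff = cutoff,
                 repulsive = repulsive, clash_energy = clash_energy),
            class = "ForceFieldParams")
}

#' Read force-field parameters from a JSON file
#' @param path JSON file with any subset of the [forcefield_params()]
#'   arguments.
#' @export
read_forcefield <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- formals(forcefield_params)
  do.call(forcefield_params, utils::modifyList(
    list(), cfg[intersect(names(cfg), names(args))]))
}

.pair_tables <- function(rec, lig, ff) {
  cr <- rec$beads$class; cl <- lig$beads$class
  classes <- union(names(ff$radius), union(cr, cl))
  rad <- ff$radius[classes]; rad[is.na(rad)] <- 2.2
  ep <- ff$eps[classes];     ep[is.na(ep)] <- 0.3
  names(rad) <- names(ep) <- classes
  rm_ <- outer(rad[cr], rad[cl], `+`)
  epsij <- sqrt(outer(ep[cr], ep[cl]))
  sgn <- matrix(1, length(cr), length(cl))
  if (length(ff$repulsive)) {
    keys <- outer(cr, cl, function(a, b) paste0(a, ":", b))
    keys2 <- outer(cr, cl, function(a, b) paste0(b, ":", a))
    sgn[keys %in% ff$repulsive | keys2 %in% ff$repulsive] <- -1
  }
  list(A = 3 * epsij * rm_^8,
       B = 4 * epsij * rm_^6 * sgn,
       QQ = .COUL_RT * outer(rec$beads$charge, lig$beads$charge))
}

#' Interaction energy between two rigid reduced structures
#'
#' E = sum over pairs within the cutoff of A/r^8 - B/r^6 + q_i q_j /
#' (eps0 r^2).  Bead pairs closer than 1 Angstrom are evaluated at
#' r = 1 (soft cap); any pair below 0.1 Angstrom sets the `"capped"`
#' attribute.
#'
#' @param rec,lig ReducedStructures (same scheme).
#' @param ff ForceFieldParams.
#' @param pose optional RigidTransform applied to the ligand.
#' @param method `"pairlist"` (cell-list neighbor search, default) or
#'   `"brute"` (plain double loop; the independent oracle used in tests).
#' @return energy in RT, with logical attribute `capped`.
#' @export
interaction_energy <- function(rec, lig, ff, pose = NULL,
                               method = c("pairlist", "brute")) {
  method <- match.arg(method)
  if (!identical(rec$scheme, lig$scheme))
    stop("receptor and ligand use different bead schemes")
  xr <- coords(rec)
  xl <- coords(lig)
  if (!is.null(pose)) xl <- apply_transform(xl, pose)
  pt <- .pair_tables(rec, lig, ff)
  if (method == "brute") {
    e <- 0; capped <- FALSE
    for (i in seq_len(nrow(xr))) for (j in seq_len(nrow(xl))) {
      r2 <- sum((xr[i, ] - xl[j, ])^2)
      if (r2 > ff$cutoff^2) next
      if (r2 < 0.01) capped <- TRUE
      r2c <- max(r2, 1)
      e <- e + pt$A[i, j] / r2c^4 - pt$B[i, j] / r2c^3 + pt$QQ[i, j] / (ff$eps0 * r2c)
    }
    return(structure(e, capped = capped))
  }
  nb <- .neighbor_pairs(xr, xl, ff$cutoff)
  if (!nrow(nb)) return(structure(0, capped = FALSE))
  r2 <- rowSums((xr[nb[, 1], , drop = FALSE] - xl[nb[, 2], , drop = FALSE])^2)
  capped <- any(r2 < 0.01)
  r2 <- pmax(r2, 1)
  idx <- cbind(nb[, 1], nb[, 2])
  e <- sum(pt$A[idx] / r2^4 - pt$B[idx] / r2^3 + pt$QQ[idx] / (ff$eps0 * r2))
  structure(e, capped = capped)
}

# Cell-list cross pairs within cutoff between two coordinate sets.
# Returns a 2-column index matrix (i into a, j into b).
.neighbor_pairs <- function(a, b, cutoff) {
  na <- nrow(a); nb <- nrow(b)
  if (na * nb <= 250000) {           # small: vectorized all-pairs
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    w <- which(d2 <= cutoff^2, arr.ind = TRUE)
    return(unname(w))
  }
  h <- cutoff
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  ca <- floor(sweep(a, 2, lo) / h); cb <- floor(sweep(b, 2, lo) / h)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_len(nb), keyb)
  res_i <- vector("list", na); res_j <- vector("list", na)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(na)) {
    cand <- integer()
    for (k in seq_len(27)) {
      kk <- paste(ca[i, 1] + off[k, 1], ca[i, 2] + off[k, 2],
                  ca[i, 3] + off[k, 3])
      cand <- c(cand, bmap[[kk]])
    }
    if (!length(cand)) next
    d2 <- colSums((t(b[cand, , drop = FALSE]) - a[i, ])^2)
    keep <- cand[d2 <= cutoff^2]
    res_i[[i]] <- rep.int(i, length(keep)); res_j[[i]] <- keep
  }
  cbind(unlist(res_i), unlist(res_j))
}

#' Per-residue best interaction energy over a set of poses
#'
#' Each residue of the receptor (and of the ligand) is annotated with the
#' most favorable (minimum) interaction energy among the poses whose
#' interface contains it, plus a normalized scale where the best value in
#' the run maps to 100 percent.  Residues contacted in no pose get NA.
#'
#' @param poses list of poses; each must have `transform` and `energy`.
#' @param rec,lig ReducedStructures.
#' @param cutoff bead-bead contact cutoff defining interface membership.
#' @return data.frame with `side`, `chain`, `resid`, `energy`, `percent`.
#' @export
per_residue_best_energy <- function(poses, rec, lig, cutoff = 7) {
  rb <- rec$beads; lb <- lig$beads
  best_r <- rep(NA_real_, length(unique(paste(rb$chain, rb$resid))))
  keys_r <- unique(paste(rb$chain, rb$resid))
  keys_l <- unique(paste(lb$chain, lb$resid))
  best_l <- rep(NA_real_, length(keys_l))
  xr <- coords(rec)
  for (p in poses) {
    xl <- apply_transform(coords(lig), p$transform)
    nb <- .neighbor_pairs(xr, xl, cutoff)
    if (!nrow(nb)) next
    rk <- unique(paste(rb$chain, rb$resid)[nb[, 1]])
    lk <- unique(paste(lb$chain, lb$resid)[nb[, 2]])
    ir <- match(rk, keys_r); il <- match(lk, keys_l)
    best_r[ir] <- pmin(best_r[ir], p$energy, na.rm = TRUE)
    best_l[il] <- pmin(best_l[il], p$energy, na.rm = TRUE)
  }
  emin <- suppressWarnings(min(c(best_r, best_l), na.rm = TRUE))
  pct <- function(e) if (is.finite(emin) && emin < 0) 100 * e / emin
                     else NA_real_
  rbind(
    data.frame(side = "receptor",
               chain = sub(" .*", "", keys_r),
               resid = as.integer(sub(".* ", "", keys_r)),
               energy = best_r, percent = pct(best_r)),
    data.frame(side = "ligand",
               chain = sub(" .*", "", keys_l),
               resid = as.integer(sub(".* ", "", keys_l)),
               energy = best_l, percent = pct(best_l)))
}

#' Steric screen across helical turns
#'
#' For a binding geometry with N monomers per turn, computes the
#' interaction energy between monomer i and the two closest monomers of the
#' next turn, i + M and i + M + 1 with M = floor(N), and flags a clash if
#' either energy exceeds the force field's clash threshold.  A pure
#' translation (infinite N) trivially has no cross-turn contact.
#'
#' @param monomer ReducedStructure.
#' @param s Screw.
#' @param ff ForceFieldParams.
#' @return list with `M`, `E_M`, `E_M1`, `clash`.
#' @export
steric_screen <- function(monomer, s, ff) {
  hp <- helix_params(s, monomer)
  if (!is.finite(hp$N))
    return(list(M = Inf, E_M = 0, E_M1 = 0, clash = FALSE))
  M <- floor(hp$N)
  tr <- transform_from_screw(s)
  eM  <- interaction_energy(monomer, monomer, ff, pose = transform_power(tr, M))
  eM1 <- interaction_energy(monomer, monomer, ff,
                            pose = transform_power(tr, M + 1))
  list(M = M, E_M = as.numeric(eM), E_M1 = as.numeric(eM1),
       clash = as.numeric(eM) > ff$clash_energy ||
               as.numeric(eM1) > ff$clash_energy)
}
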