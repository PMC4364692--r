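# Interface and morphology metrics: residue-residue contacts, fraction of
# native contacts (f_NAT), fraction of interface residues (f_IR), RMSD
# variants, solvent-accessible and buried surface area, groove width.

#' Residue-residue contacts between two structures
#'
#' A residue pair (one residue from each partner) is a contact if any pair
#' of their heavy atoms (or beads) is closer than `cutoff`.
#'
#' @param A,B Structures or ReducedStructures.
#' @param cutoff distance cutoff, Angstrom (community-standard 5.0 for heavy
#'   atoms; use a larger value for beads).
#' @return object of class `ContactSet`: data.frame with `res_a`, `res_b`
#'   residue keys ("chain resid ins"), plus the criterion as attributes.
#' @export
contacts <- function(A, B, cutoff = 5) {
  stopifnot(cutoff > 0)
  da <- if (inherits(A, "Structure")) A$atoms else A$beads
  db <- if (inherits(B, "Structure")) B$atoms else B$beads
  xa <- cbind(da$x, da$y, da$z); xb <- cbind(db$x, db$y, db$z)
  nb <- .neighbor_pairs(xa, xb, cutoff)
  ka <- paste(da$chain, da$resid, da$ins)
  kb <- paste(db$chain, db$resid, db$ins)
  if (nrow(nb)) {
    prs <- unique(data.frame(res_a = ka[nb[, 1]], res_b = kb[nb[, 2]],
                             stringsAsFactors = FALSE))
  } else {
    prs <- data.frame(res_a = character(), res_b = character())
  }
  rownames(prs) <- NULL
  structure(prs, cutoff = cutoff,
            atoms = if (inherits(A, "Structure")) "heavy" else "bead",
            class = c("ContactSet", "data.frame"))
}

.pair_keys <- function(cs) paste(cs$res_a, "|", cs$res_b)

#' Fraction of native contacts
#'
#' f_NAT = |reference pairs also in test| / |reference pairs|.
#' @param reference,test ContactSets over the same monomer numbering.
#' @export
fnat <- function(reference, test) {
  if (!nrow(reference)) stop("undefined fraction: empty reference contact set")
  mean(.pair_keys(reference) %in% .pair_keys(test))
}

#' Interface residues on one side of a contact set
#' @param cs ContactSet.
#' @param side `"a"` (receptor) or `"b"` (ligand).
#' @export
interface_residues <- function(cs, side = c("a", "b")) {
  side <- match.arg(side)
  unique(if (side == "a") cs$res_a else cs$res_b)
}

#' Fraction of shared interface residues (per monomer side)
#'
#' f_IR = |reference residues also in test| / |reference residues| computed
#' on a single monomer's side of the interface.
#' @param reference,test character vectors of residue keys (see
#'   [interface_residues()]), or ContactSets (then `side` selects the
#'   monomer).
#' @param side which side when ContactSets are given.
#' @export
fir <- function(reference, test, side = "a") {
  if (inherits(reference, "ContactSet"))
    reference <- interface_residues(reference, side)
  if (inherits(test, "ContactSet"))
    test <- interface_residues(test, side)
  if (!length(reference)) stop("undefined fraction: empty reference interface")
  mean(reference %in% test)
}

# ---- RMSD ---------------------------------------------------------------

.paired_coords <- function(A, B, selection = "CA", residues = NULL) {
  da <- if (inherits(A, "Structure")) A$atoms else A$beads
  db <- if (inherits(B, "Structure")) B$atoms else B$beads
  if (inherits(A, "ReducedStructure") && identical(selection, "CA"))
    selection <- "BB"
  if (!is.null(selection)) {
    da <- da[da$atom %in% selection, , drop = FALSE]
    db <- db[db$atom %in% selection, , drop = FALSE]
  }
  if (!is.null(residues)) {
    da <- da[paste(da$chain, da$resid, da$ins) %in% residues, , drop = FALSE]
    db <- db[paste(db$chain, db$resid, db$ins) %in% residues, , drop = FALSE]
  }
  ka <- paste(da$chain, da$resid, da$ins, da$atom)
  kb <- paste(db$chain, db$resid, db$ins, db$atom)
  common <- intersect(ka, kb)
  if (!length(common)) stop("selection error: no paired atoms")
  list(a = as.matrix(da[match(common, ka), c("x", "y", "z")]),
       b = as.matrix(db[match(common, kb), c("x", "y", "z")]))
}

#' RMSD between two structures
#'
#' Modes: `"global"` (optimal superposition over the selection),
#' `"direct"` (no fitting, coordinates compared as-is), `"ligand"`
#' (for two-monomer assemblies: superpose the first monomers, report the
#' unfitted RMSD of the second), `"interface"` (fit and measure on
#' interface residues of a reference contact set).
#'
#' @param A,B Structures.  For `"ligand"` mode give `A_lig`/`B_lig`.
#' @param selection atom-name selection (default Calpha).
#' @param mode see above.
#' @param A_lig,B_lig second monomers for `"ligand"` mode.
#' @param ref_contacts ContactSet for `"interface"` mode; its residues on
#'   both sides define the interface selection (keys refer to A/A_lig).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(A, B, selection = "CA",
                 mode = c("global", "direct", "ligand", "interface"),
                 A_lig = NULL, B_lig = NULL, ref_contacts = NULL) {
  mode <- match.arg(mode)
  if (mode == "direct") {
    p <- .paired_coords(A, B, selection)
    return(sqrt(mean(rowSums((p$a - p$b)^2))))
  }
  if (mode == "global") {
    p <- .paired_coords(A, B, selection)
    return(kabsch(p$a, p$b)$rmsd)
  }
  if (mode == "ligand") {
    stopifnot(!is.null(A_lig), !is.null(B_lig))
    pr <- .paired_coords(A, B, selection)
    fit <- kabsch(pr$a, pr$b)$transform
    pl <- .paired_coords(A_lig, B_lig, selection)
    return(sqrt(mean(rowSums((apply_transform(pl$a, fit) - pl$b)^2))))
  }
  # interface mode: restrict to residues in the reference interface,
  # superpose on them and measure there (CAPRI-style iRMSD)
  stopifnot(!is.null(ref_contacts))
  if (is.null(A_lig)) {
    resk <- unique(c(ref_contacts$res_a, ref_contacts$res_b))
    p <- .paired_coords(A, B, selection, residues = resk)
    return(kabsch(p$a, p$b)$rmsd)
  }
  pa <- .paired_coords(A, B, selection,
                       residues = interface_residues(ref_contacts, "a"))
  pb <- .paired_coords(A_lig, B_lig, selection,
                       residues = interface_residues(ref_contacts, "b"))
  kabsch(rbind(pa$a, pb$a), rbind(pa$b, pb$b))$rmsd
}

# ---- SASA ---------------------------------------------------------------

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          FE = 1.80, ZN = 1.39, MG = 1.73, MN = 1.61, CL = 1.75, NA. = 2.27,
          BR = 1.85)

.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by sphere-point sampling on each atom's solvent-expanded
#' sphere, with points inside any neighboring expanded sphere removed.
#'
#' @param s Structure (heavy atoms).
#' @param probe probe radius, Angstrom (water default 1.4).
#' @param n_points sample points per atom (default 960).
#' @param radii named van der Waals radius table by element; unknown
#'   elements raise an error.
#' @return numeric vector of per-atom areas (Angstrom^2); `sum()` gives the
#'   total.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, radii = .VDW) {
  at <- s$atoms
  el <- toupper(at$element)
  el[el == "NA"] <- "NA."
  r <- radii[el]
  if (anyNA(r))
    stop("radius-table error: unknown element(s) ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  r <- unname(r) + probe
  xyz <- coords(s)
  n <- nrow(xyz)
  pts <- .fib_sphere(n_points)
  maxr <- max(r)
  nb <- .neighbor_pairs(xyz, xyz, 2 * maxr)
  nb <- nb[nb[, 1] != nb[, 2], , drop = FALSE]
  # keep only true overlaps
  d2 <- rowSums((xyz[nb[, 1], , drop = FALSE] - xyz[nb[, 2], , drop = FALSE])^2)
  keep <- d2 < (r[nb[, 1]] + r[nb[, 2]])^2
  nb <- nb[keep, , drop = FALSE]
  nlist <- split(nb[, 2], factor(nb[, 1], levels = seq_len(n)))
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * r[i] + rep(xyz[i, ], each = n_points)
    free <- rep(TRUE, n_points)
    for (j in nlist[[i]]) {
      dj <- colSums((t(p) - xyz[j, ])^2)
      free <- free & dj > r[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  area
}

#' Buried surface area of an interface, with region decomposition
#'
#' BSA of monomer X = ASA(X alone) - ASA(X within the complex), computed
#' per monomer on the assembled coordinates.  Region contributions use the
#' truncation scheme: the BSA computation is repeated after deleting the
#' region's residues and the difference is the region's contribution
#' (`method = "truncation"`).  `method = "atomic"` instead sums per-atom
#' ASA losses by region, which is exactly additive.
#'
#' @param A,B Structures in their assembled relative position.
#' @param regions optional RegionSpec naming regions of interest.
#' @param method `"truncation"` (default) or `"atomic"`.
#' @param ... passed to [sasa()] (probe, n_points).
#' @return list with `bsa_a`, `bsa_b` (Angstrom^2) and, when `regions` is
#'   given, data frames `regions_a`, `regions_b` of per-region
#'   contributions (including a `rest` row for residues in no named
#'   region).
#' @export
buried_surface <- function(A, B, regions = NULL,
                           method = c("truncation", "atomic"), ...) {
  method <- match.arg(method)
  half <- function(X, Y) {       # per-atom buried area of X against Y
    cx <- structure(list(atoms = rbind(X$atoms, Y$atoms), label = "cx"),
                    class = "Structure")
    sasa(X, ...) - sasa(cx, ...)[seq_len(nrow(X$atoms))]
  }
  ba <- half(A, B); bb <- half(B, A)
  out <- list(bsa_a = sum(ba), bsa_b = sum(bb))
  if (is.null(regions)) return(out)
  decomp <- function(X, Y, per_atom) {
    nm <- names(regions$ranges)
    allres <- unlist(lapply(nm, function(g) region_residues(regions, g)))
    rows <- lapply(nm, function(g) {
      res <- region_residues(regions, g)
      inreg <- X$atoms$resid %in% res
      if (method == "atomic") {
        contrib <- sum(per_atom[inreg])
      } else {
        if (all(!inreg)) {
          contrib <- 0
        } else if (all(inreg)) {
          contrib <- sum(per_atom)
        } else {
          Xt <- subset_atoms(X, !inreg)
          contrib <- sum(per_atom) - sum(half(Xt, Y))
        }
      }
      data.frame(region = g, bsa = contrib)
    })
    rest <- !(X$atoms$resid %in% allres)
    rows[[length(rows) + 1]] <- data.frame(
      region = "rest",
      bsa = if (method == "atomic") sum(per_atom[rest]) else {
        if (all(rest)) sum(per_atom)
        else if (!any(rest)) 0
        else sum(per_atom) - sum(half(subset_atoms(X, !rest), Y))
      })
    do.call(rbind, rows)
  }
  out$regions_a <- decomp(A, B, ba)
  out$regions_b <- decomp(B, A, bb)
  out
}

# ---- groove width -------------------------------------------------------

#' Groove-width profile of a helical filament
#'
#' For each azimuthal station (every `angular_step` degrees over one full
#' turn) and each radial shell (every `radial_step` Angstrom between
#' (r + R)/2 and R, where r and R are the filament's inner and outer radii),
#' the protein occupancy along the axial direction is computed on the
#' vertical reference line; the protein-free axial gaps between successive
#' turns give the groove width.  Per angle, the mean, minimum and maximum
#' over the radial shells are reported.
#'
#' @param filament multi-chain Structure (at least one full helical turn;
#'   measurements are restricted to the central pitch-high window to avoid
#'   end effects).
#' @param axis Screw describing the filament's generating interface (its
#'   axis is the filament axis).
#' @param angular_step degrees (default 0.5).
#' @param radial_step Angstrom (default 1).
#' @param atom_radius effective atom radius used for occupancy (default
#'   2.0 Angstrom).
#' @return data.frame of class `GrooveProfile` with `angle`, `width_mean`,
#'   `width_min`, `width_max`.
#' @export
groove_width <- function(filament, axis, angular_step = 0.5,
                         radial_step = 1, atom_radius = 2.0) {
  xyz <- coords(filament)
  u <- axis$axis
  rel <- xyz - rep(axis$O, each = nrow(xyz))
  z <- as.numeric(rel %*% u)
  a <- c(0, 0, 1); if (abs(sum(a * u)) > 0.9) a <- c(1, 0, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross(u, e1)
  px <- as.numeric(rel %*% e1); py <- as.numeric(rel %*% e2)
  rad <- sqrt(px^2 + py^2)
  phi <- atan2(py, px)
  r_in <- min(rad); r_out <- max(rad)
  hp <- helix_params(axis, NULL)
  pitchw <- if (is.finite(hp$P) && hp$P > 0) hp$P else diff(range(z))
  zc <- mean(range(z))
  zlo <- max(min(z), zc - pitchw / 2); zhi <- min(max(z), zc + pitchw / 2)
  shells <- seq((r_in + r_out) / 2, r_out, by = radial_step)
  angles <- seq(0, 360 - angular_step, by = angular_step)
  wmat <- matrix(NA_real_, length(angles), length(shells))
  for (k in seq_along(shells)) {
    rho <- shells[k]
    # perpendicular distance from atom i to the vertical line at (rho, ang):
    # d^2 = rad^2 + rho^2 - 2 rad rho cos(phi - ang)
    for (jj in seq_along(angles)) {
      ang <- angles[jj] * pi / 180
      d2 <- rad^2 + rho^2 - 2 * rad * rho * cos(phi - ang)
      hit <- which(d2 < atom_radius^2)
      if (!length(hit)) { wmat[jj, k] <- NA; next }
      h <- sqrt(atom_radius^2 - d2[hit])
      iv <- cbind(z[hit] - h, z[hit] + h)
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      # merge intervals, collect interior gaps inside the central window
      gaps <- numeric(); cur <- iv[1, ]
      if (nrow(iv) > 1) for (q in 2:nrow(iv)) {
        if (iv[q, 1] <= cur[2]) cur[2] <- max(cur[2], iv[q, 2])
        else {
          if (cur[2] >= zlo && iv[q, 1] <= zhi)
            gaps <- c(gaps, iv[q, 1] - cur[2])
          cur <- iv[q, ]
        }
      }
      wmat[jj, k] <- if (length(gaps)) mean(gaps) else 0
    }
  }
  out <- data.frame(angle = angles,
                    width_mean = rowMeans(wmat, na.rm = TRUE),
                    width_min = suppressWarnings(apply(wmat, 1, min, na.rm = TRUE)),
                    width_max = suppressWarnings(apply(wmat, 1, max, na.rm = TRUE)))
  out$width_min[!is.finite(out$width_min)] <- NA
  out$width_max[!is.finite(out$width_max)] <- NA
  out$width_mean[is.nan(out$width_mean)] <- NA
  class(out) <- c("GrooveProfile", "data.frame")
  attr(out, "r_int") <- r_in; attr(out, "r_ext") <- r_out
  out
}
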