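# Screw decomposition of rigid-body transforms and helical parameters.
#
# Conventions: rotation angle theta in degrees, theta in (0, 180]; the axis
# direction is chosen so theta is positive, handedness is carried by the sign
# of the axial translation `trans` relative to the axis.  The axis point O is
# the perpendicular foot of the origin on the screw axis (unique, so outputs
# are deterministic).

.DEG <- pi / 180

#' Rigid-body transform
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t translation 3-vector (Angstrom).
#' @return object of class `RigidTransform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- unname(as.matrix(R)); t <- unname(as.numeric(t))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R is not a proper rotation matrix")
  structure(list(R = R, t = t), class = "RigidTransform")
}

#' Apply a rigid transform to coordinates or a structure-like object
#' @param x Structure, ReducedStructure or n x 3 matrix.
#' @param tr RigidTransform.
#' @return same type as `x`, transformed.
#' @export
apply_transform <- function(x, tr) {
  if (is.matrix(x)) return(x %*% t(tr$R) + rep(tr$t, each = nrow(x)))
  set_coords(x, apply_transform(coords(x), tr))
}

#' Compose transforms: returns the transform "first a, then b"
#' @param a,b RigidTransform.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

#' Inverse of a rigid transform
#' @param tr RigidTransform.
#' @export
invert_transform <- function(tr)
  rigid_transform(t(tr$R), -as.numeric(t(tr$R) %*% tr$t))

#' Repeated composition of a transform with itself
#' @param tr RigidTransform.
#' @param k non-negative integer power.
#' @export
transform_power <- function(tr, k) {
  out <- rigid_transform()
  for (i in seq_len(k)) out <- compose_transforms(out, tr)
  out
}

.rotmat <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2)); a <- theta_deg * .DEG
  c1 <- cos(a); s1 <- sin(a)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c1 * diag(3) + s1 * ux + (1 - c1) * tcrossprod(u)
}

.cross <- function(a, b) c(a[2]*b[3] - a[3]*b[2],
                           a[3]*b[1] - a[1]*b[3],
                           a[1]*b[2] - a[2]*b[1])

# ---- superposition ------------------------------------------------------

.pair_selection <- function(mobile, target, selection) {
  am <- if (inherits(mobile, "Structure")) mobile$atoms else mobile$beads
  at <- if (inherits(target, "Structure")) target$atoms else target$beads
  if (inherits(mobile, "ReducedStructure") && identical(selection, "CA"))
    selection <- "BB"
  if (!is.null(selection)) {
    am <- am[am$atom %in% selection, , drop = FALSE]
    at <- at[at$atom %in% selection, , drop = FALSE]
  }
  km <- paste(am$resid, am$ins, am$atom)
  kt <- paste(at$resid, at$ins, at$atom)
  common <- intersect(km, kt)
  list(m = am[match(common, km), c("x", "y", "z")],
       t = at[match(common, kt), c("x", "y", "z")])
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the rigid transform minimizing the RMSD of `mobile` onto `target`
#' over paired atoms (matched by residue number, insertion code and atom
#' name; Calpha by default).
#'
#' @param mobile,target Structures of the same monomer.
#' @param selection atom-name selection, default `"CA"`; NULL for all atoms.
#' @return list with `transform` (RigidTransform) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target, selection = "CA") {
  p <- .pair_selection(mobile, target, selection)
  X <- as.matrix(p$m); Y <- as.matrix(p$t)
  if (nrow(X) < 3) stop("underdetermined: fewer than 3 paired atoms")
  kabsch(X, Y)
}

#' Kabsch superposition of paired coordinate sets
#' @param X,Y n x 3 matrices of paired coordinates; the transform maps X
#'   onto Y.
#' @return list with `transform` and `rmsd`.
#' @export
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(X - rep(cx, each = nrow(X)), Y - rep(cy, each = nrow(Y)))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  tr <- rigid_transform(R, t)
  dif <- apply_transform(X, tr) - Y
  list(transform = tr, rmsd = sqrt(mean(rowSums(dif^2))))
}

# ---- screw decomposition ------------------------------------------------

#' Screw object constructor
#' @param O axis point (3-vector, Angstrom).
#' @param axis unit axis direction.
#' @param theta rotation angle, degrees, in (0, 180] (0 for pure
#'   translation).
#' @param trans signed axial translation, Angstrom.
#' @param flag degenerate-case flag: "", "pure_translation" or "identity".
#' @export
screw <- function(O, axis, theta, trans, flag = "") {
  n <- sqrt(sum(axis^2))
  if (n > 0) axis <- axis / n
  structure(list(O = as.numeric(O), axis = as.numeric(axis),
                 theta = as.numeric(theta), trans = as.numeric(trans),
                 flag = flag), class = "Screw")
}

#' @export
print.Screw <- function(x, ...) {
  cat(sprintf(paste0("<Screw theta=%.3f deg trans=%.3f A axis=(%.4f %.4f ",
                     "%.4f) O=(%.2f %.2f %.2f)%s>\n"),
              x$theta, x$trans, x$axis[1], x$axis[2], x$axis[3],
              x$O[1], x$O[2], x$O[3],
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Extract the screw parameters of a rigid transform
#'
#' Analytic decomposition of a rigid-body transform into a rotation `theta`
#' about an axis (point `O`, direction `axis`) plus a translation `trans`
#' along the axis.  `theta` is reported in (0, 180]; rotations below 0.1
#' degrees are flagged `"pure_translation"` (the axis is then the direction
#' of the translation) and the identity is flagged `"identity"`.
#'
#' @param tr RigidTransform.
#' @return a [screw()].
#' @export
screw_from_transform <- function(tr) {
  R <- tr$R; t <- tr$t
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(ct) / .DEG
  if (theta < 0.1) {                        # (near-)pure translation
    nt <- sqrt(sum(t^2))
    if (nt < 1e-9)
      return(screw(c(0, 0, 0), c(0, 0, 1), 0, 0, flag = "identity"))
    return(screw(c(0, 0, 0), t / nt, 0, nt, flag = "pure_translation"))
  }
  if (theta > 179.999) {                    # axis from R + I columns
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    u <- M[, j] / sqrt(sum(M[, j]^2))
  } else {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    u <- v / sqrt(sum(v^2))
  }
  # deterministic axis sign for theta == 180 (v vanishes there)
  if (theta > 179.999) {
    s <- sum(u * t)
    if (abs(s) > 1e-9) { if (s < 0) u <- -u }
    else {
      nz <- which(abs(u) > 1e-9)[1]
      if (u[nz] < 0) u <- -u
    }
  }
  trans <- sum(t * u)
  tp <- t - trans * u                       # in-plane part
  half <- theta / 2 * .DEG
  O <- 0.5 * (tp + .cross(u, tp) / tan(half))
  # O above solves (I - R) O = tp but may have an axial component; remove it
  O <- O - sum(O * u) * u
  screw(O, u, theta, trans)
}

#' Rebuild the rigid transform of a screw
#' @param s Screw.
#' @return RigidTransform; exact inverse of [screw_from_transform()].
#' @export
transform_from_screw <- function(s) {
  if (s$theta == 0)
    return(rigid_transform(diag(3), s$axis * s$trans))
  R <- .rotmat(s$axis, s$theta)
  t <- s$O - as.numeric(R %*% s$O) + s$trans * s$axis
  rigid_transform(R, t)
}

#' Screw transformation relating two copies of a monomer
#'
#' Superposes `A` onto `B` (Calpha by default) and decomposes the resulting
#' transform.  Warns if the superposition RMSD exceeds 3 Angstrom, which
#' suggests the two structures are not copies of the same monomer.
#'
#' @param A,B Structures (same monomer, e.g. consecutive filament subunits).
#' @param selection atom selection for the superposition.
#' @return a [screw()] with attribute `"rmsd"`.
#' @export
screw_between_monomers <- function(A, B, selection = "CA") {
  sp <- superpose(A, B, selection)
  if (sp$rmsd > 3)
    warning(sprintf("superposition rmsd %.2f A > 3 A: A and B may not be copies of the same monomer", sp$rmsd))
  s <- screw_from_transform(sp$transform)
  attr(s, "rmsd") <- sp$rmsd
  s
}

# ---- helical parameters -------------------------------------------------

#' Global helical parameters of a screw
#'
#' N = 360/theta monomers per turn, pitch P = N * |trans|, handedness
#' dir = "R" if theta * trans > 0 else "L"; the inner and outer radii are
#' the minimal and maximal distances of the monomer's atoms (or beads) from
#' the axis line.
#'
#' @param s Screw.
#' @param monomer optional Structure/ReducedStructure for the radii.
#' @return list of class `HelixParams` with `N`, `P`, `dir`, `r_int`,
#'   `r_ext`.
#' @export
helix_params <- function(s, monomer = NULL) {
  if (s$theta < 0.1) {
    N <- Inf; P <- Inf
  } else {
    N <- 360 / s$theta
    P <- N * abs(s$trans)
  }
  dir <- if (s$theta * s$trans > 0) "R" else if (s$theta * s$trans < 0) "L"
         else "0"
  r_int <- r_ext <- NA_real_
  if (!is.null(monomer)) {
    xyz <- coords(monomer)
    rel <- xyz - rep(s$O, each = nrow(xyz))
    ax <- rel %*% s$axis
    rad <- sqrt(pmax(rowSums(rel^2) - as.numeric(ax)^2, 0))
    r_int <- min(rad); r_ext <- max(rad)
  }
  structure(list(N = N, P = P, dir = dir, r_int = r_int, r_ext = r_ext,
                 theta = s$theta, trans = s$trans),
            class = "HelixParams")
}

#' @export
print.HelixParams <- function(x, ...) {
  cat(sprintf("<HelixParams N=%.3f P=%.2f A dir=%s radius %.1f : %.1f A>\n",
              x$N, x$P, x$dir,
              if (is.na(x$r_int)) NA else x$r_int,
              if (is.na(x$r_ext)) NA else x$r_ext))
  invisible(x)
}

#' Angular deviation between two binding geometries
#'
#' The rotation angle (degrees) of `a` composed with the inverse of `b`:
#' a frame-independent measure of how far apart two monomer placements are
#' in orientation.
#' @param a,b RigidTransforms (or Screws, converted internally).
#' @export
angular_deviation <- function(a, b) {
  if (inherits(a, "Screw")) a <- transform_from_screw(a)
  if (inherits(b, "Screw")) b <- transform_from_screw(b)
  d <- compose_transforms(invert_transform(b), a)
  ct <- max(-1, min(1, (sum(diag(d$R)) - 1) / 2))
  acos(ct) / .DEG
}

#' Maximum radius of a monomer about its centroid
#'
#' R_M used by the geometric classification (maximum distance of any atom or
#' bead from the monomer centroid).
#' @param monomer Structure or ReducedStructure.
#' @export
monomer_radius <- function(monomer) {
  xyz <- coords(monomer)
  ctr <- colMeans(xyz)
  sqrt(max(rowSums((xyz - rep(ctr, each = nrow(xyz)))^2)))
}
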