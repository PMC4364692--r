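# Construction of regular, mixed-mode, curved-axis and supercoiled
# oligomer models from screw transforms.

#' Deterministic chain-id sequence A, B, ..., Z, AA, AB, ...
#' @param n number of ids.
#' @export
chain_ids <- function(n) {
  one <- LETTERS
  if (n <= 26) return(one[seq_len(n)])
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(one, two)[seq_len(n)]
}

.stack_chains <- function(copies, label) {
  ids <- chain_ids(length(copies))
  for (i in seq_along(copies)) copies[[i]]$atoms$chain <- ids[i]
  structure(list(atoms = do.call(rbind, lapply(copies, `[[`, "atoms")),
                 label = label), class = "Structure")
}

#' Build a regular filament (or ring) by repeating a screw transform
#'
#' Chain i carries the (i-1)-fold composition of the generating transform,
#' so the composite transform of the whole construct equals T^n.
#'
#' @param monomer Structure (chain ids are reassigned A, B, ...).
#' @param s Screw (or RigidTransform).
#' @param n number of monomers (>= 2).
#' @param max_atoms memory guard, error above this total atom count.
#' @return multi-chain Structure.
#' @export
build_filament <- function(monomer, s, n, max_atoms = 5e6) {
  stopifnot(n >= 2)
  if (n * nrow(monomer$atoms) > max_atoms)
    stop("size error: requested filament exceeds the atom budget")
  tr <- if (inherits(s, "Screw")) transform_from_screw(s) else s
  copies <- vector("list", n)
  cur <- monomer
  copies[[1]] <- monomer
  for (i in 2:n) {
    cur <- apply_transform(cur, tr)
    copies[[i]] <- cur
  }
  .stack_chains(copies, sprintf("%s_fil%d", monomer$label, n))
}

#' Filament specification for mixed-mode constructions
#'
#' @param interfaces named list of Screws (or RigidTransforms), the interface
#'   vocabulary.
#' @param sequence character vector of interface labels; interface j places
#'   monomer j+1 relative to monomer j.  Recycled to `n - 1` if a repeat
#'   block shorter than the construct is given.
#' @param n total monomer count (>= 2).
#' @return object of class `FilamentSpec`.
#' @export
filament_spec <- function(interfaces, sequence, n) {
  stopifnot(n >= 2)
  if (!all(sequence %in% names(interfaces)))
    stop("unknown interface label in sequence")
  structure(list(interfaces = interfaces, sequence = sequence, n = as.integer(n)),
            class = "FilamentSpec")
}

#' Build a mixed-mode filament and analyze its repeat block
#'
#' Monomer i+1 is placed by the i-th interface transform of the (recycled)
#' sequence.  The composite transform of one full repeat block is decomposed
#' into its screw, giving the super-helix parameters of the construct.
#'
#' @param monomer Structure.
#' @param spec FilamentSpec.
#' @param warn_clash_dist flag interfaces whose consecutive monomers overlap
#'   (centroid distance below this, Angstrom); the structure is still built.
#' @return list with `structure`, `block_screw` (screw of the repeat-block
#'   composite) and `block_params` ([helix_params()] of the repeat block,
#'   radii measured on the monomer).
#' @export
build_mixed_filament <- function(monomer, spec, warn_clash_dist = 2) {
  labs <- rep(spec$sequence, length.out = spec$n - 1)
  trs <- lapply(spec$interfaces, function(s)
    if (inherits(s, "Screw")) transform_from_screw(s) else s)
  copies <- vector("list", spec$n)
  copies[[1]] <- monomer
  cur_tr <- rigid_transform()
  prev_ctr <- centroid(monomer)
  for (i in 2:spec$n) {
    cur_tr <- compose_transforms(trs[[labs[i - 1]]], cur_tr)   # local step first
    copies[[i]] <- apply_transform(monomer, cur_tr)
    ctr <- centroid(copies[[i]])
    if (sqrt(sum((ctr - prev_ctr)^2)) < warn_clash_dist)
      warning(sprintf("consecutive monomers %d/%d nearly coincide", i - 1, i))
    prev_ctr <- ctr
  }
  # composite over one repeat block maps monomer 1 to monomer b+1
  block <- rigid_transform()
  for (lab in rev(spec$sequence)) block <- compose_transforms(block, trs[[lab]])
  bs <- screw_from_transform(block)
  list(structure = .stack_chains(copies, sprintf("%s_mix%d", monomer$label,
                                                 spec$n)),
       block_screw = bs,
       block_params = helix_params(bs, monomer))
}

# ---- curved-axis construction ------------------------------------------

# Rotation-minimizing frames along a sampled curve (double-reflection
# method).  pts: m x 3 curve points; returns list of 3x3 frames with columns
# (n1, n2, t): two normals and the tangent.
.rmf_frames <- function(pts) {
  m <- nrow(pts)
  tang <- matrix(0, m, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  if (m > 2) for (i in 2:(m - 1)) tang[i, ] <- pts[i + 1, ] - pts[i - 1, ]
  tang[m, ] <- pts[m, ] - pts[m - 1, ]
  tang <- tang / sqrt(rowSums(tang^2))
  frames <- vector("list", m)
  t1 <- tang[1, ]
  a <- c(0, 0, 1); if (abs(sum(a * t1)) > 0.9) a <- c(1, 0, 0)
  n1 <- a - sum(a * t1) * t1; n1 <- n1 / sqrt(sum(n1^2))
  frames[[1]] <- cbind(n1, .cross(t1, n1), t1)
  for (i in seq_len(m - 1)) {
    f <- frames[[i]]
    v1 <- pts[i + 1, ] - pts[i, ]; c1 <- sum(v1 * v1)
    rL <- f[, 1] - (2 / c1) * sum(v1 * f[, 1]) * v1
    tL <- f[, 3] - (2 / c1) * sum(v1 * f[, 3]) * v1
    v2 <- tang[i + 1, ] - tL; c2 <- sum(v2 * v2)
    n1 <- if (c2 > 1e-12) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
    n1 <- n1 - sum(n1 * tang[i + 1, ]) * tang[i + 1, ]
    n1 <- n1 / sqrt(sum(n1^2))
    frames[[i + 1]] <- cbind(n1, .cross(tang[i + 1, ], n1), tang[i + 1, ])
  }
  frames
}

#' Guide curve constructors
#'
#' `curve_line()` is a straight line from `origin` along `dirv`;
#' `curve_circle()` a circle of given radius in the plane spanned by
#' `u`, `v`; `curve_helix()` a helix of given radius and pitch about `axis`.
#' Each returns a function of arc length s giving a 3-vector.
#' @param origin,dirv line origin and direction.
#' @export
curve_line <- function(origin = c(0, 0, 0), dirv = c(0, 0, 1)) {
  dirv <- dirv / sqrt(sum(dirv^2))
  function(s) s %o% dirv + rep(origin, each = length(s))
}

#' @rdname curve_line
#' @param radius circle/helix radius (Angstrom).
#' @param center circle center.
#' @param u,v orthonormal in-plane basis of the circle.
#' @export
curve_circle <- function(radius, center = c(0, 0, 0),
                         u = c(1, 0, 0), v = c(0, 1, 0)) {
  function(s) {
    a <- s / radius
    outer(cos(a) - 1, u) * radius + outer(sin(a), v) * radius +
      rep(center, each = length(a))
  }
}

#' @rdname curve_line
#' @param pitch helix pitch (Angstrom per turn); `Inf` gives a straight
#'   line.
#' @param axis helix axis direction.
#' @param phase angular phase offset (radians).
#' @export
curve_helix <- function(radius, pitch, center = c(0, 0, 0),
                        axis = c(0, 0, 1), phase = 0) {
  if (!is.finite(pitch)) return(curve_line(center + radius * c(cos(phase),
                                                               sin(phase), 0),
                                           axis))
  axis <- axis / sqrt(sum(axis^2))
  a <- c(0, 0, 1); if (abs(sum(a * axis)) > 0.9) a <- c(1, 0, 0)
  u <- a - sum(a * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- .cross(axis, u)
  b <- pitch / (2 * pi)
  k <- sqrt(radius^2 + b^2)          # arc length per unit angle
  function(s) {
    ang <- s / k + phase
    outer(cos(ang), u) * radius + outer(sin(ang), v) * radius +
      outer(ang - phase, axis) * b + rep(center, each = length(ang))
  }
}

#' Build a filament along a curved guide axis
#'
#' The monomer is first expressed in the frame of its own screw axis
#' (origin O, z along the axis).  Monomer i is then placed at arc length
#' i * |trans| along the guide curve using a rotation-minimizing frame, with
#' the per-step twist theta re-applied about the local tangent.  For a
#' straight guide curve starting at O along the screw axis the construction
#' reduces exactly to [build_filament()].
#'
#' @param monomer Structure.
#' @param s Screw (the local interface geometry).
#' @param curve function of arc length returning curve points (see
#'   [curve_line()] and friends), or NULL for the straight limit.
#' @param n monomer count.
#' @return multi-chain Structure.  A self-intersection warning is emitted if
#'   the curvature radius is smaller than the monomer's outer radius.
#' @export
build_on_curve <- function(monomer, s, curve = NULL, n = 2) {
  stopifnot(n >= 2)
  rise <- abs(s$trans)
  if (rise < 1e-6) stop("curved-axis construction requires a nonzero rise")
  if (is.null(curve)) curve <- curve_line(s$O, s$axis * sign(s$trans))
  sgn <- sign(s$trans)
  step_theta <- s$theta * sgn            # twist about the +tangent direction
  svals <- (seq_len(n) - 1) * rise
  pts <- curve(svals)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3, byrow = FALSE)
  # curvature check at mid-curve
  if (n >= 3) {
    v1 <- pts[2, ] - pts[1, ]; v2 <- pts[3, ] - pts[2, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(max(-1, min(1, cosang)))
    if (ang > 1e-6) {
      rcurv <- rise / ang
      hp <- helix_params(s, monomer)
      if (is.finite(hp$r_ext) && rcurv < hp$r_ext)
        warning("self-intersection: curvature radius smaller than monomer outer radius")
    }
  }
  frames <- .rmf_frames(pts)
  # monomer in the screw-axis frame: z along axis*sgn
  zax <- s$axis * sgn
  a <- c(0, 0, 1); if (abs(sum(a * zax)) > 0.9) a <- c(1, 0, 0)
  u <- a - sum(a * zax) * zax; u <- u / sqrt(sum(u^2))
  B0 <- cbind(u, .cross(zax, u), zax)
  local <- (coords(monomer) - rep(s$O, each = nrow(monomer$atoms))) %*% B0
  copies <- vector("list", n)
  for (i in seq_len(n)) {
    tw <- .rotmat(c(0, 0, 1), step_theta * (i - 1))
    M <- frames[[i]] %*% tw
    xyz <- local %*% t(M) + rep(pts[i, ], each = nrow(local))
    copies[[i]] <- set_coords(monomer, xyz)
  }
  .stack_chains(copies, sprintf("%s_curve%d", monomer$label, n))
}

#' Build a two-strand supercoiled filament
#'
#' Two copies of the filament are built along two parallel helical guide
#' curves of the given supercoil pitch, with strand axes separated by
#' `separation` (the guide helix radius is separation / 2 and the strands
#' are offset by 180 degrees).  An infinite pitch gives two straight
#' parallel filaments.
#'
#' @param monomer Structure.
#' @param s Screw (local interface).
#' @param supercoil_pitch supercoil pitch, Angstrom (e.g. 1600 for a 160 nm
#'   supercoil).
#' @param separation distance between the two strand axes, Angstrom.
#' @param n monomers per strand.
#' @return list with `structure` (2n chains; strand 2 chains follow strand
#'   1's) and `guides` (the two curve functions).
#' @export
build_supercoiled_pair <- function(monomer, s, supercoil_pitch, separation,
                                   n) {
  if (separation <= 0)
    stop("strand separation must be positive")
  hp <- helix_params(s, monomer)
  if (is.finite(hp$r_ext) && separation < 2 * hp$r_ext)
    warning("inter-strand clash: separation below twice the monomer outer radius")
  radius <- separation / 2
  g1 <- curve_helix(radius, supercoil_pitch, phase = 0)
  g2 <- curve_helix(radius, supercoil_pitch, phase = pi)
  f1 <- build_on_curve(monomer, s, g1, n)
  f2 <- build_on_curve(monomer, s, g2, n)
  ids <- chain_ids(2 * n)
  f2$atoms$chain <- ids[match(f2$atoms$chain, chain_ids(n)) + n]
  out <- structure(list(atoms = rbind(f1$atoms, f2$atoms),
                        label = sprintf("%s_sc2x%d", monomer$label, n)),
                   class = "Structure")
  list(structure = out, guides = list(g1, g2))
}
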