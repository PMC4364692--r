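# Multi-start rigid-body self-docking: start-grid generation, local energy
# minimization over the six rigid-body degrees of freedom, pose filtering
# and deduplication.

.orientation_set <- function(n) {
  # deterministic quasi-uniform rotations: golden-angle spin about the six
  # octahedral axes, cycled
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                c(0, 1, 1) / sqrt(2))
  lapply(seq_len(n), function(i) {
    ax <- axes[((i - 1) %% 6) + 1, ]
    .rotmat(ax, (i - 1) * 137.50776405)
  })
}

#' Generate docking start points and orientations
#'
#' Global mode: ligand centers on a quasi-spherical (Fibonacci) shell around
#' the receptor at a constant surface-to-surface distance, with about
#' `spacing` Angstrom between neighboring points (10 by default).  Targeted
#' mode: a dense cubic grid (2 Angstrom spacing) of centers no farther than
#' `max_dist` (20) from the reference ligand's center of mass.
#'
#' @param receptor,ligand ReducedStructures.
#' @param mode `"global"` or `"targeted"`.
#' @param spacing grid spacing, Angstrom (default 10 global / 2 targeted).
#' @param surf_dist surface-to-surface start distance for global mode.
#' @param ref_pose RigidTransform of the reference pose (targeted mode).
#' @param max_dist targeted-mode radius around the reference ligand COM.
#' @param n_orient orientations per start position (default 6 global, 1 =
#'   the reference orientation in targeted mode).
#' @return object of class `StartGrid`: list with `positions` (m x 3),
#'   `orientations` (list of rotation matrices), `mode`, `spacing`.
#' @export
generate_starts <- function(receptor, ligand,
                            mode = c("global", "targeted"),
                            spacing = NULL, surf_dist = 5,
                            ref_pose = NULL, max_dist = 20,
                            n_orient = NULL) {
  mode <- match.arg(mode)
  ctr <- centroid(receptor)
  if (mode == "global") {
    spacing <- spacing %||% 10
    n_orient <- n_orient %||% 6
    rr <- monomer_radius(receptor); rl <- monomer_radius(ligand)
    R <- rr + rl + surf_dist
    m <- max(12L, round(4 * pi * R^2 / spacing^2))
    pos <- .fib_sphere(m) * R + rep(ctr, each = m)
    ors <- .orientation_set(n_orient)
  } else {
    stopifnot(!is.null(ref_pose))
    spacing <- spacing %||% 2
    n_orient <- n_orient %||% 1
    com <- colMeans(apply_transform(coords(ligand), ref_pose))
    g <- seq(-max_dist, max_dist, by = spacing)
    pos <- as.matrix(expand.grid(x = g, y = g, z = g))
    pos <- pos[sqrt(rowSums(pos^2)) <= max_dist, , drop = FALSE]
    pos <- pos + rep(com, each = nrow(pos))
    ors <- c(list(ref_pose$R),
             if (n_orient > 1) .orientation_set(n_orient - 1) else NULL)
    if (n_orient > 1)
      ors[-1] <- lapply(ors[-1], function(Q) Q %*% ref_pose$R)
  }
  structure(list(positions = pos, orientations = ors, mode = mode,
                 spacing = spacing), class = "StartGrid")
}

# skew-symmetric cross-product matrix
.skew <- function(w) matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0),
                            3, 3)

# left Jacobian of SO(3) at rotation vector w (radians)
.so3_left_jacobian <- function(w) {
  th <- sqrt(sum(w^2))
  W <- .skew(w)
  if (th < 1e-8) return(diag(3) + W / 2)
  diag(3) + (1 - cos(th)) / th^2 * W + (th - sin(th)) / th^3 * (W %*% W)
}

.rotvec_mat <- function(w) {          # exp([w]x), w in radians
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  .rotmat(w / th, th / .DEG)
}

#' Minimize one docking pose
#'
#' Local minimization (BFGS with analytic force/torque gradients) over the
#' six rigid-body degrees of freedom of the ligand — three translations of
#' its center and a rotation vector applied about the center — starting
#' from a given center position and orientation.
#'
#' @param receptor,ligand ReducedStructures.
#' @param start list with `position` (target ligand COM) and `orientation`
#'   (rotation matrix), or a RigidTransform.
#' @param ff ForceFieldParams.
#' @param maxit iteration budget.
#' @return a pose: list with `transform`, `energy` (RT), `converged`,
#'   `capped`, `start_id`.
#' @export
minimize_pose <- function(receptor, ligand, start, ff, maxit = 150) {
  lig_xyz <- coords(ligand)
  com <- colMeans(lig_xyz)
  if (inherits(start, "RigidTransform")) {
    R0 <- start$R
    p0 <- as.numeric(start$R %*% com) + start$t
  } else {
    R0 <- start$orientation
    p0 <- start$position
  }
  base <- lig_xyz %*% t(R0)
  base_com <- as.numeric(R0 %*% com)
  base_rel <- base - rep(base_com, each = nrow(base))
  pt <- .pair_tables(receptor, ligand, ff)
  xr <- coords(receptor)
  cut2 <- ff$cutoff^2

  eval_state <- function(x) {
    Rd <- .rotvec_mat(x[4:6])
    ctr <- p0 + x[1:3]
    rel <- base_rel %*% t(Rd)
    xl <- rel + rep(ctr, each = nrow(rel))
    nb <- .neighbor_pairs(xr, xl, ff$cutoff)
    if (!nrow(nb))
      return(list(e = 0, g = rep(0, 6)))
    dvec <- xl[nb[, 2], , drop = FALSE] - xr[nb[, 1], , drop = FALSE]
    r2 <- rowSums(dvec^2)
    clamped <- r2 < 1
    r2c <- pmax(r2, 1)
    idx <- cbind(nb[, 1], nb[, 2])
    A <- pt$A[idx]; B <- pt$B[idx]; QQ <- pt$QQ[idx]
    e <- sum(A / r2c^4 - B / r2c^3 + QQ / (ff$eps0 * r2c))
    dEdr2 <- -4 * A / r2c^5 + 3 * B / r2c^4 - QQ / (ff$eps0 * r2c^2)
    dEdr2[clamped] <- 0               # flat inside the soft cap
    fj <- dvec * (2 * dEdr2)          # dE/d(ligand bead position), rowwise
    force <- colSums(fj)
    lever <- rel[nb[, 2], , drop = FALSE]
    torque <- colSums(cbind(lever[, 2] * fj[, 3] - lever[, 3] * fj[, 2],
                            lever[, 3] * fj[, 1] - lever[, 1] * fj[, 3],
                            lever[, 1] * fj[, 2] - lever[, 2] * fj[, 1]))
    gw <- as.numeric(t(.so3_left_jacobian(x[4:6])) %*% torque)
    list(e = e, g = c(force, gw))
  }
  cache <- new.env(parent = emptyenv())
  efun <- function(x) {
    st <- eval_state(x)
    assign("g", st$g, envir = cache); assign("x", x, envir = cache)
    st$e
  }
  gfun <- function(x) {
    if (exists("x", cache) && all(x == get("x", cache)))
      return(get("g", cache))
    eval_state(x)$g
  }
  e0 <- efun(rep(0, 6))
  opt <- stats::optim(rep(0, 6), efun, gfun, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  x <- opt$par
  Rd <- .rotvec_mat(x[4:6])
  R <- Rd %*% R0
  t <- p0 + x[1:3] - as.numeric(Rd %*% base_com)
  tr <- rigid_transform(R, t)
  e <- interaction_energy(receptor, ligand, ff, pose = tr)
  if (as.numeric(e) > e0 + 1e-9) {    # descent guarantee: revert if worse
    tr <- rigid_transform(R0, p0 - base_com)
    e <- interaction_energy(receptor, ligand, ff, pose = tr)
    opt$convergence <- 1L
  }
  list(transform = tr, energy = as.numeric(e),
       converged = opt$convergence == 0, capped = isTRUE(attr(e, "capped")),
       start_id = NA_integer_)
}

#' Multi-start rigid-body docking
#'
#' Minimizes one pose per (position, orientation) start, sorts by energy
#' (ties broken by start id) and attaches per-pose screw and helical
#' parameters.  Results from several runs (e.g. self-docking of two crystal
#' forms) can be merged with [merge_dock_results()].
#'
#' @param receptor,ligand ReducedStructures.
#' @param grid StartGrid from [generate_starts()].
#' @param ff ForceFieldParams.
#' @param maxit per-pose minimizer budget.
#' @param verbose print progress.
#' @return object of class `DockResult`: list with `poses` (list) and
#'   `table` (data.frame: start_id, energy, theta, trans, N, P, dir,
#'   converged).
#' @export
dock <- function(receptor, ligand, grid, ff, maxit = 150, verbose = FALSE) {
  n_pos <- nrow(grid$positions)
  n_or <- length(grid$orientations)
  poses <- vector("list", n_pos * n_or)
  k <- 0
  for (i in seq_len(n_pos)) {
    for (j in seq_len(n_or)) {
      k <- k + 1
      p <- minimize_pose(receptor, ligand,
                         list(position = grid$positions[i, ],
                              orientation = grid$orientations[[j]]),
                         ff, maxit = maxit)
      p$start_id <- k
      poses[[k]] <- p
      if (verbose && k %% 25 == 0)
        message(sprintf("  minimized %d / %d starts", k, n_pos * n_or))
    }
  }
  .dock_result(poses, receptor, ligand)
}

.dock_result <- function(poses, receptor, ligand) {
  if (!length(poses)) {
    tab <- data.frame(start_id = integer(), energy = numeric(),
                      theta = numeric(), trans = numeric(), N = numeric(),
                      P = numeric(), dir = character(),
                      converged = logical(), capped = logical())
    return(structure(list(poses = list(), table = tab, receptor = receptor,
                          ligand = ligand), class = "DockResult"))
  }
  rows <- lapply(poses, function(p) {
    s <- screw_from_transform(p$transform)
    hp <- helix_params(s, ligand)
    data.frame(start_id = p$start_id, energy = p$energy, theta = s$theta,
               trans = s$trans, N = hp$N, P = hp$P, dir = hp$dir,
               converged = p$converged, capped = p$capped)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$energy, tab$start_id)
  structure(list(poses = poses[ord], table = tab[ord, , drop = FALSE],
                 receptor = receptor, ligand = ligand),
            class = "DockResult")
}

#' Merge docking results from several runs
#' @param ... DockResult objects sharing the same ligand numbering.
#' @export
merge_dock_results <- function(...) {
  rs <- list(...)
  poses <- do.call(c, lapply(rs, `[[`, "poses"))
  for (i in seq_along(poses)) poses[[i]]$start_id <- i
  .dock_result(poses, rs[[1]]$receptor, rs[[1]]$ligand)
}

#' Filter and deduplicate docking poses
#'
#' Retains poses within `e_window` (20 RT) of the reference energy, removes
#' poses whose interface with the preceding or following monomer of the
#' implied filament contains a listed boundary residue, and deduplicates by
#' greedy ligand-RMSD clustering (best-energy representative kept).
#'
#' @param result DockResult.
#' @param e_ref reference energy (RT); default: best energy in the run.
#' @param e_window retention window above `e_ref`, RT.
#' @param boundary_residues integer residue numbers bordering pruned
#'   flexible regions.
#' @param contact_cutoff bead-contact cutoff for the boundary filter.
#' @param dedup_rmsd ligand-RMSD threshold for deduplication, Angstrom.
#' @return filtered DockResult (attribute `empty` flags an empty result).
#' @export
filter_poses <- function(result, e_ref = NULL, e_window = 20,
                         boundary_residues = NULL, contact_cutoff = 7,
                         dedup_rmsd = 1.0) {
  poses <- result$poses
  if (!length(poses)) return(result)
  e <- vapply(poses, `[[`, numeric(1), "energy")
  e_ref <- e_ref %||% min(e)
  keep <- e <= e_ref + e_window
  poses <- poses[keep]
  if (!is.null(boundary_residues) && length(poses)) {
    ok <- vapply(poses, function(p) {
      nxt <- contacts(result$receptor,
                      set_coords(result$ligand,
                                 apply_transform(coords(result$ligand),
                                                 p$transform)),
                      cutoff = contact_cutoff)
      prv <- contacts(result$receptor,
                      set_coords(result$ligand,
                                 apply_transform(coords(result$ligand),
                                                 invert_transform(p$transform))),
                      cutoff = contact_cutoff)
      res <- c(nxt$res_a, nxt$res_b, prv$res_a, prv$res_b)
      resid <- as.integer(sub("^\\S+ (\\d+).*$", "\\1", res))
      !any(resid %in% boundary_residues)
    }, logical(1))
    poses <- poses[ok]
  }
  if (length(poses) > 1) {            # dedup, poses already energy-sorted
    xl <- coords(result$ligand)
    placed <- lapply(poses, function(p) apply_transform(xl, p$transform))
    keep <- logical(length(poses))
    for (i in seq_along(poses)) {
      dup <- FALSE
      for (j in which(keep)) {
        d <- sqrt(mean(rowSums((placed[[i]] - placed[[j]])^2)))
        if (d < dedup_rmsd) { dup <- TRUE; break }
      }
      keep[i] <- !dup
    }
    poses <- poses[keep]
  }
  out <- .dock_result(poses, result$receptor, result$ligand)
  attr(out, "empty") <- length(poses) == 0
  out
}
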