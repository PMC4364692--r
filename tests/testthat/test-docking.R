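test_that("global start grids cover a shell at the requested density", {
  red <- coarse_grain(toy_blob(20))
  grid <- generate_starts(red, red, "global", spacing = 10, surf_dist = 5)
  R <- 2 * monomer_radius(red) + 5
  expected <- 4 * pi * R^2 / 100
  expect_equal(nrow(grid$positions), expected, tolerance = 0.1)
  # all positions on the shell
  d <- sqrt(rowSums((grid$positions -
                     rep(centroid(red), each = nrow(grid$positions)))^2))
  expect_true(all(abs(d - R) < 1e-6))
  expect_equal(length(grid$orientations), 6)
})

test_that("targeted grids stay within range of the reference and are denser", {
  red <- coarse_grain(toy_blob(20))
  ref <- rigid_transform(diag(3), c(25, 0, 0))
  tg <- generate_starts(red, red, "targeted", ref_pose = ref)
  com <- colMeans(apply_transform(coords(red), ref))
  d <- sqrt(rowSums((tg$positions - rep(com, each = nrow(tg$positions)))^2))
  expect_true(all(d <= 20 + 1e-9))
  expect_equal(tg$spacing, 2)
  gl <- generate_starts(red, red, "global", spacing = 10)
  # density: targeted points per volume exceed the global shell density
  expect_gt(nrow(tg$positions), nrow(gl$positions))
})

test_that("minimizer descends and finds the two-bead analytic minimum", {
  ff <- forcefield_params()
  a <- one_bead(c(0, 0, 0), class = "SCA")
  b <- one_bead(c(0, 0, 0), class = "SCA")
  rm_ <- 2 * ff$radius[["SCA"]]
  p <- minimize_pose(a, b, list(position = c(rm_ + 1.5, 0, 0),
                                orientation = diag(3)), ff)
  d <- sqrt(sum((as.numeric(p$transform$t))^2))
  expect_equal(d, rm_, tolerance = 1e-3)
  expect_equal(p$energy, -ff$eps[["SCA"]], tolerance = 1e-9)
  # start exactly at a minimum: stays put
  p2 <- minimize_pose(a, b, list(position = c(rm_, 0, 0),
                                 orientation = diag(3)), ff)
  expect_equal(as.numeric(p2$transform$t), c(rm_, 0, 0), tolerance = 1e-6)
  # descent property from assorted starts
  red <- coarse_grain(toy_blob(15))
  set.seed(5)
  for (i in 1:5) {
    pos <- centroid(red) + rand_unit() * runif(1, 15, 40)
    st <- list(position = pos, orientation = helixweaver:::.rotmat(rand_unit(),
                                                                   runif(1, 0, 180)))
    e_start <- as.numeric(interaction_energy(
      red, red, ff,
      pose = rigid_transform(st$orientation,
                             st$position - as.numeric(st$orientation %*% centroid(red)))))
    pp <- minimize_pose(red, red, st, ff, maxit = 80)
    expect_lte(pp$energy, e_start + 1e-9)
  }
})

test_that("dock is deterministic and sorts poses by energy", {
  red <- coarse_grain(toy_blob(12, seed = 13))
  ff <- forcefield_params()
  grid <- generate_starts(red, red, "global", spacing = 25, n_orient = 2)
  r1 <- dock(red, red, grid, ff, maxit = 60)
  r2 <- dock(red, red, grid, ff, maxit = 60)
  expect_identical(r1$table, r2$table)
  expect_true(!is.unsorted(r1$table$energy))
  expect_equal(nrow(r1$table), nrow(grid$positions) * 2)
})

test_that("filter_poses applies the energy window, boundary and dedup rules", {
  red <- coarse_grain(toy_blob(12, seed = 13))
  mk <- function(e, tx) list(transform = rigid_transform(diag(3), c(tx, 0, 0)),
                             energy = e, converged = TRUE, capped = FALSE,
                             start_id = NA_integer_)
  poses <- list(mk(-40, 30), mk(-35, 40), mk(-21, 50), mk(-19, 60))
  res <- helixweaver:::.dock_result(poses, red, red)
  f <- filter_poses(res, e_window = 20)
  # E_ref = -40: keeps -40, -35, -21; drops -19
  expect_equal(sort(f$table$energy), c(-40, -35, -21))
  # explicit reference
  f2 <- filter_poses(res, e_ref = -40, e_window = 20)
  expect_equal(nrow(f2$table), 3)
  # dedup: two nearly identical placements keep the better one
  poses3 <- list(mk(-40, 30), mk(-39, 30.4), mk(-30, 45))
  res3 <- helixweaver:::.dock_result(poses3, red, red)
  f3 <- filter_poses(res3, dedup_rmsd = 1.0)
  expect_equal(f3$table$energy, c(-40, -30))
  # idempotent, never grows
  f4 <- filter_poses(f3, dedup_rmsd = 1.0)
  expect_equal(f4$table$energy, f3$table$energy)
})

test_that("boundary-residue contacts disqualify a pose", {
  m <- toy_rod(16, seed = 2)
  red <- coarse_grain(m)
  # pose touching the rod's first residues
  span <- range(red$beads$x)
  pose <- list(transform = rigid_transform(diag(3),
                                           c(span[1] - 4, 0, 0)),
               energy = -10, converged = TRUE, capped = FALSE,
               start_id = NA_integer_)
  res <- helixweaver:::.dock_result(list(pose), red, red)
  kept <- filter_poses(res, boundary_residues = integer())
  expect_equal(nrow(kept$table), 1)
  gone <- filter_poses(res, boundary_residues = c(1L, 2L))
  expect_equal(nrow(gone$table), 0)
  expect_true(attr(gone, "empty"))
})

test_that("role swap yields the mirror-equivalent top pose", {
  red <- coarse_grain(toy_shoe(14, seed = 3))
  ff <- forcefield_params()
  grid <- generate_starts(red, red, "global", spacing = 20, n_orient = 3)
  r <- dock(red, red, grid, ff, maxit = 80)
  top <- r$poses[[1]]
  # receptor/ligand exchange: the inverse transform has the same energy
  e_sw <- as.numeric(interaction_energy(red, red, ff,
                                        pose = invert_transform(top$transform)))
  expect_equal(e_sw, top$energy, tolerance = 1e-6)
})
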