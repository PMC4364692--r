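test_that("contacts match a brute-force all-pairs scan", {
  set.seed(31)
  a <- toy_blob(25, seed = 1)
  b <- apply_transform(toy_blob(25, seed = 2),
                       rigid_transform(diag(3), c(14, 2, -1)))
  cs <- contacts(a, b, cutoff = 5)
  # independent O(n^2) oracle
  oracle <- list()
  for (i in seq_len(nrow(a$atoms))) {
    d <- sqrt((b$atoms$x - a$atoms$x[i])^2 + (b$atoms$y - a$atoms$y[i])^2 +
              (b$atoms$z - a$atoms$z[i])^2)
    js <- which(d < 5)
    if (length(js))
      oracle[[length(oracle) + 1]] <- data.frame(
        res_a = paste(a$atoms$chain[i], a$atoms$resid[i], a$atoms$ins[i]),
        res_b = paste(b$atoms$chain[js], b$atoms$resid[js], b$atoms$ins[js]))
  }
  oracle <- unique(do.call(rbind, oracle))
  expect_setequal(paste(cs$res_a, cs$res_b),
                  paste(oracle$res_a, oracle$res_b))
  # far apart: empty
  far <- apply_transform(b, rigid_transform(diag(3), c(500, 0, 0)))
  expect_equal(nrow(contacts(a, far, 5)), 0)
})

test_that("a 4.9 A atom pair is a contact at cutoff 5", {
  at <- data.frame(atom = c("CA", "CB"), element = "C", resid = 1L, ins = "",
                   resname = "ALA", chain = "A",
                   x = c(0, 1), y = 0, z = 0)
  A <- structure_new(at[1, ], "a")
  B <- structure_new(transform(at[2, ], resid = 2L, x = 4.9), "b")
  expect_equal(nrow(contacts(A, B, 5)), 1)
  expect_equal(nrow(contacts(A, B, 4.8)), 0)
})

test_that("fnat and fir behave on identity, disjoint and partial sets", {
  a <- toy_blob(25, seed = 1)
  b <- apply_transform(a, rigid_transform(diag(3), c(16, 0, 0)))
  cs <- contacts(a, b, 5)
  expect_gt(nrow(cs), 0)
  expect_equal(fnat(cs, cs), 1)
  expect_equal(fir(cs, cs), 1)
  empty <- contacts(a, apply_transform(b, rigid_transform(diag(3), c(500, 0, 0))), 5)
  expect_equal(fnat(cs, empty), 0)
  expect_error(fnat(empty, cs), "undefined")
  expect_error(fir(character(), character()), "undefined")
  # monotone non-increasing under removal of shared pairs
  half <- cs[seq_len(floor(nrow(cs) / 2)), , drop = FALSE]
  expect_lte(fnat(cs, half), fnat(cs, cs))
  # fir on explicit residue lists
  expect_equal(fir(c("A 1 ", "A 2 "), c("A 2 ", "A 9 ")), 0.5)
})

test_that("rmsd modes: identity, planted ligand offset, interface", {
  a <- toy_blob(20, seed = 6)
  expect_equal(rmsd(a, a), 0, tolerance = 1e-12)
  # ligand mode: dimers differing by a pure 4 A ligand shift
  s <- screw_z(55, 12)
  lig1 <- apply_transform(a, transform_from_screw(s))
  lig2 <- apply_transform(lig1, rigid_transform(diag(3), c(4, 0, 0)))
  r <- rmsd(a, a, mode = "ligand", A_lig = lig1, B_lig = lig2)
  expect_equal(r, 4, tolerance = 1e-9)
  # global mode removes a joint motion
  g <- rand_transform()
  expect_equal(rmsd(a, apply_transform(a, g), mode = "global"), 0,
               tolerance = 1e-9)
  expect_gt(rmsd(a, apply_transform(a, g), mode = "direct"), 1)
})

test_that("sasa matches the closed form and refines toward the oracle", {
  at <- data.frame(atom = "C1", element = "C", resid = 1L, ins = "",
                   resname = "LIG", chain = "A", x = 0, y = 0, z = 0)
  lone <- structure_new(at, "one")
  expect_equal(sasa(lone, probe = 1.4, n_points = 960),
               4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  # two overlapping spheres bury area
  at2 <- rbind(at, transform(at, atom = "C2", x = 2.0))
  two <- structure_new(at2, "two")
  s2 <- sasa(two)
  expect_lt(sum(s2), 2 * 4 * pi * 3.1^2)
  expect_gt(sum(s2), 4 * pi * 3.1^2)
  # refinement oracle on a 10-atom cluster: 960 points within 1% of a
  # 10x denser reference
  set.seed(40)
  atoms <- do.call(rbind, lapply(1:10, function(i)
    transform(at, atom = paste0("C", i), resid = i,
              x = rnorm(1, sd = 2.2), y = rnorm(1, sd = 2.2),
              z = rnorm(1, sd = 2.2))))
  clus <- structure_new(atoms, "cluster")
  coarse <- sum(sasa(clus, n_points = 960))
  fine <- sum(sasa(clus, n_points = 9600))
  expect_lt(abs(coarse - fine) / fine, 0.01)
  # unknown element errors
  bad <- structure_new(transform(at, element = "XX"), "bad")
  expect_error(sasa(bad), "radius-table")
})

test_that("buried surface vanishes at distance and decomposes additively", {
  a <- toy_blob(15, seed = 8)
  bfar <- apply_transform(a, rigid_transform(diag(3), c(100, 0, 0)))
  out <- buried_surface(a, bfar, n_points = 240)
  expect_equal(out$bsa_a, 0, tolerance = 1e-9)
  # touching pair buries symmetric-ish area
  bnear <- apply_transform(a, rigid_transform(diag(3), c(13, 0, 0)))
  out2 <- buried_surface(a, bnear, n_points = 240)
  expect_gt(out2$bsa_a, 50)
  expect_lt(abs(out2$bsa_a - out2$bsa_b) / max(out2$bsa_a, out2$bsa_b), 0.5)
  # atomic decomposition is exactly additive; truncation approximately
  spec <- region_spec(ranges = list(head = c(1, 5), mid = c(6, 10)))
  dat <- buried_surface(a, bnear, regions = spec, method = "atomic",
                        n_points = 240)
  expect_equal(sum(dat$regions_a$bsa), dat$bsa_a, tolerance = 1e-9)
  dtr <- buried_surface(a, bnear, regions = spec, method = "truncation",
                        n_points = 240)
  expect_equal(sum(dtr$regions_a$bsa), dtr$bsa_a,
               tolerance = 0.25 * max(dtr$bsa_a, 1))
})

test_that("groove width is ~0 for a solid wall and recovers a built-in gap", {
  # solid cylinder of atoms: radius 10, z in [0, 40]
  grid <- expand.grid(ring = 0:35, z = seq(0, 40, by = 1.5))
  at <- data.frame(atom = "CA", element = "C",
                   resid = seq_len(nrow(grid)), ins = "", resname = "GLY",
                   chain = "A",
                   x = 10 * cos(grid$ring * 10 * pi / 180),
                   y = 10 * sin(grid$ring * 10 * pi / 180),
                   z = grid$z)
  solid <- structure_new(at, "cyl")
  ax <- screw(c(0, 0, 0), c(0, 0, 1), 36, 4)   # pitch 40 covers the z-range
  gp <- groove_width(solid, ax, angular_step = 10, atom_radius = 2)
  expect_lt(max(gp$width_mean, na.rm = TRUE), 1.5)
  # helical ribbon with an engineered 12 A gap: rungs every 20 A in z,
  # ribbon thickness ~ 2*4 A, so the free gap is 20 - 8 = 12 A
  rungs <- expand.grid(ring = 0:71, lev = 0:3)
  rb <- data.frame(atom = "CA", element = "C",
                   resid = seq_len(nrow(rungs)), ins = "", resname = "GLY",
                   chain = "A",
                   x = 12 * cos(rungs$ring * 5 * pi / 180),
                   y = 12 * sin(rungs$ring * 5 * pi / 180),
                   z = rungs$lev * 20)
  ribbon <- structure_new(rb, "ribbon")
  ax2 <- screw(c(0, 0, 0), c(0, 0, 1), 36, 2)  # pitch 20
  gp2 <- groove_width(ribbon, ax2, angular_step = 10, atom_radius = 4)
  med <- stats::median(gp2$width_mean, na.rm = TRUE)
  expect_equal(med, 12, tolerance = 1)
})
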