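test_that("build_filament stacks chains by powers of the screw", {
  m <- toy_shoe(15)
  s <- screw_z(60, 14.17, O = c(3, 1, 0))
  fil <- build_filament(m, s, 5)
  expect_equal(unique(fil$atoms$chain), c("A", "B", "C", "D", "E"))
  tr <- transform_from_screw(s)
  for (i in c(2, 5)) {
    want <- apply_transform(coords(m), transform_power(tr, i - 1))
    got <- coords(get_chain(fil, chain_ids(i)[i]))
    expect_lt(max(abs(want - got)), 1e-9)
  }
  expect_error(build_filament(m, s, 1e7), "size error")
})

test_that("cyclic screws close rings exactly", {
  m <- toy_shoe(15)
  s <- screw_z(60, 0, O = c(10, -4, 0))
  t6 <- transform_power(transform_from_screw(s), 6)
  expect_lt(max(abs(apply_transform(coords(m), t6) - coords(m))), 1e-6)
})

test_that("composite screw of monomers 1 and k+1 scales the generator", {
  m <- toy_blob(18)
  set.seed(4)
  s <- rand_screw(theta_range = c(20, 50))
  fil <- build_filament(m, s, 5)
  sk <- screw_between_monomers(get_chain(fil, "A"), get_chain(fil, "D"))
  expect_equal(sk$theta, 3 * s$theta, tolerance = 1e-6)
  expect_equal(abs(sk$trans), 3 * abs(s$trans), tolerance = 1e-6)
})

test_that("mixed filament with a single interface reduces to build_filament", {
  m <- toy_shoe(15)
  s <- screw_z(58, 15, O = c(2, 0, 0))
  spec <- filament_spec(list(X = s), rep("X", 1), n = 6)
  mix <- build_mixed_filament(m, spec)
  fil <- build_filament(m, s, 6)
  expect_lt(max(abs(coords(mix$structure) - coords(fil))), 1e-9)
  expect_equal(mix$block_params$N, 360 / 58, tolerance = 1e-9)
})

test_that("mixed-mode repeat block predicts the built super-helix", {
  m <- toy_shoe(15)
  sX <- screw_z(60, 13.8)
  # X*-like: slightly different angle, tilted axis through a shifted point
  ax <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  sXs <- screw(c(4, 0, 0) - sum(c(4, 0, 0) * ax) * ax, ax, 58.06, 15.19)
  spec <- filament_spec(list(X = sX, Xs = sXs), c("X", "Xs"), n = 13)
  mix <- build_mixed_filament(m, spec)
  # block transform equals the screw of (monomer 1 -> monomer 3)
  got <- screw_between_monomers(get_chain(mix$structure, "A"),
                                get_chain(mix$structure, "C"))
  expect_equal(got$theta, mix$block_screw$theta, tolerance = 1e-6)
  expect_equal(abs(got$trans), abs(mix$block_screw$trans), tolerance = 1e-6)
  # the block axis direction matches the axis fitted from distant blocks
  far <- screw_between_monomers(get_chain(mix$structure, "A"),
                                get_chain(mix$structure, "M"))
  dot <- abs(sum(far$axis * mix$block_screw$axis))
  expect_gt(dot, cos(0.5 * pi / 180))
})

test_that("curved-axis construction reproduces the straight limit", {
  m <- toy_shoe(12)
  s <- screw_z(47, 11, O = c(5, 2, 0))
  straight <- build_filament(m, s, 8)
  curved <- build_on_curve(m, s, curve = NULL, n = 8)
  expect_lt(max(abs(coords(straight) - coords(curved))), 1e-6)
})

test_that("circular guides close into toroids", {
  m <- make_toy_monomer(10, "blob", seed = 3)
  s <- screw_z(36, 12)
  n <- 20
  radius <- n * abs(s$trans) / (2 * pi)     # circumference = n * rise
  tor <- build_on_curve(m, s, curve_circle(radius), n = n)
  # ring closure: the first/last centroid gap looks like one more step of
  # the chain of consecutive gaps, not like the open end of a filament
  cents <- t(vapply(chain_ids(n),
                    function(id) centroid(get_chain(tor, id)), numeric(3)))
  gap <- sqrt(sum((cents[1, ] - cents[n, ])^2))
  consec <- sqrt(rowSums((cents[-1, , drop = FALSE] -
                          cents[-n, , drop = FALSE])^2))
  expect_lt(gap, 2 * stats::median(consec))
  # an uncurved build of the same screw leaves the ends ~(n-1) rises apart
  open_gap <- (n - 1) * abs(s$trans)
  expect_lt(gap, open_gap / 5)
})

test_that("gentle supercoils preserve the local interface", {
  m <- make_toy_monomer(10, "blob", seed = 3)
  s <- screw_z(58, 15)
  sc <- build_on_curve(m, s, curve_helix(55, 1600), n = 8)
  straight <- build_filament(m, s, 8)
  # compare local consecutive-pair interfaces via ligand rmsd after
  # superposing the first of each pair
  for (i in c(1, 4, 7)) {
    ids <- chain_ids(8)
    r <- rmsd(get_chain(straight, ids[i]), get_chain(sc, ids[i]),
              mode = "ligand",
              A_lig = get_chain(straight, ids[i + 1]),
              B_lig = get_chain(sc, ids[i + 1]))
    expect_lt(r, 1.0)
  }
})

test_that("supercoiled pairs respect separation and limits", {
  m <- make_toy_monomer(10, "blob", seed = 3)
  s <- screw_z(58, 15)
  out <- build_supercoiled_pair(m, s, supercoil_pitch = 1600,
                                separation = 110, n = 6)
  expect_equal(length(unique(out$structure$atoms$chain)), 12)
  # strand axis separation: distance between guide curves at equal arc
  g1 <- out$guides[[1]](c(0, 30)); g2 <- out$guides[[2]](c(0, 30))
  d <- sqrt(rowSums((g1 - g2)^2))
  expect_true(all(abs(d - 110) < 1))
  # infinite pitch: two straight parallel filaments
  inf <- build_supercoiled_pair(m, s, Inf, 110, n = 4)
  z1 <- coords(get_chain(inf$structure, "A"))
  z2 <- coords(get_chain(inf$structure, "E"))
  expect_equal(sqrt(sum((colMeans(z1) - colMeans(z2))^2)), 110,
               tolerance = 1e-6)
  expect_error(build_supercoiled_pair(m, s, 1600, 0, n = 4), "positive")
  expect_warning(build_supercoiled_pair(m, s, 1600, 5, n = 4), "clash")
})

test_that("constructions are deterministic", {
  m <- toy_shoe(12)
  s <- screw_z(47, 11)
  expect_identical(coords(build_filament(m, s, 6)),
                   coords(build_filament(m, s, 6)))
  expect_identical(coords(build_on_curve(m, s, curve_helix(60, 900), 6)),
                   coords(build_on_curve(m, s, curve_helix(60, 900), 6)))
})
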