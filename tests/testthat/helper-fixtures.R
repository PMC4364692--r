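# Shared fixtures for the test suite.  Everything is generated in code;
# nothing is downloaded.

# small deterministic monomers
toy_blob <- function(n = 20, seed = 5) make_toy_monomer(n, "blob", seed = seed)
toy_rod <- function(n = 20, seed = 5) make_toy_monomer(n, "rod", seed = seed)
toy_shoe <- function(n = 20, seed = 5)
  make_toy_monomer(n, "horseshoe", seed = seed)

# canonical screws
screw_z <- function(theta, trans, O = c(0, 0, 0))
  screw(O, c(0, 0, 1), theta, trans)

rand_unit <- function() { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }

# random proper screw with axis point perpendicular to the axis
rand_screw <- function(theta_range = c(5, 175), trans_range = c(-20, 20)) {
  ax <- rand_unit()
  O <- stats::rnorm(3, sd = 25)
  screw(O - sum(O * ax) * ax, ax,
        stats::runif(1, theta_range[1], theta_range[2]),
        stats::runif(1, trans_range[1], trans_range[2]))
}

rand_transform <- function() {
  ax <- rand_unit()
  rigid_transform(helixweaver:::.rotmat(ax, stats::runif(1, 0, 179)),
                  stats::rnorm(3, sd = 15))
}

# maximum point-mapping discrepancy of two transforms over a point cloud
transform_gap <- function(t1, t2, pts = NULL) {
  if (is.null(pts)) { set.seed(42); pts <- matrix(stats::rnorm(60, sd = 30), ncol = 3) }
  max(abs(apply_transform(pts, t1) - apply_transform(pts, t2)))
}

# monomer with a single engineered binding site: oppositely charged tips of
# a horseshoe; with a strengthened dielectric the tip-to-tip + concave
# packing mode dominates every alternative
engineered_monomer <- function() {
  rn <- rep("LEU", 20); rn[1] <- "ARG"; rn[20] <- "ASP"
  make_toy_monomer(20, "horseshoe", seed = 11, resnames = rn)
}

engineered_ff <- function() forcefield_params(eps0 = 4)

# bound dimer pose of the toy horseshoe (used by the MC tests): minimize
# from a near-contact start and verify an actual interface formed
make_bound_system <- function(seed = 3, ff = forcefield_params()) {
  red <- coarse_grain(make_toy_monomer(14, "horseshoe", seed = seed))
  start <- minimize_pose(red, red,
                         list(position = centroid(red) + c(0, 0, 6),
                              orientation = diag(3)), ff, maxit = 200)
  placed <- set_coords(red, apply_transform(coords(red), start$transform))
  ref <- contacts(red, placed, cutoff = 7)
  stopifnot(nrow(ref) > 0)
  list(red = red, ff = ff, start = start, ref = ref)
}

# single-bead reduced structures for closed-form energy checks
one_bead <- function(xyz, class = "SCA", charge = 0, resname = "LEU") {
  beads <- data.frame(atom = "SC1", class = class, charge = charge,
                      resid = 1L, ins = "", resname = resname, chain = "A",
                      x = xyz[1], y = xyz[2], z = xyz[3], natoms = 4L)
  structure(list(beads = beads, scheme = "bb+sc2", label = "bead"),
            class = "ReducedStructure")
}

pdb_fixture_3res <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A  10      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A  10      12.697   7.143  -4.936  1.00  0.00           C",
    "ATOM      4  O   ALA A  10      13.560   7.312  -5.797  1.00  0.00           O",
    "ATOM      5  CB  ALA A  10      10.536   6.237  -4.113  1.00  0.00           C",
    "ATOM      6  N   GLY A  11      12.639   7.861  -3.815  1.00  0.00           N",
    "ATOM      7  CA  GLY A  11      13.602   8.920  -3.528  1.00  0.00           C",
    "ATOM      8  C   GLY A  11      13.861   9.747  -4.780  1.00  0.00           C",
    "ATOM      9  O   GLY A  11      12.989   9.906  -5.635  1.00  0.00           O",
    "ATOM     10  N   ARG A  12      15.068  10.281  -4.900  1.00  0.00           N",
    "ATOM     11  CA  ARG A  12      15.436  11.099  -6.050  1.00  0.00           C",
    "ATOM     12  C   ARG A  12      16.953  11.175  -6.165  1.00  0.00           C",
    "ATOM     13  O   ARG A  12      17.662  10.729  -5.261  1.00  0.00           O",
    "ATOM     14  CB  ARG A  12      14.860  10.529  -7.349  1.00  0.00           C",
    "ATOM     15  CG  ARG A  12      15.214  11.355  -8.582  1.00  0.00           C",
    "ATOM     16  CD  ARG A  12      14.663  10.742  -9.863  1.00  0.00           C",
    "ATOM     17  NE  ARG A  12      15.069  11.508 -11.040  1.00  0.00           N",
    "ATOM     18  CZ  ARG A  12      14.749  11.184 -12.291  1.00  0.00           C",
    "ATOM     19  NH1 ARG A  12      14.005  10.113 -12.548  1.00  0.00           N",
    "ATOM     20  NH2 ARG A  12      15.178  11.937 -13.296  1.00  0.00           N",
    "END"), path)
  path
}
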