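water_xyz <- function(path) {
  writeLines(c("3", "water",
               "O   0.000000   0.000000   0.117300",
               "H   0.000000   0.757200  -0.469200",
               "H   0.000000  -0.757200  -0.469200"), path)
  path
}

test_that("XYZ files round-trip through read/write", {
  p <- water_xyz(withr::local_tempfile(fileext = ".xyz"))
  s <- read_xyz(p)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$label, c("O1", "H2", "H3"))

  frag <- make_fragment(fragment_spec(tau1 = 30, tau2 = -120, tau_aryl = 70))
  p2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frag, p2)
  back <- read_xyz(p2)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(frag$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("malformed XYZ input is rejected", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "truncated",
               "C 0 0 0", "C 1 0 0", "C 1 1 0", "C 2 1 0"), p)
  expect_error(read_xyz(p), "count is 5")
  writeLines(c("1", "bad", "C zero 0 0"), p)
  expect_error(read_xyz(p), "non-numeric")
})

test_that("dihedral follows the IUPAC sign convention", {
  s_trans <- structure3d(rep("C", 4), c(0, 1, 1, 2), c(0, 0, 1, 1),
                         c(0, 0, 0, 0))
  expect_equal(dihedral(s_trans, "C1", "C2", "C3", "C4"), 180)
  s_cis <- structure3d(rep("C", 4), c(0, 1, 1, 0), c(0, 0, 1, 1),
                       c(0, 0, 0, 0))
  expect_equal(dihedral(s_cis, "C1", "C2", "C3", "C4"), 0)
  s_col <- structure3d(rep("C", 4), c(0, 1, 2, 3), c(0, 0, 0, 1),
                       c(0, 0, 0, 0))
  expect_error(dihedral(s_col, "C1", "C2", "C3", "C4"), "collinear")
})

test_that("dihedral is invariant under atom-order reversal, negated by mirroring", {
  # the signed IUPAC torsion does not depend on which end it is viewed from;
  # reflection through a plane flips its sign
  set.seed(3)
  for (i in 1:20) {
    xyz <- matrix(rnorm(12), 4, 3)
    s <- structure3d(rep("C", 4), xyz[, 1], xyz[, 2], xyz[, 3])
    fwd <- dihedral(s, "C1", "C2", "C3", "C4")
    rev <- dihedral(s, "C4", "C3", "C2", "C1")
    expect_equal(rev, fwd, tolerance = 1e-9)
    mirrored <- structure3d(rep("C", 4), xyz[, 1], xyz[, 2], -xyz[, 3])
    mir <- dihedral(mirrored, "C1", "C2", "C3", "C4")
    if (abs(abs(fwd) - 180) > 1e-9)
      expect_equal(mir, -fwd, tolerance = 1e-9)
  }
})

test_that("dihedral agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(17)
  for (i in 1:20) {
    xyz <- matrix(rnorm(12, sd = 2), 4, 3)
    s <- structure3d(rep("C", 4), xyz[, 1], xyz[, 2], xyz[, 3])
    expect_equal(dihedral(s, "C1", "C2", "C3", "C4"),
                 as.numeric(bio3d::torsion.xyz(as.vector(t(xyz)))),
                 tolerance = 1e-6)
  }
})

test_that("virtual angles handle right angles, collinearity and errors", {
  s <- structure3d(rep("C", 4), c(1, 0, 0, -1), c(0, 0, 1, 0), c(0, 0, 0, 0))
  expect_equal(virtual_angle(s, "C1", "C2", "C3"), 90)
  expect_equal(virtual_angle(s, "C1", "C2", "C4"), 180)
  s2 <- structure3d(rep("C", 3), c(0, 0, 1), c(0, 0, 0), c(0, 0, 0))
  expect_error(virtual_angle(s2, "C1", "C2", "C3"), "coincident")
})

test_that("vdW contacts use the radii-sum threshold", {
  s <- structure3d(c("O", "H", "S", "H", "C", "C"),
                   x = c(0, 2.20, 10, 12.80, 20, 30),
                   y = 0, z = 0)
  oh <- vdw_contact(s, "O1", "H2")
  expect_equal(oh$threshold, 2.69)
  expect_true(oh$is_contact)
  sh <- vdw_contact(s, "S3", "H4")
  expect_equal(sh$threshold, 2.97)
  expect_true(sh$is_contact)    # 2.80 A: marginal but below the sum
  far <- vdw_contact(s, "C5", "C6")
  expect_false(far$is_contact)
  expect_error(vdw_contact(s, "O1", "O1"), "distinct")
})

test_that("ring puckering classifies planar rings and ideal chairs", {
  hexagon <- structure3d(rep("C", 6),
                         x = 1.4 * cos(2 * pi * (0:5) / 6),
                         y = 1.4 * sin(2 * pi * (0:5) / 6), z = 0)
  pk <- ring_pucker(hexagon, paste0("C", 1:6))
  expect_equal(pk$label, "planar")
  expect_lt(pk$Q, 1e-8)

  # ideal chair built from tetrahedral internal coordinates, 1.54 A bonds
  L <- 1.54; r0 <- sqrt(8) / 3 * L; z0 <- r0 / (4 * sqrt(2))
  chair <- structure3d(rep("C", 6),
                       x = r0 * cos(pi * (0:5) / 3),
                       y = r0 * sin(pi * (0:5) / 3),
                       z = z0 * (-1)^(0:5))
  pk <- ring_pucker(chair, paste0("C", 1:6))
  expect_gt(pk$Q, 0.5)
  expect_true(pk$theta < 5 || pk$theta > 175)
  expect_error(ring_pucker(chair, paste0("C", 1:5)), "six")
})

test_that("the 4C1 pyranose fragment is labeled 4C1", {
  frag <- make_fragment(fragment_spec())
  pk <- ring_pucker(frag, c("O5", "C1", "C2", "C3", "C4", "C5"))
  expect_equal(pk$label, "4C1")
  expect_lt(pk$theta, 5)
})

test_that("Karplus relation and antiperiplanar rule behave as documented", {
  expect_equal(karplus_j(90), 0.4)            # cos terms vanish
  expect_equal(karplus_j(180), 10.9)
  # symmetric about 180 and maximal there
  thetas <- seq(0, 360, by = 5)
  expect_equal(karplus_j(thetas), karplus_j(360 - thetas))
  expect_equal(thetas[which.max(karplus_j(thetas))], 180)
  expect_true(antiperiplanar_check(9.5))
  expect_false(antiperiplanar_check(7.5))     # strict inequality
  expect_error(antiperiplanar_check(-1))
})

test_that("geometric measurements are invariant under rigid motions", {
  set.seed(29)
  frag <- make_fragment(fragment_spec(tau1 = 25, tau2 = -130, tau_aryl = 65))
  ring <- c("O5", "C1", "C2", "C3", "C4", "C5")
  ref <- list(
    d = dihedral(frag, "C2", "N2", "C7", "O7"),
    a = virtual_angle(frag, "N2", "C7", "N8"),
    pk = ring_pucker(frag, ring),
    ct = vdw_contact(frag, "O7", "HN8")$distance)
  for (i in 1:10) {
    moved <- apply_rigid(frag, random_rigid_motion())
    expect_equal(dihedral(moved, "C2", "N2", "C7", "O7"), ref$d,
                 tolerance = 1e-6)
    expect_equal(virtual_angle(moved, "N2", "C7", "N8"), ref$a,
                 tolerance = 1e-6)
    pk <- ring_pucker(moved, ring)
    expect_equal(pk$Q, ref$pk$Q, tolerance = 1e-6)
    expect_equal(pk$theta, ref$pk$theta, tolerance = 1e-6)
    expect_equal(vdw_contact(moved, "O7", "HN8")$distance, ref$ct,
                 tolerance = 1e-6)
  }
})
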