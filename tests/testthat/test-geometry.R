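test_that("magnesium center uses MG, falls back to the N centroid", {
  p <- make_chlorin(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(magnesium_center(p), c(0, 0, 0), tolerance = 1e-6)
  p_nomg <- make_chlorin(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0),
                         include_mg = FALSE)
  expect_equal(magnesium_center(p_nomg), c(0, 0, 0), tolerance = 1e-6)
  # two nitrogens only -> degenerate error
  p2 <- p_nomg
  p2$atoms <- p2$atoms[p2$atoms$atom_name %in% c("NB", "ND"), ]
  expect_error(magnesium_center(p2), "degenerate")
  expect_error(magnesium_center(make_polyene(8)), "chlorin")
})

test_that("qy dipole matches the planted axis and transforms with rotations", {
  p <- make_chlorin(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(qy_dipole(p)$direction, c(1, 0, 0), tolerance = 1e-6)
  # rotate 90 degrees about z: x-axis dipole becomes y-axis
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  expect_equal(qy_dipole(rigid_transform(p, Rz))$direction, c(0, 1, 0),
               tolerance = 1e-6)
  # mirror image negates the direction but leaves kappa^2 unchanged
  pm <- p
  pm$atoms$x <- -pm$atoms$x
  expect_equal(qy_dipole(pm)$direction, c(-1, 0, 0), tolerance = 1e-6)
  other <- transition_dipole(c(0, 0, 9), c(1, 1, 0))
  expect_equal(kappa_squared(qy_dipole(p), other),
               kappa_squared(qy_dipole(pm), other))
  p3 <- p
  p3$atoms <- p3$atoms[p3$atoms$atom_name != "ND", ]
  expect_error(qy_dipole(p3), "Qy atoms")
})

test_that("ring plane fit recovers the planted normal, rmsd tracks noise", {
  p <- make_chlorin(c(1, 2, 3), c(0, 0, 1), c(1, 0, 0))
  pl <- ring_plane(p)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$rmsd_from_plane, 0, tolerance = 1e-9)
  set.seed(5)
  pn <- make_chlorin(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0),
                     out_of_plane_sd = 0.1)
  pln <- ring_plane(pn)
  expect_lt(abs(pln$rmsd_from_plane - 0.1), 0.08)
  ang <- acos(abs(sum(pln$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 5)
  # collinear atoms are rejected
  pc <- p
  pc$atoms$y <- 0
  pc$atoms$z <- 0
  expect_error(ring_plane(pc), "collinear")
})

test_that("interplane angle folds to [0, 90] and matches planted angles", {
  a <- ring_plane(make_chlorin(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)))
  expect_equal(interplane_angle(a, a), 0)
  b <- ring_plane(make_chlorin(c(9, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(interplane_angle(a, b), 90, tolerance = 1e-6)
  # obtuse normals fold: planted 120-degree tilt reads as 60
  c60 <- ring_plane(make_chlorin(c(0, 9, 0),
                                 c(sin(120 * pi / 180), 0,
                                   cos(120 * pi / 180)),
                                 c(0, 1, 0)))
  expect_equal(interplane_angle(a, c60), 60, tolerance = 1e-6)
})

test_that("minimum interatomic distance equals the brute-force oracle", {
  set.seed(21)
  for (i in 1:50) {
    pa <- make_chlorin(runif(3, -20, 20), rnorm(3), rnorm(3))
    pb <- make_polyene(sample(6:15, 1), chain_id = "B")
    pb <- rigid_transform(pb, random_rotation(), runif(3, -20, 20))
    md <- min_interatomic_distance(pa, pb)
    expect_equal(md$distance,
                 brute_min_distance(psifret:::pigment_coords(pa),
                                    psifret:::pigment_coords(pb)),
                 tolerance = 1e-12)
  }
  # arg-min atom pair is reported
  p1 <- make_chlorin(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  p2 <- make_chlorin(c(10, 0, 0), c(0, 0, 1), c(1, 0, 0), chain_id = "B",
                     residue_number = 602)
  md <- min_interatomic_distance(p1, p2)
  # the facing methine carbons (ring radius 3 A, at 45 degrees) come
  # closer than the facing nitrogens (radius 2.05 A on the axis)
  expect_equal(md$distance, 10 - 3 * sqrt(2), tolerance = 1e-9)
  expect_equal(md$atom_a, "CHA")
  expect_equal(md$atom_b, "CHB")
})

test_that("dihedrals: closed forms, planted twists, gap handling", {
  # four corners of a planar square traversed in a U: torsion 0
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # trans zig-zag: 180
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, -1, 0))), 180)
  pe <- make_polyene(12)
  dh <- polyene_dihedrals(pe)
  expect_equal(dh$bond_index, 2:13)
  expect_true(all(abs(abs(dh$dihedral_deg) - 180) < 1e-6))
  pe9 <- make_polyene(12, cis_positions = 9)
  dh9 <- polyene_dihedrals(pe9)
  expect_equal(abs(dh9$dihedral_deg[dh9$bond_index == 9]), 0,
               tolerance = 1e-6)
  # deleting a backbone atom removes the bonds that need it, reports the gap
  gap <- pe
  gap$atoms <- gap$atoms[gap$atoms$atom_name != "C7", ]
  dhg <- polyene_dihedrals(gap)
  expect_equal(attr(dhg, "gaps"), "C7")
  expect_false(any(dhg$bond_index %in% 5:8))
  expect_true(all(c(2:4, 9:13) %in% dhg$bond_index))
})

test_that("cis/trans classification: planted labels, boundary, rigid invariance", {
  expect_equal(classify_cis_trans(polyene_dihedrals(
    make_polyene(12)))$configuration, "all-trans")
  lab <- classify_cis_trans(polyene_dihedrals(
    make_polyene(20, cis_positions = c(9, 17))))
  expect_equal(lab$configuration, "cis")
  expect_equal(lab$cis_positions, c(9L, 17L))
  # threshold boundary
  dd <- data.frame(bond_index = 1:2, dihedral_deg = c(89.9, 179))
  expect_equal(classify_cis_trans(dd)$cis_positions, 1L)
  dd$dihedral_deg <- c(90.1, -89.9)
  expect_equal(classify_cis_trans(dd)$cis_positions, 2L)
  # invariant under rigid rotation + translation
  set.seed(33)
  for (i in 1:20) {
    cis <- sort(sample(2:11, sample(0:2, 1)))
    pe <- make_polyene(10, cis_positions = cis)
    pe2 <- rigid_transform(pe, random_rotation(), runif(3, -50, 50))
    lab2 <- classify_cis_trans(polyene_dihedrals(pe2))
    expect_equal(lab2$cis_positions, as.integer(cis))
  }
})

test_that("kappa^2 is symmetric, sign-invariant, and bounded", {
  set.seed(8)
  for (i in 1:200) {
    d <- transition_dipole(runif(3, -5, 5), rnorm(3))
    a <- transition_dipole(runif(3, -5, 5) + c(10, 0, 0), rnorm(3))
    k <- kappa_squared(d, a)
    expect_gte(k, 0)
    expect_lte(k, 4)
    expect_equal(k, kappa_squared(a, d))
    aneg <- transition_dipole(a$anchor, -a$direction)
    expect_equal(k, kappa_squared(d, aneg))
  }
  expect_error(kappa_squared(transition_dipole(c(0, 0, 0), c(1, 0, 0)),
                             transition_dipole(c(0, 0, 0), c(0, 1, 0))),
               "coincident")
})
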