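test_that("peptide COM depth matches the mass-weighted oracle", {
  set.seed(21)
  for (rep in 1:20) {
    tpl <- permeatrace:::buildPeptideTemplate("open")
    xyz <- matrix(rnorm(nrow(tpl$coords) * 3, 5, 2), ncol = 3)
    traj <- mkTraj(tpl$atoms, list(xyz))
    m <- atomData(traj)$mass
    zc <- runif(1, -1, 1)
    expect_equal(peptideComZ(traj, 0, zc),
                 sum(xyz[, 3] * m) / sum(m) - zc, tolerance = 1e-9)
  }
})

test_that("a peptide placed above the headgroups has the constructed depth", {
  gf <- membraneFixture(n_side = 6L, jitter = 0)
  mem <- gf$trajectory
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  z_mid <- frameBox(mem, 0)[3] / 2
  # ring 3 nm above the upper headgroup surface (which sits at +2.0)
  pep_xyz <- sweep(tpl$coords, 2, c(2, 2, z_mid + 5.0), "+")
  atoms <- rbind(tpl$atoms, atomData(mem)[, c("name", "resid", "resname")])
  traj <- mkTraj(atoms, list(rbind(pep_xyz, frameCoords(mem, 0))),
                 box = frameBox(mem, 0))
  ref <- referenceSurfaces(traj, 0)
  z <- peptideComZ(traj, 0, ref$z_center)
  # template COM is near the ring center (small backbone asymmetries)
  expect_equal(z, 5.0, tolerance = 0.05)
  expect_equal(ref$z_head_upper - ref$z_center, 2.0, tolerance = 1e-9)
})

test_that("backbone ellipse axes recover construction and rotate equivariantly", {
  phi <- 2 * pi * ((1:10) - 0.5) / 10
  pts <- cbind(0.7 * cos(phi), 0.5 * sin(phi), 0)
  ax <- permeatrace:::principalAxes(pts)
  expect_equal(abs(ax$major), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(abs(ax$minor), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(abs(sum(ax$major * ax$minor)), 1e-9)
  # known rotation
  th <- 0.7; ps <- 0.3
  R <- permeatrace:::rotX(th * 180 / pi) %*% permeatrace:::rotZ(ps * 180 / pi)
  axr <- permeatrace:::principalAxes(pts %*% t(R))
  expect_equal(abs(sum(axr$major * (R %*% ax$major))), 1, tolerance = 1e-9)
  expect_equal(abs(sum(axr$minor * (R %*% ax$minor))), 1, tolerance = 1e-9)
  # noisy rings (sigma = 0.05) recover the construction to ~5 degrees;
  # the error distribution over replicates is summarized by its median
  # since single 10-point instances are eigenvector-noise limited
  set.seed(31)
  angs <- replicate(100, {
    noisy <- pts + matrix(rnorm(30, 0, 0.05), ncol = 3)
    axn <- permeatrace:::principalAxes(noisy)
    acos(min(1, abs(sum(axn$major * c(1, 0, 0))))) * 180 / pi
  })
  expect_lt(median(angs), 5)
  # collinear backbone is degenerate
  line <- cbind(seq_len(10), 0, 0)
  expect_error(permeatrace:::principalAxes(line), "collinear")
})

test_that("orientation angle matches the atan2 oracle on random axis pairs", {
  expect_equal(orientationAngle(c(1, 0, 0), c(0, 1, 0))$theta, 0,
               tolerance = 1e-9)
  perp <- orientationAngle(c(0, 0, 1), c(0, 1, 0))
  expect_equal(perp$theta, 90, tolerance = 1e-9)
  expect_equal(perp$theta_folded, 90, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:500) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u  # ensure non-parallel
    v <- v / sqrt(sum(v^2))
    v2 <- (u + v) / sqrt(2)                 # oblique partner
    o <- orientationAngle(u, v2)
    a_expect <- oracleAngleDeg(o$normal, c(0, 0, 1))
    expect_equal(o$theta, a_expect, tolerance = 1e-9)
    expect_equal(o$theta_folded, min(a_expect, 180 - a_expect),
                 tolerance = 1e-9)
  }
  expect_error(orientationAngle(c(1, 0, 0), c(1, 0, 0)), "parallel")
})

test_that("hydrophobic moment is the polar-to-apolar COM difference", {
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  xyz <- tpl$coords
  # stack polar residues (ALA) at z = 0 and apolar at z = -1
  pol <- tpl$atoms$resname == "ALA"
  xyz[pol, 3] <- 0
  xyz[!pol, 3] <- -1
  traj <- mkTraj(tpl$atoms, list(xyz + 5))
  hm <- hydrophobicMoment(traj, 0)
  expect_equal(hm[3], -1, tolerance = 1e-9)
  # one-class polarity map: zero vector with warning
  allpol <- c(LEU = "apolar", ALA = "apolar", PRO = "apolar",
              PHE = "apolar")
  expect_warning(hm0 <- hydrophobicMoment(traj, 0, allpol), "one polarity")
  expect_equal(hm0, c(0, 0, 0))
})

test_that("entry-side normalization is an involution and flips lower entry", {
  res <- generateScenario(scenarioSpec(list(
    phase("diffuse", 3), phase("approach", 8),
    phase("anchor", 12, residue = 3)), seed = 17, n_side = 5L))
  traj <- res$trajectory
  # the raw box rotation is an involution
  twice <- rotateBoxX180(rotateBoxX180(traj))
  expect_lt(max(abs(twice@coords - traj@coords)), 1e-12)
  # upper-entry trajectory is returned unchanged
  same <- normalizeEntrySide(traj)
  expect_identical(same@coords, traj@coords)
  # a lower-entry trajectory (the same scenario mirrored) gets flipped back
  lower <- rotateBoxX180(traj)
  fixed <- normalizeEntrySide(lower)
  fc <- permeatrace:::firstContactFrame(fixed)
  zc <- referenceSurfaces(fixed, fc)$z_center
  expect_gt(peptideComZ(fixed, fc, zc), 0)
  # mirror-symmetric descriptors are preserved exactly
  ref_o <- membraneReference(traj); ref_f <- membraneReference(fixed)
  for (f in c(0L, 10L, 20L)) {
    z_o <- peptideComZ(traj, f, refTable(ref_o)$z_center[f + 1])
    z_f <- peptideComZ(fixed, f, refTable(ref_f)$z_center[f + 1])
    expect_equal(abs(z_f), abs(z_o), tolerance = 1e-9)
    ax_o <- backboneEllipseAxes(traj, f)
    ax_f <- backboneEllipseAxes(fixed, f)
    expect_equal(orientationAngle(ax_f$major, ax_f$minor)$theta_folded,
                 orientationAngle(ax_o$major, ax_o$minor)$theta_folded,
                 tolerance = 1e-9)
  }
})
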