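test_that("orientation A/B classification follows the reporter side chains", {
  # parallel in-membrane ring, reporters toward the center -> A;
  # the same geometry rolled 180 degrees about the major axis -> B
  specA <- scenarioSpec(list(
    phase("diffuse", 2), phase("approach", 5), phase("anchor", 8, residue = 3),
    phase("insert", 10), phase("orient", 10, orientation = "A"),
    phase("stay", 10)), seed = 5, n_side = 5L)
  resA <- generateScenario(specA)
  ref <- membraneReference(resA$trajectory)
  f <- nFrames(resA$trajectory) - 1L
  olA <- classifyOrientation(resA$trajectory, f, refTable(ref)[f + 1, ])
  expect_equal(olA$label, "A")
  expect_lt(olA$reporter_projection, 0)
  specB <- specA; specB$phases[[5]] <- phase("orient", 10, orientation = "B")
  resB <- generateScenario(specB)
  refB <- membraneReference(resB$trajectory)
  olB <- classifyOrientation(resB$trajectory, f, refTable(refB)[f + 1, ])
  expect_equal(olB$label, "B")
  expect_gt(olB$reporter_projection, 0)
  # outside the membrane: no label
  ol0 <- classifyOrientation(resA$trajectory, 0L, refTable(ref)[1, ])
  expect_equal(ol0$label, "none")
  expect_false(ol0$in_membrane)
})

test_that("the A/B boundary sits exactly at zero reporter projection", {
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  pro <- which(tpl$sequence == "PRO")
  gf <- membraneFixture(n_side = 5L, jitter = 0)
  mem <- gf$trajectory
  z_mid <- frameBox(mem, 0)[3] / 2
  for (eps in c(0.25, 0.01, 1e-7, -1e-7, -0.01, -0.25)) {
    xyz <- tpl$coords
    xyz[tpl$cb_rows[pro], 3] <- eps  # reporter offset along +z (aqueous)
    xyz <- sweep(xyz, 2, c(1.5, 1.5, z_mid + 1.7), "+")  # in-membrane
    atoms <- rbind(tpl$atoms, atomData(mem)[, c("name", "resid", "resname")])
    traj <- mkTraj(atoms, list(rbind(xyz, frameCoords(mem, 0))),
                   box = frameBox(mem, 0))
    refrow <- referenceSurfaces(traj, 0)
    ol <- classifyOrientation(traj, 0, refrow)
    expect_equal(ol$label, if (eps > 0) "B" else "A")
  }
})

test_that("rotation events equal the dwell-filtered run-length oracle", {
  times <- (0:399) * 100
  expect_equal(nrow(detectRotationEvents(rep("A", 400), times)), 0L)
  lab <- c(rep("A", 100), rep("B", 100))
  ev <- detectRotationEvents(lab, (0:199) * 100, dwell = 5L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "rotation_AB")
  expect_equal(ev$start_frame, 100L)
  # flickery series against the oracle
  set.seed(8)
  for (rep in 1:20) {
    lab <- sample(c("A", "B", "none"), 400, TRUE,
                  prob = c(0.45, 0.45, 0.1))
    # inject persistent blocks so some events survive the dwell
    lab[51:120] <- "A"; lab[201:260] <- "B"
    ev <- detectRotationEvents(lab, times, dwell = 5L)
    want <- oracleRotations(lab, 5L)
    expect_equal(paste0(substr(ev$type, 10, 10), substr(ev$type, 11, 11)),
                 want)
  }
})

test_that("orientation fractions are exact percentages that sum to 100", {
  lab <- c(rep("A", 87), rep("B", 13))
  fr <- orientationFractions(lab)
  expect_equal(unname(fr["A"]), 87)
  expect_equal(unname(fr["B"]), 13)
  expect_equal(sum(fr), 100)
  fr2 <- orientationFractions(c(rep("none", 10), rep("B", 30)))
  expect_equal(unname(fr2["A"]), 0)
  expect_equal(unname(fr2["B"]), 100)
  expect_error(orientationFractions(rep("none", 5)), "no labelled")
  # equilibration cut discards the head of the series
  lab3 <- c(rep("A", 50), rep("B", 50))
  expect_equal(unname(orientationFractions(lab3, 50)["B"]), 100)
})

test_that("scripted Markov occupancy is recovered within 2 points at 1e4 frames", {
  lab <- generateOrientationSeries(10000, frac_A = 0.7, seed = 23)
  fr <- orientationFractions(lab)
  expect_lt(abs(fr["A"] - 70), 2)
})

test_that("occupancy heatmap conserves counts and flattens uniform samples", {
  hm1 <- occupancyHeatmap(rep(1.2, 50), rep(45, 50))
  expect_equal(sum(hm1$counts), 50)
  expect_equal(sum(hm1$counts > 0), 1L)
  set.seed(12)
  n <- 40000
  z <- runif(n, -4, 6); th <- runif(n, 0, 180)
  hm <- occupancyHeatmap(z, th)
  expect_equal(sum(hm$counts), n)
  p_cell <- 1 / length(hm$counts)
  expect_lt(max(abs(hm$counts - n * p_cell)),
            6 * sqrt(n * p_cell * (1 - p_cell)))
})

test_that("a scripted rigid roll is recovered by the flip detector within 2 degrees", {
  # build a peptide rolling about its major axis over a static membrane
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  gf <- membraneFixture(n_side = 5L, jitter = 0)
  mem_xyz <- frameCoords(gf$trajectory, 0)
  box <- frameBox(gf$trajectory, 0)
  atoms <- rbind(tpl$atoms,
                 atomData(gf$trajectory)[, c("name", "resid", "resname")])
  for (roll in c(60, 120, 180, 240)) {
    angs <- seq(180, 180 + roll, length.out = 30)
    frames <- lapply(angs, function(a) {
      xyz <- tpl$coords %*% t(permeatrace:::rotX(a))
      xyz <- sweep(xyz, 2, c(1.5, 1.5, box[3] / 2 - 0.5), "+")
      rbind(xyz, mem_xyz)
    })
    traj <- mkTraj(atoms, frames, box = box)
    ref <- membraneReference(traj)
    fl <- detectFlip(traj, 0:29, ref)
    expect_lt(abs(abs(fl$net_rotation_deg) - roll), 2)
    if (roll == 180) expect_true(fl$flip)
    if (roll == 60) expect_false(fl$flip)
  }
})
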