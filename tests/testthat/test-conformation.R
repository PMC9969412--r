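test_that("Kabsch RMSD is zero under rigid motion and matches the bio3d oracle", {
  ref <- closedReferenceBackbone()
  expect_equal(kabschRmsd(ref, ref), 0, tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:100) {
    R <- permeatrace:::rotX(runif(1, 0, 360)) %*%
      permeatrace:::rotZ(runif(1, 0, 360))
    moved <- ref %*% t(R)
    moved <- sweep(moved, 2, rnorm(3, 0, 2), "+")
    expect_lt(kabschRmsd(moved, ref), 1e-9)
    # perturbed pair against the independent superposition oracle
    X <- ref + matrix(rnorm(length(ref), 0, 0.15), ncol = 3)
    Y <- moved
    expect_equal(kabschRmsd(X, Y), oracleRmsd(X, Y), tolerance = 1e-9)
  }
})

test_that("rmsdToClosed requires matching atom counts", {
  traj <- peptideFixture("closed")
  ref <- closedReferenceBackbone()
  expect_equal(rmsdToClosed(traj, 0, ref), 0, tolerance = 1e-9)
  expect_error(rmsdToClosed(traj, 0, ref[-1, ]), "mismatch")
})

test_that("intramolecular H-bonds: closed fixture has the four canonical bonds", {
  traj <- peptideFixture("closed")
  hb <- intraHbonds(traj, 0)
  expect_equal(nrow(hb), 4L)
  expect_setequal(paste(hb$donor_pos, hb$acceptor_pos),
                  c("1 8", "8 1", "3 6", "6 3"))
  expect_true(all(hb$dist_nm <= 0.35))
  expect_true(all(hb$angle_deg >= 150))
  # a fully extended (scaled-up) ring has none
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  stretched <- mkTraj(tpl$atoms, list(tpl$coords * 3 + 5))
  expect_equal(nrow(intraHbonds(stretched, 0)), 0L)
})

test_that("H-bond detection equals the exhaustive pair-scan oracle on random geometries", {
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  set.seed(29)
  for (rep in 1:100) {
    # random compact cloud: some pairs land inside the criterion
    xyz <- tpl$coords + matrix(rnorm(nrow(tpl$coords) * 3, 0, 0.12),
                               ncol = 3)
    traj <- mkTraj(tpl$atoms, list(xyz + 5))
    hb <- intraHbonds(traj, 0)
    N <- xyz[tpl$atoms$name == "N", , drop = FALSE]
    H <- xyz[tpl$atoms$name == "HN", , drop = FALSE]
    O <- xyz[tpl$atoms$name == "O", , drop = FALSE]
    expected <- oracleHbondPairs(N, H, O)
    expect_setequal(paste(hb$donor_pos, hb$acceptor_pos),
                    if (nrow(expected)) paste(expected[, 1], expected[, 2])
                    else character())
  }
})

test_that("conformation label flips exactly at the RMSD threshold", {
  no_hb <- data.frame(donor_pos = integer(), acceptor_pos = integer())
  for (rmsd in c(0.05, 0.1, 0.199999, 0.2)) {
    expect_equal(classifyConformation(rmsd, no_hb)$label, "closed")
  }
  for (rmsd in c(0.2000001, 0.21, 0.35, 1)) {
    expect_equal(classifyConformation(rmsd, no_hb)$label, "open")
  }
  # partial canonical pattern above threshold: half-closed
  part <- data.frame(donor_pos = c(1L, 8L), acceptor_pos = c(8L, 1L))
  expect_equal(classifyConformation(0.35, part)$label, "half_closed")
  full <- data.frame(donor_pos = c(1L, 8L, 3L, 6L),
                     acceptor_pos = c(8L, 1L, 6L, 3L))
  expect_equal(classifyConformation(0.05, full)$label, "closed")
  # non-canonical partial pattern is open, not half-closed
  odd <- data.frame(donor_pos = 2L, acceptor_pos = 7L)
  expect_equal(classifyConformation(0.35, odd)$label, "open")
})

test_that("register shift is an exact offset-by-one match, both directions", {
  canon <- defaultConfig()$hbond_pattern$canonical
  mk <- function(shift) {
    d <- vapply(canon, `[`, integer(1), 1)
    a <- vapply(canon, `[`, integer(1), 2)
    data.frame(donor_pos = ((d - 1L + shift) %% 10L) + 1L,
               acceptor_pos = ((a - 1L + shift) %% 10L) + 1L)
  }
  expect_false(detectRegisterShift(mk(0L)))
  expect_true(detectRegisterShift(mk(1L)))
  expect_true(detectRegisterShift(mk(-1L)))
  expect_false(detectRegisterShift(mk(2L)))
  expect_false(detectRegisterShift(mk(0L)[1:2, ]))  # subset, not shifted set
  expect_false(detectRegisterShift(mk(1L)[1:3, ]))  # incomplete shifted set
  # random patterns against an exhaustive matcher
  set.seed(3)
  for (rep in 1:50) {
    obs <- data.frame(donor_pos = sample(10, 4, TRUE),
                      acceptor_pos = sample(10, 4, TRUE))
    expected <- FALSE
    for (s in c(1L, -1L)) {
      sh <- mk(s)
      expected <- expected ||
        setequal(paste(obs$donor_pos, obs$acceptor_pos),
                 paste(sh$donor_pos, sh$acceptor_pos)) &&
        nrow(unique(obs)) == 4L
    }
    expect_equal(detectRegisterShift(obs), expected)
  }
})

test_that("lock state flips exactly at zero out-of-plane projection", {
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  phe <- which(tpl$sequence == "PHE")
  for (offset5 in c(0.3, 0.05, 1e-6)) {
    for (sgn in c(1, -1)) {
      xyz <- tpl$coords
      # both PHE side chains on the aqueous (up) side, then push PHE5 down
      xyz[tpl$cb_rows[phe], 3] <- 0.3
      xyz[tpl$cb_rows[phe[1]], 3] <- sgn * offset5
      traj <- mkTraj(tpl$atoms, list(xyz + 5))
      st <- lockState(traj, 0, z_center = 0)  # peptide above center
      expect_equal(st$state, if (sgn < 0) "locked" else "unlocked")
    }
  }
  # exactly zero projection counts as aqueous (unlocked)
  xyz <- tpl$coords
  xyz[tpl$cb_rows[phe], 3] <- 0.3
  xyz[tpl$cb_rows[phe[1]], 3] <- 0
  # with CB exactly in-plane its projection is ~0; tie goes to unlocked
  traj <- mkTraj(tpl$atoms, list(xyz + 5))
  st <- lockState(traj, 0, z_center = 0)
  expect_equal(st$state, "unlocked")
  # no configured turn residues: n/a
  expect_equal(lockState(traj, 0, turn_positions = integer(),
                         z_center = 0)$state, "n/a")
  # perpendicular ring: membrane-pointing normal undefined, n/a
  upright <- mkTraj(tpl$atoms,
                    list(tpl$coords %*% t(permeatrace:::rotX(90)) + 5))
  expect_equal(lockState(upright, 0, z_center = 0)$state, "n/a")
})
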