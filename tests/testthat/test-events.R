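test_that("anchoring detection names the scripted residue; null stays silent", {
  spec <- scenarioSpec(list(
    phase("diffuse", 3), phase("approach", 8),
    phase("anchor", 15, residue = 5), phase("retreat", 8),
    phase("stay", 6)), seed = 31, n_side = 5L)
  res <- generateScenario(spec)
  an <- analyzeTrajectory(res$trajectory)
  anch <- evOf(an$events, "anchoring")
  expect_equal(nrow(anch), 1L)
  expect_match(anch$residues, "^PHE5")
  expect_equal(anch$start_frame, 11L)
  expect_match(anch$attributes, "conformation_at_contact")
  # peptide that detaches: no insertion event
  expect_equal(nrow(evOf(an$events, "insertion")), 0L)
  # pure-diffusion null: nothing fires
  nul <- generateNull(80, seed = 8, n_side = 5L)
  expect_equal(nrow(analyzeTrajectory(nul$trajectory)$events), 0L)
})

test_that("peptide-lipid H-bonds are tagged by lipid moiety", {
  # one peptide residue with its amide close to a phosphate bead
  tpl <- permeatrace:::buildPeptideTemplate("closed")
  gf <- membraneFixture(n_side = 4L, jitter = 0)
  mem <- gf$trajectory
  box <- frameBox(mem, 0)
  roles_m <- atomRoles(mem)
  p_atom <- roles_m@phosphate[1]
  p_xyz <- frameCoords(mem, 0)[p_atom, ]
  place <- function(gap_nm) {
    xyz <- tpl$coords
    # put residue 1's N at gap_nm above the phosphate, H in between
    nrow1 <- which(tpl$atoms$name == "N" & tpl$atoms$resid == 1)
    hrow1 <- which(tpl$atoms$name == "HN" & tpl$atoms$resid == 1)
    delta <- p_xyz + c(0, 0, gap_nm) - xyz[nrow1, ]
    xyz <- sweep(xyz, 2, delta, "+")
    xyz[hrow1, ] <- xyz[nrow1, ] - c(0, 0, 0.10)  # N-H points at the P bead
    atoms <- rbind(tpl$atoms, atomData(mem)[, c("name", "resid", "resname")])
    mkTraj(atoms, list(rbind(xyz, frameCoords(mem, 0))), box = box)
  }
  hb <- trackPeptideLipidHbonds(place(0.29), frames = 0L)
  expect_gte(nrow(hb), 1L)
  r1 <- hb[hb$residue == "LEU1", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$moiety, "phosphate")
  expect_equal(r1$dist_nm, 0.29, tolerance = 1e-6)
  # same geometry at 0.5 nm: nothing
  hb2 <- trackPeptideLipidHbonds(place(0.50), frames = 0L)
  expect_equal(nrow(hb2[hb2$residue == "LEU1", ]), 0L)
})

test_that("anchoring precedes insertion and insertion needs persistence", {
  res <- generateScenario(scenarioSpec(list(
    phase("diffuse", 3), phase("approach", 8),
    phase("anchor", 12, residue = 3), phase("insert", 20),
    phase("stay", 20)), seed = 12, n_side = 5L))
  an <- analyzeTrajectory(res$trajectory)
  anch <- evOf(an$events, "anchoring")
  ins <- evOf(an$events, "insertion")
  expect_equal(nrow(ins), 1L)
  expect_lte(anch$start_frame, ins$start_frame)
  truth_ins <- evOf(res$truth$events, "insertion")
  dwell <- 20L  # 2 ns at 100 ps
  expect_lte(abs(ins$start_frame - truth_ins$start_frame), dwell)
})

test_that("conformational events equal the dwell-filtered run-length oracle", {
  set.seed(44)
  for (rep in 1:20) {
    n <- 300
    lab <- sample(c("open", "half_closed", "closed"), n, TRUE)
    # persistent blocks
    lab[21:80] <- "open"; lab[121:200] <- "half_closed"
    lab[221:300] <- "closed"
    desc <- data.frame(frame = 0:(n - 1), time_ps = (0:(n - 1)) * 100,
                       conf_label = lab, lock_state = "n/a",
                       orientation = "none", stringsAsFactors = FALSE)
    ev <- detectConformationEvents(desc, dwell = 10L)
    filt <- permeatrace:::dwellFilterLabels(lab, 10L)
    r <- rle(filt)
    expected_n <- sum(r$values[-1] != r$values[-length(r$values)])
    expect_equal(nrow(ev), expected_n)
  }
  # scripted open -> half-closed -> closed in orientation B
  res <- generateScenario(scenarioSpec(list(
    phase("diffuse", 2), phase("approach", 6),
    phase("anchor", 12, residue = 3), phase("insert", 20),
    phase("orient", 12, orientation = "B"), phase("half_close", 20),
    phase("close", 25), phase("stay", 5)),
    seed = 3, n_side = 5L, start_conformation = "open"))
  an <- analyzeTrajectory(res$trajectory)
  hc <- evOf(an$events, "half_closing")
  cl <- evOf(an$events, "closing")
  expect_equal(nrow(hc), 1L)
  expect_equal(nrow(cl), 1L)
  expect_lt(hc$start_frame, cl$start_frame)
  expect_match(hc$attributes, "\"orientation_at_onset\":\"B\"")
  expect_match(cl$attributes, "\"orientation_at_onset\":\"B\"")
  # a scripted closing in orientation A must still be reported (the
  # orientation-B finding is a property of data, not hard-coded)
  resA <- generateScenario(scenarioSpec(list(
    phase("diffuse", 2), phase("approach", 6),
    phase("anchor", 12, residue = 3), phase("insert", 20),
    phase("orient", 12, orientation = "A"), phase("close", 25),
    phase("stay", 5)), seed = 4, n_side = 5L))
  anA <- analyzeTrajectory(resA$trajectory)
  clA <- evOf(anA$events, "closing")
  expect_equal(nrow(clA), 1L)
  expect_match(clA$attributes, "\"orientation_at_onset\":\"A\"")
})

test_that("crossing classification matches the residence-threshold semantics", {
  base <- list(
    phase("diffuse", 2), phase("approach", 6),
    phase("anchor", 10, residue = 3), phase("insert", 15),
    phase("orient", 10, orientation = "B"), phase("close", 15))
  perm <- generateScenario(scenarioSpec(
    c(base, list(phase("cross", 40, mode = "permanent", flip = TRUE),
                 phase("stay", 10))), seed = 21, n_side = 5L))
  anp <- analyzeTrajectory(perm$trajectory)
  cp <- evOf(anp$events, "crossing_permanent")
  expect_equal(nrow(cp), 1L)
  expect_match(cp$attributes, "\"flip\":true")
  expect_match(cp$attributes, "\"leaflet_to\":\"lower\"")
  expect_equal(nrow(evOf(anp$events, "crossing_transient")), 0L)
  tran <- generateScenario(scenarioSpec(
    c(base, list(phase("cross", 30, mode = "transient"),
                 phase("stay", 10))), seed = 22, n_side = 5L))
  ant <- analyzeTrajectory(tran$trajectory)
  ct <- evOf(ant$events, "crossing_transient")
  expect_equal(nrow(ct), 1L)
  expect_match(ct$attributes, "\"flip\":false")
  expect_equal(nrow(evOf(ant$events, "crossing_permanent")), 0L)
  # 2-frame scripted dip below the center counts as transient
  z <- c(rep(0.8, 30), rep(-0.05, 2), rep(0.8, 30))
  desc <- data.frame(frame = seq_along(z) - 1,
                     time_ps = (seq_along(z) - 1) * 100, z_com = z)
  ref <- membraneReference(perm$trajectory)
  ev <- detectLeafletCrossing(perm$trajectory, ref,
                              cbind(desc, theta_folded = 0), rejoin = 3L)
  expect_equal(ev$type, "crossing_transient")
  expect_equal(ev$start_frame, 30L)
  expect_equal(ev$end_frame, 31L)
})

test_that("anchor probability pools runs and is order-invariant", {
  runs <- data.frame(
    peptide = rep(paste0("pep", 1:7), each = 5),
    pulled_position = 8L, pulled_residue = "LEU",
    start_conformation = "open",
    success = rep(c(TRUE, FALSE), length.out = 35),
    first_anchor_frame = ifelse(rep(c(TRUE, FALSE), length.out = 35), 4L, NA))
  runs$success[runs$success][15:18] <- FALSE  # 14 successes of 35
  runs$first_anchor_frame[!runs$success] <- NA
  tab <- anchorProbability(runs)
  expect_equal(tab$n_runs, 35L)
  expect_equal(tab$n_success, 14L)
  expect_equal(tab$probability, 0.4)
  shuffled <- anchorProbability(runs[sample(nrow(runs)), ])
  expect_equal(shuffled, tab)
  # all-failure cell gives probability zero
  zero <- runs; zero$success <- FALSE; zero$first_anchor_frame <- NA
  expect_equal(anchorProbability(zero)$probability, 0)
  # success without an anchor frame violates the record invariant
  bad <- runs; bad$first_anchor_frame[bad$success][1] <- NA
  expect_error(anchorProbability(bad), "first_anchor_frame")
})

test_that("the timeline merges chronologically and flags inconsistencies", {
  times <- (0:199) * 100
  a <- eventRecord("anchoring", 10, 20, times, residues = "LEU3")
  i <- eventRecord("insertion", 21, 60, times)
  c1 <- eventRecord("closing", 80, 90, times)
  x <- eventRecord("crossing_permanent", 120, 199, times)
  tl <- assembleTimeline(x, c1, a, i, start_conformation = "open")
  expect_equal(tl$timeline$type,
               c("anchoring", "insertion", "closing", "crossing_permanent"))
  expect_true(all(tl$timeline$consistent))
  expect_equal(unname(tl$counts["closing"]), 1L)
  # shuffled input order gives the identical timeline
  tl2 <- assembleTimeline(c1, x, i, a, start_conformation = "open")
  expect_identical(tl2$timeline, tl$timeline)
  # a closing with no insertion at all is flagged, not dropped
  tl3 <- assembleTimeline(c1, a, start_conformation = "open")
  expect_equal(nrow(tl3$timeline), 2L)
  expect_false(tl3$timeline$consistent[tl3$timeline$type == "closing"])
  # empty input: empty timeline
  expect_equal(nrow(assembleTimeline()$timeline), 0L)
})
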