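test_that("an intact headgroup lattice shows zero gaps", {
  gf <- membraneFixture(n_side = 8L, jitter = 0)
  gm <- scanGaps(gf$trajectory, 0, "upper")
  expect_equal(nrow(gapTable(gm)), 0L)
  expect_true(all(gm@grid %in% c(0L, 1L)))
  gml <- scanGaps(gf$trajectory, 0, "lower")
  expect_equal(nrow(gapTable(gml)), 0L)
})

test_that("one removed headgroup opens one gap matching the flood-fill oracle", {
  res <- generateScenario(scenarioSpec(
    list(phase("diffuse", 2)), seed = 3, n_side = 8L, membrane_jitter = 0,
    gap_schedule = list(list(frames = c(0, 1), sites = 28))))
  gm <- scanGaps(res$trajectory, 0, "upper")
  tb <- gapTable(gm)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$area_nm2, tb$n_cells * gm@cell^2)
  # area close to the tail-bead footprint, and side-chain accessible
  expect_gt(tb$area_nm2, 0.3)
  expect_lt(tb$area_nm2, 0.6)
  expect_true(gapAccessibility(tb$area_nm2))
  # component structure equals the igraph oracle
  expect_equal(sort(tb$n_cells), oracleComponents(gm@grid == 2L))
})

test_that("gaps merge across the periodic x-boundary into one component", {
  # lattice sites 1 and 8 share a row and are adjacent across x wrap
  res <- generateScenario(scenarioSpec(
    list(phase("diffuse", 1)), seed = 3, n_side = 8L, membrane_jitter = 0,
    gap_schedule = list(list(frames = c(0, 0), sites = c(1, 8)))))
  gm <- scanGaps(res$trajectory, 0, "upper")
  expect_equal(nrow(gapTable(gm)), 1L)
  expect_gt(gapTable(gm)$area_nm2, 0.6)  # two merged footprints
})

test_that("connected components equal the flood-fill oracle on random grids", {
  set.seed(77)
  for (rep in 1:100) {
    nx <- sample(8:64, 1); ny <- sample(8:64, 1)
    mask <- matrix(runif(nx * ny) < runif(1, 0.1, 0.6), nx, ny)
    lab <- permeatrace:::periodicComponents(mask)
    expect_equal(sort(as.integer(table(lab[lab > 0]))),
                 oracleComponents(mask))
    # labelled cells are exactly the masked cells
    expect_identical(lab > 0, mask)
  }
})

test_that("gap maps are invariant under whole-cell periodic translations", {
  res <- generateScenario(scenarioSpec(
    list(phase("diffuse", 1)), seed = 6, n_side = 8L, membrane_jitter = 0.02,
    gap_schedule = list(list(frames = c(0, 0), sites = c(5, 13, 40)))))
  traj <- res$trajectory
  gm <- scanGaps(traj, 0, "upper")
  box <- frameBox(traj, 0)
  nx <- nrow(gm@grid)
  cellx <- box[1] / nx
  for (k in c(3L, 17L)) {
    shifted <- traj
    shifted@coords[, 1, ] <- (shifted@coords[, 1, ] + k * cellx) %% box[1]
    gs <- scanGaps(shifted, 0, "upper")
    expect_equal(sort(gapTable(gs)$area_nm2), sort(gapTable(gm)$area_nm2))
    # the grid itself is the circularly shifted original
    expect_equal(gs@grid, gm@grid[((seq_len(nx) - 1L - k) %% nx) + 1L, ])
  }
})

test_that("gap accessibility threshold semantics", {
  expect_true(gapAccessibility(0.25, 0.23))
  expect_false(gapAccessibility(0.10, 0.23))
  expect_true(gapAccessibility(0.23, 0.23))   # >= convention at the boundary
  expect_false(gapAccessibility(0.2299999, 0.23))
})

test_that("gap lifetimes follow the scripted schedule", {
  # gap present frames 2-4 (10 ps stride): lifetime 20 ps; then a second,
  # separate appearance at frames 7-8
  res <- generateScenario(scenarioSpec(
    list(phase("diffuse", 10)), seed = 2, n_side = 6L, membrane_jitter = 0,
    dt_ps = 10,
    gap_schedule = list(list(frames = c(2, 4), sites = 15),
                        list(frames = c(7, 8), sites = 15))))
  maps <- lapply(0:9, function(f) scanGaps(res$trajectory, f, "upper"))
  tr <- gapLifetimes(maps, stride_ps = 10)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$first_frame, c(2L, 7L))
  expect_equal(tr$lifetime_ps, c(20, 10))
})

test_that("gap-size distribution: point mass, max conservation, exponential fit", {
  res <- generateScenario(scenarioSpec(
    list(phase("diffuse", 5)), seed = 2, n_side = 6L, membrane_jitter = 0,
    gap_schedule = list(list(frames = c(0, 4), sites = 15))))
  maps <- lapply(0:4, function(f) scanGaps(res$trajectory, f, "upper"))
  d <- gapSizeDistribution(maps)
  expect_length(unique(d$areas), 1L)   # same gap every frame: point mass
  expect_equal(d$max_area, max(vapply(maps, function(g)
    max(gapTable(g)$area_nm2), numeric(1))))
  expect_equal(sum(d$prob), 1)
  # Poisson-removed surfaces: probability falls off with area
  gfp <- generateGapFrames(n_frames = 40, removal_prob = 0.06,
                           n_side = 8L, membrane_jitter = 0, seed = 19)
  ref <- membraneReference(gfp$trajectory)
  pmaps <- lapply(0:39, function(f)
    scanGaps(gfp$trajectory, f, "upper", ref))
  dp <- gapSizeDistribution(pmaps)
  expect_gt(length(dp$areas), 30)
  expect_true(is.finite(dp$decay_constant))
  expect_gt(dp$decay_constant, 0)
  # no gaps at all: empty histogram, fit skipped
  gf0 <- membraneFixture(n_side = 4L, jitter = 0)
  d0 <- gapSizeDistribution(list(scanGaps(gf0$trajectory, 0, "upper")))
  expect_length(d0$areas, 0L)
  expect_true(is.na(d0$decay_constant))
})
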