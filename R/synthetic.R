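# Seeded synthetic trajectory generator with scripted ground truth.
#
# The generator emulates the statistical and kinematic structure the
# analysis assumes: a planar two-leaflet bilayer of pseudo-lipids (one
# choline-nitrogen bead, one phosphate bead, two ester-succeeding carbon
# beads, two tail beads per lipid) with thermal jitter and a schedule of
# buriable headgroups that opens packing gaps; and a 10-residue cyclic
# peptide (4 backbone beads + 1 side-chain bead per residue) moved rigidly
# through scripted kinematic phases with additive Gaussian noise. Closed
# phases are built with the four canonical cross-ring hydrogen-bond
# contacts, open phases without; orientation changes are realized as rolls
# about the major axis; crossings translate the center of mass across the
# bilayer center with an optional 180-degree roll (flip).

PEPTIDE_SEQ_DEFAULT <- c("LEU", "ALA", "LEU", "PRO", "PHE",
                         "LEU", "ALA", "LEU", "PRO", "PHE")

# membrane geometry constants (nm, relative to the bilayer center)
MEM_Z <- list(head = 2.0, phos = 1.85, ester = 1.5, tail1 = 1.1, tail2 = 0.7)

rotX <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}
rotZ <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

## ---- peptide templates ----------------------------------------------------

CANONICAL_PAIRS <- list(c(1L, 8L), c(8L, 1L), c(3L, 6L), c(6L, 3L))

# backbone + side-chain template for one conformer, ring in the xy plane,
# major axis along x. Returns list(atoms, coords) with 5 atoms per residue
# (N, HN, CA, O, CB) and 0-based template metadata.
buildPeptideTemplate <- function(conformer = c("closed", "open",
                                               "half_closed", "open_shifted"),
                                 sequence = PEPTIDE_SEQ_DEFAULT,
                                 a = 0.65, b = 0.45) {
  conformer <- match.arg(conformer)
  n <- length(sequence)
  phi <- 2 * pi * ((1:n) - 0.5) / n
  CA <- cbind(a * cos(phi), b * sin(phi), 0)
  # open-state deformation is tangential (in the ring plane) so the ring
  # normal from the backbone-ellipse fit stays well defined
  tang <- cbind(-a * sin(phi), b * cos(phi), 0)
  tang <- tang / sqrt(rowSums(tang^2))
  if (conformer == "open") CA <- CA + 0.50 * cos(2 * phi + 0.7) * tang
  if (conformer == "half_closed") CA <- CA + 0.35 * cos(2 * phi + 0.7) * tang
  if (conformer == "open_shifted") CA <- CA[c(2:n, 1L), ]
  pairs <- switch(conformer,
                  closed = CANONICAL_PAIRS,
                  half_closed = CANONICAL_PAIRS[1:2],
                  open = list(),
                  open_shifted = lapply(CANONICAL_PAIRS, function(p)
                    ((p - 1L + 1L) %% n) + 1L))
  N <- O <- H <- matrix(NA_real_, n, 3)
  for (p in pairs) {
    d <- p[1]; acp <- p[2]
    m <- (CA[d, ] + CA[acp, ]) / 2
    u <- CA[acp, ] - CA[d, ]; u <- u / sqrt(sum(u^2))
    w <- c(-u[2], u[1], 0); w <- w / sqrt(sum(w^2))
    s <- if (d < acp) 0.08 else -0.08
    N[d, ] <- m - 0.145 * u + s * w
    H[d, ] <- N[d, ] + 0.10 * u
    O[acp, ] <- m + 0.145 * u + s * w
  }
  for (i in 1:n) {
    if (anyNA(N[i, ])) {
      N[i, ] <- c(0.72 * CA[i, 1:2], CA[i, 3] + 0.15)
      H[i, ] <- c(0.66 * CA[i, 1:2], CA[i, 3] + 0.25)
    }
    if (anyNA(O[i, ])) O[i, ] <- c(0.72 * CA[i, 1:2], CA[i, 3] - 0.15)
  }
  CB <- cbind(1.25 * CA[, 1:2], CA[, 3])
  rep_pos <- which(sequence == "PRO")
  CB[rep_pos, ] <- cbind(1.10 * CA[rep_pos, 1:2, drop = FALSE],
                         CA[rep_pos, 3] - 0.20)
  atoms <- data.frame(
    name = rep(c("N", "HN", "CA", "O", "CB"), n),
    resid = rep(1:n, each = 5L),
    resname = rep(sequence, each = 5L),
    stringsAsFactors = FALSE)
  coords <- matrix(NA_real_, 5L * n, 3)
  for (i in 1:n) {
    coords[(i - 1L) * 5L + 1:5, ] <- rbind(N[i, ], H[i, ], CA[i, ],
                                           O[i, ], CB[i, ])
  }
  list(atoms = atoms, coords = coords, sequence = sequence,
       phi = phi, ca_rows = (0:(n - 1L)) * 5L + 3L,
       cb_rows = (0:(n - 1L)) * 5L + 5L)
}

#' Closed-conformation reference backbone
#'
#' Backbone coordinates (template frame) of the closed conformer, in the
#' atom order the generator and the selection rules produce, for use as the
#' \code{reference} of \code{\link{rmsdToClosed}}.
#'
#' @param sequence residue names (length 10 by default).
#' @return \code{[n_backbone, 3]} matrix, nm.
#' @export
closedReferenceBackbone <- function(sequence = PEPTIDE_SEQ_DEFAULT) {
  tpl <- buildPeptideTemplate("closed", sequence)
  bb <- tpl$atoms$name %in% c("N", "HN", "CA", "O")
  tpl$coords[bb, , drop = FALSE]
}

## ---- membrane -------------------------------------------------------------

# static pseudo-bilayer: n_side x n_side lipids per leaflet on a square
# lattice with the given area per lipid. Returns atom table, base
# coordinates (relative to bilayer center), lattice site centers and ids.
buildMembrane <- function(n_side = 8L, apl = 0.65, first_resid = 11L) {
  d <- sqrt(apl)
  box_xy <- n_side * d
  xy <- expand.grid(x = (seq_len(n_side) - 0.5) * d,
                    y = (seq_len(n_side) - 0.5) * d)
  n_lip <- nrow(xy)
  mk <- function(leaf_sign, resid0) {
    atoms <- coords <- list()
    for (i in seq_len(n_lip)) {
      z <- leaf_sign * c(MEM_Z$head, MEM_Z$phos, MEM_Z$ester, MEM_Z$ester,
                         MEM_Z$tail1, MEM_Z$tail2)
      dx <- c(0, 0, -0.1, 0.1, 0, 0)
      atoms[[i]] <- data.frame(
        name = c("NC3", "P", "EST1", "EST2", "T1", "T2"),
        resid = resid0 + i - 1L, resname = "PLIP",
        stringsAsFactors = FALSE)
      coords[[i]] <- cbind(xy$x[i] + dx, xy$y[i], z)
    }
    list(atoms = do.call(rbind, atoms), coords = do.call(rbind, coords))
  }
  up <- mk(1, first_resid)
  lo <- mk(-1, first_resid + n_lip)
  list(atoms = rbind(up$atoms, lo$atoms),
       coords = rbind(up$coords, lo$coords),
       sites = xy, box_xy = box_xy,
       upper_resids = first_resid:(first_resid + n_lip - 1L),
       lower_resids = (first_resid + n_lip):(first_resid + 2L * n_lip - 1L))
}

## ---- scenario specification ----------------------------------------------

#' Create a scripted kinematic phase
#'
#' @param type one of \code{"diffuse"}, \code{"approach"}, \code{"anchor"},
#'   \code{"insert"}, \code{"orient"}, \code{"lock"}, \code{"unlock"},
#'   \code{"half_close"}, \code{"close"}, \code{"open"}, \code{"cross"},
#'   \code{"stay"}, \code{"retreat"}.
#' @param duration phase length in frames (> 0).
#' @param ... phase parameters: \code{residue} (anchor position, integer)
#'   for \code{anchor}; \code{orientation} (\code{"A"}/\code{"B"}) for
#'   \code{orient}; \code{mode} (\code{"permanent"}/\code{"transient"}) and
#'   \code{flip} (logical) for \code{cross}.
#' @return a phase list.
#' @export
phase <- function(type, duration, ...) {
  stopifnot(duration > 0)
  c(list(type = type, duration = as.integer(duration)), list(...))
}

#' Specify a synthetic permeation scenario
#'
#' @param phases ordered list of \code{\link{phase}} objects.
#' @param seed integer RNG seed; a fixed seed gives bitwise-reproducible
#'   output.
#' @param n_side lipids per leaflet edge (lipids per leaflet =
#'   \code{n_side^2}).
#' @param membrane_jitter thermal jitter s.d. of the lipid beads, nm.
#' @param noise Gaussian positional noise s.d. of the peptide beads, nm.
#' @param dt_ps frame stride, ps.
#' @param start_conformation \code{"open"} or \code{"closed"}.
#' @param sequence peptide residue names (10 positions).
#' @param gap_schedule list of \code{list(frames = c(from, to), sites =
#'   ids)} headgroup removals (0-based frames, upper-leaflet lattice site
#'   ids); removed headgroup and phosphate beads are buried below the
#'   interfacial slab.
#' @param stiffness scales jitter and scheduled gap frequency down (> 1
#'   emulates a stiffer, e.g. cholesterol-containing, membrane).
#' @return a scenario spec list for \code{\link{generateScenario}}.
#' @export
scenarioSpec <- function(phases, seed = 1L, n_side = 8L,
                         membrane_jitter = 0.02, noise = 0.02,
                         dt_ps = 100, start_conformation = "open",
                         sequence = PEPTIDE_SEQ_DEFAULT,
                         gap_schedule = list(), stiffness = 1) {
  stopifnot(length(phases) >= 1L, stiffness > 0)
  seen <- character()
  for (p in phases) {
    needs <- switch(p$type,
                    insert = "anchor",
                    orient = , lock = , unlock = , half_close = ,
                    close = , open = , cross = "insert",
                    NULL)
    if (!is.null(needs) && !needs %in% seen)
      stop(sprintf("invalid phase order: '%s' before any '%s' phase",
                   p$type, needs))
    seen <- c(seen, p$type)
  }
  list(phases = phases, seed = as.integer(seed), n_side = as.integer(n_side),
       membrane_jitter = membrane_jitter / stiffness, noise = noise,
       dt_ps = dt_ps, start_conformation = start_conformation,
       sequence = sequence, gap_schedule = gap_schedule,
       stiffness = stiffness)
}

# per-frame script: deterministic kinematic state for every frame
scriptFrames <- function(spec) {
  z_high <- MEM_Z$head + 3.0
  st <- list(z = z_high, ang = 90, conformer = spec$start_conformation,
             lock = "unlocked", anchor_res = NA_integer_,
             anchor_ext = FALSE, reach_down = FALSE)
  rows <- list()
  truth <- list()
  f0 <- 0L
  for (p in spec$phases) {
    dur <- p$duration
    fr <- f0:(f0 + dur - 1L)
    seg <- data.frame(frame = fr, z = st$z, ang = st$ang,
                      conformer = st$conformer, lock = st$lock,
                      anchor_res = st$anchor_res, anchor_ext = st$anchor_ext,
                      reach_down = FALSE, stringsAsFactors = FALSE)
    tr <- NULL
    switch(p$type,
      diffuse = , stay = NULL,
      approach = { seg$z <- seq(st$z, 2.6, length.out = dur) },
      retreat = {
        seg$z <- seq(st$z, z_high, length.out = dur)
        seg$anchor_res <- NA_integer_
        seg$anchor_ext <- FALSE
      },
      anchor = {
        seg$z <- 2.2
        seg$anchor_res <- p$residue
        seg$anchor_ext <- TRUE
        tr <- list(type = "anchoring", start = fr[1], end = fr[dur],
                   residue = p$residue)
      },
      insert = {
        seg$z <- seq(2.2, 1.75, length.out = dur)
        onset <- fr[which(seg$z < MEM_Z$head)[1]]
        tr <- list(type = "insertion", start = onset, end = fr[dur])
      },
      orient = {
        target <- if (identical(p$orientation, "B")) 180 else 0
        seg$ang <- seq(st$ang, target, length.out = dur)
        seg$anchor_ext <- FALSE
        if (st$ang %in% c(0, 180) && target != st$ang)
          tr <- list(type = paste0("rotation_",
                                   if (st$ang == 0) "AB" else "BA"),
                     start = fr[1], end = fr[dur])
      },
      lock = { seg$lock <- "locked" },
      unlock = { seg$lock <- "unlocked" },
      half_close = {
        seg$conformer <- "half_closed"
        tr <- list(type = "half_closing", start = fr[1], end = fr[dur])
      },
      close = {
        seg$conformer <- "closed"
        tr <- list(type = "closing", start = fr[1], end = fr[dur])
      },
      open = {
        seg$conformer <- "open"
        tr <- list(type = "opening", start = fr[1], end = fr[dur])
      },
      cross = {
        flip <- isTRUE(p$flip)
        if (identical(p$mode, "transient")) {
          k <- max(3L, dur %/% 3L)
          hold <- dur - 2L * k
          seg$z <- c(seq(st$z, -0.3, length.out = k),
                     rep(-0.3, hold),
                     seq(-0.3, st$z, length.out = k))
        } else {
          seg$z <- seq(st$z, -1.75, length.out = dur)
          if (flip) {
            # the roll happens while passing the membrane center
            q <- dur %/% 4L
            mid <- dur - 2L * q
            seg$ang <- c(rep(st$ang, q),
                         seq(st$ang, st$ang + 180, length.out = mid),
                         rep(st$ang + 180, q))
          }
        }
        seg$reach_down <- seg$z > -0.8   # anchor reaches into the far leaflet
        below <- which(seg$z < 0)
        tr <- list(type = if (identical(p$mode, "transient"))
                     "crossing_transient" else "crossing_permanent",
                   start = fr[below[1]], end = fr[below[length(below)]],
                   flip = flip)
      },
      stop("unknown phase type: ", p$type))
    rows[[length(rows) + 1L]] <- seg
    if (!is.null(tr)) truth[[length(truth) + 1L]] <- tr
    last <- seg[dur, ]
    st$z <- last$z; st$ang <- last$ang; st$conformer <- last$conformer
    st$lock <- last$lock
    if (!is.na(last$anchor_res)) st$anchor_res <- last$anchor_res
    st$anchor_ext <- last$anchor_ext
    f0 <- f0 + dur
  }
  list(script = do.call(rbind, rows), truth = truth)
}

# true orientation label implied by the script
scriptOrientationLabel <- function(z, ang) {
  a <- ang %% 360
  # 5-degree margin inside the classifier's 30-degree parallel gate, so
  # scripted truth never sits on the decision boundary
  parallel_A <- (a <= 25) || (a >= 335)
  parallel_B <- (a >= 155 && a <= 205)
  if (z >= MEM_Z$head - 0.1 || z <= -MEM_Z$head + 0.1 ||
      (!parallel_A && !parallel_B))
    return("none")
  upper <- z >= 0
  if (parallel_B) { if (upper) "B" else "A" }
  else { if (upper) "A" else "B" }
}

#' Generate a ground-truth-annotated synthetic trajectory
#'
#' Builds the pseudo-bilayer and drives the cyclic peptide through the
#' scripted phases of a \code{\link{scenarioSpec}}, with seeded Gaussian
#' jitter on all beads. The returned ground truth lists the scripted
#' events and the per-frame true conformation, orientation and lock
#' labels.
#'
#' @param spec a scenario spec from \code{\link{scenarioSpec}}.
#' @return list: \code{trajectory} (a \linkS4class{Trajectory}),
#'   \code{truth} with \code{events} (event data.frame), \code{labels}
#'   (per-frame data.frame) and \code{script} (the noiseless kinematic
#'   script).
#' @export
generateScenario <- function(spec) {
  set.seed(spec$seed)
  sc <- scriptFrames(spec)
  script <- sc$script
  nfr <- nrow(script)
  times <- (seq_len(nfr) - 1L) * spec$dt_ps

  mem <- buildMembrane(spec$n_side)
  templates <- lapply(
    stats::setNames(nm = c("closed", "open", "half_closed", "open_shifted")),
    buildPeptideTemplate, sequence = spec$sequence)
  tpl0 <- templates[[1]]
  pep_atoms <- tpl0$atoms
  atoms <- rbind(pep_atoms, mem$atoms)
  n_pep <- nrow(pep_atoms)
  box <- c(mem$box_xy, mem$box_xy, 2 * (MEM_Z$head + 2.0))
  z_mid <- box[3] / 2

  # lattice site under the box center: anchor target
  ctr <- c(mem$box_xy / 2, mem$box_xy / 2)
  site_id <- which.min((mem$sites$x - ctr[1])^2 + (mem$sites$y - ctr[2])^2)
  site_xy <- c(mem$sites$x[site_id], mem$sites$y[site_id])

  phe_pos <- which(spec$sequence == "PHE")
  seq_n <- length(spec$sequence)

  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nfr))
  labels <- data.frame(frame = script$frame,
                       conformation = script$conformer,
                       orientation = NA_character_,
                       lock = NA_character_,
                       z_true = script$z, ang_true = script$ang,
                       stringsAsFactors = FALSE)

  # gap schedule (site ids are upper-leaflet lattice indices); the anchor
  # site is opened for the duration of anchoring
  buried_at <- function(f) {
    out <- integer()
    for (g in spec$gap_schedule) {
      if (f >= g$frames[1] && f <= g$frames[2]) out <- c(out, g$sites)
    }
    anch <- script$anchor_ext[f + 1L]
    if (isTRUE(anch)) out <- c(out, site_id)
    unique(out)
  }

  for (k in seq_len(nfr)) {
    s <- script[k, ]
    # membrane with jitter and scheduled burials
    mc <- mem$coords +
      matrix(stats::rnorm(length(mem$coords), 0, spec$membrane_jitter),
             ncol = 3)
    bur <- buried_at(s$frame)
    if (length(bur)) {
      res_bur <- mem$upper_resids[bur]
      hit <- mem$atoms$resid %in% res_bur &
        mem$atoms$name %in% c("NC3", "P", "EST1", "EST2")
      mc[hit, 3] <- mc[hit, 3] - 1.2
    }
    # peptide: template -> spin (anchor residue to template -y) -> tilt/roll
    tpl <- templates[[s$conformer]]
    anchor <- if (is.na(s$anchor_res)) 3L else s$anchor_res
    yaw <- -90 - tpl0$phi[anchor] * 180 / pi
    # roll/tilt in the template frame (about the ring's own major axis),
    # then the spin that puts the anchor residue at the ring bottom
    R <- rotZ(yaw) %*% rotX(s$ang)
    pc <- tpl$coords %*% t(R)
    pc[, 1] <- pc[, 1] + site_xy[1]
    pc[, 2] <- pc[, 2] + site_xy[2]
    pc[, 3] <- pc[, 3] + s$z
    # phenylalanine lock side chains: offset from the ring plane along the
    # world z axis (their in-plane anchor point is the CA projected onto
    # the ring plane, so the saddle of the open conformer does not leak in)
    aq <- if (s$z >= 0) 1 else -1
    for (j in seq_along(phe_pos)) {
      p5 <- j == 1L  # the first PHE position plays the lock in scripts
      side <- if (identical(s$lock, "locked") && p5) -aq else aq
      row <- tpl0$cb_rows[phe_pos[j]]
      ca_row <- tpl0$ca_rows[phe_pos[j]]
      ca_ip <- R %*% c(tpl$coords[ca_row, 1], tpl$coords[ca_row, 2], 0)
      pc[row, ] <- c(ca_ip[1] + site_xy[1], ca_ip[2] + site_xy[2],
                     ca_ip[3] + s$z + 0.3 * side)
    }
    # anchor side chain reaching down (anchoring/insertion, or into the
    # far leaflet during a crossing)
    if (isTRUE(s$anchor_ext)) {
      # anchor bead dips through the headgroup gap onto the exposed tails
      row <- tpl0$cb_rows[anchor]
      pc[row, ] <- c(site_xy[1], site_xy[2], MEM_Z$tail1 + 0.25)
    } else if (isTRUE(s$reach_down)) {
      # the far-leaflet reach uses a strand leucine when the scripted
      # anchor is a turn phenylalanine, so the lock descriptor (defined by
      # the turn side chains) is not entangled with the crossing anchor
      reach_res <- if (anchor %in% phe_pos) {
        which(spec$sequence == "LEU")[1]
      } else anchor
      row <- tpl0$cb_rows[reach_res]
      ca_row <- tpl0$ca_rows[reach_res]
      pc[row, ] <- pc[ca_row, ] + c(0, 0, -0.8)
    }
    # noise: rigid-body displacement of the whole peptide (dominant, as
    # thermal motion of bonded atoms is strongly correlated) plus a small
    # uncorrelated per-atom component
    pc <- sweep(pc, 2, stats::rnorm(3, 0, spec$noise), "+")
    pc <- pc + matrix(stats::rnorm(length(pc), 0, spec$noise / 5), ncol = 3)
    arr[, , k] <- rbind(pc, mc)
    arr[, 3, k] <- arr[, 3, k] + z_mid
    labels$orientation[k] <- scriptOrientationLabel(s$z, s$ang)
    a_mod <- s$ang %% 360
    parallel <- a_mod <= 25 || a_mod >= 335 || (a_mod >= 155 && a_mod <= 205)
    labels$lock[k] <- if (length(phe_pos)) {
      if (parallel) s$lock else "n/a"
    } else "n/a"
  }

  roles <- resolveRoles(atoms, defaultConfig())
  atoms$mass <- guessMass(atoms$name)
  seg <- rep("lipid", nrow(atoms))
  seg[seq_len(n_pep)] <- "peptide"
  atoms$segment <- seg
  traj <- new("Trajectory", coords = arr,
              box = matrix(rep(box, each = nfr), nfr, 3),
              times = times, atoms = atoms, roles = roles)

  ev <- emptyEvents()
  for (tr in sc$truth) {
    ev <- rbind(ev, eventRecord(
      tr$type, tr$start, tr$end, times,
      residues = if (!is.null(tr$residue))
        paste0(spec$sequence[tr$residue], tr$residue) else character(),
      attributes = list(flip = isTRUE(tr$flip))))
  }
  # lock-release ground truth is derived from the per-frame lock labels,
  # which account for phenylalanine anchors acting as locks
  ll <- labels$lock
  for (k in seq_len(nfr)[-1]) {
    if (identical(ll[k - 1], "locked") && identical(ll[k], "unlocked"))
      ev <- rbind(ev, eventRecord("lock_release", k - 1L,
                                  min(k + 8L, nfr - 1L), times))
  }
  if (nrow(ev)) ev <- ev[order(ev$start_frame), , drop = FALSE]
  rownames(ev) <- NULL
  list(trajectory = traj,
       truth = list(events = ev, labels = labels, script = script,
                    anchor_site = site_id))
}

#' Generate a null (no-contact) trajectory
#'
#' The peptide diffuses at least 2.5 nm above the upper headgroup surface
#' for the whole trajectory; the ground truth contains no events.
#'
#' @param duration number of frames.
#' @param seed RNG seed.
#' @param ... further arguments to \code{\link{scenarioSpec}}.
#' @return as \code{\link{generateScenario}}, with an empty event table.
#' @export
generateNull <- function(duration = 100L, seed = 1L, ...) {
  spec <- scenarioSpec(list(phase("diffuse", duration)), seed = seed, ...)
  generateScenario(spec)
}

#' Canonical four-step permeation scenario
#'
#' Anchoring, insertion with rotation into orientation B, in-membrane
#' closing, and permanent leaflet crossing with flip — the full permeation
#' pathway in one scripted trajectory.
#'
#' @param seed RNG seed.
#' @param anchor_residue ring position of the anchoring side chain.
#' @param ... further arguments to \code{\link{scenarioSpec}}.
#' @return a scenario spec.
#' @export
fourStepScenario <- function(seed = 1L, anchor_residue = 3L, ...) {
  scenarioSpec(list(
    phase("diffuse", 10), phase("approach", 15),
    phase("anchor", 15, residue = anchor_residue),
    phase("insert", 25), phase("orient", 20, orientation = "B"),
    phase("stay", 5), phase("close", 30),
    phase("cross", 40, mode = "permanent", flip = TRUE),
    phase("stay", 15)),
    seed = seed, start_conformation = "open", ...)
}

## ---- pulling ensembles ----------------------------------------------------

#' Generate a pulling-run ensemble with known anchor probabilities
#'
#' Draws a Bernoulli success flag per run from the per-position probability
#' and scripts each run accordingly: successful runs anchor and stay
#' anchored to the end of the run; failed runs approach, make only a brief
#' (sub-dwell) contact and retreat.
#'
#' @param p_success named numeric vector: ring position (as character) ->
#'   anchoring success probability.
#' @param n_per_position runs per position.
#' @param peptides peptide ids to cycle over (pooling dimension).
#' @param start_conformation \code{"open"} or \code{"closed"}.
#' @param seed RNG seed.
#' @param n_side lipids per leaflet edge for the mini-membranes.
#' @return list: \code{runs} (per-run spec list), \code{truth} (data.frame
#'   of scripted successes).
#' @export
generatePullingEnsemble <- function(p_success, n_per_position = 25L,
                                    peptides = paste0("pep", 1:5),
                                    start_conformation = "open",
                                    seed = 1L, n_side = 5L) {
  stopifnot(all(p_success >= 0 & p_success <= 1))
  set.seed(seed)
  runs <- list(); rows <- list()
  sequence <- PEPTIDE_SEQ_DEFAULT
  run_id <- 0L
  for (pos_chr in names(p_success)) {
    pos <- as.integer(pos_chr)
    p <- p_success[[pos_chr]]
    for (i in seq_len(n_per_position)) {
      run_id <- run_id + 1L
      success <- stats::runif(1) < p
      runs[[run_id]] <- list(
        run_id = run_id, peptide = peptides[(i - 1L) %% length(peptides) + 1L],
        pulled_position = pos, pulled_residue = sequence[pos],
        start_conformation = start_conformation,
        success = success, seed = seed * 10000L + run_id,
        n_side = n_side)
      rows[[run_id]] <- data.frame(
        run_id = run_id, pulled_position = pos,
        pulled_residue = sequence[pos], success = success)
    }
  }
  list(runs = runs, truth = do.call(rbind, rows))
}

# build the mini-trajectory for one pulling run
generatePullingRun <- function(run) {
  phases <- if (run$success) {
    list(phase("diffuse", 3), phase("approach", 8),
         phase("anchor", 30, residue = run$pulled_position))
  } else {
    list(phase("diffuse", 3), phase("approach", 8),
         phase("anchor", 3, residue = run$pulled_position),
         phase("retreat", 10), phase("stay", 17))
  }
  spec <- scenarioSpec(phases, seed = run$seed, n_side = run$n_side,
                       start_conformation = run$start_conformation)
  generateScenario(spec)$trajectory
}

## ---- label series and gap surfaces ----------------------------------------

#' Markov orientation-label series with known occupancy
#'
#' Two-state (A/B) Markov chain with switching probabilities chosen so the
#' stationary fraction of A equals \code{frac_A}.
#'
#' @param n_frames series length.
#' @param frac_A stationary fraction of orientation A (0-1).
#' @param switch_scale overall switching rate scale (0-1).
#' @param seed RNG seed.
#' @return character vector of labels \code{"A"}/\code{"B"}.
#' @export
generateOrientationSeries <- function(n_frames, frac_A = 0.7,
                                      switch_scale = 0.1, seed = 1L) {
  set.seed(seed)
  p_ab <- switch_scale * (1 - frac_A)
  p_ba <- switch_scale * frac_A
  out <- character(n_frames)
  cur <- if (stats::runif(1) < frac_A) "A" else "B"
  for (i in seq_len(n_frames)) {
    out[i] <- cur
    p <- if (cur == "A") p_ab else p_ba
    if (stats::runif(1) < p) cur <- if (cur == "A") "B" else "A"
  }
  out
}

#' Generate membrane-only frames with Poisson headgroup removals
#'
#' Builds a peptide-free bilayer trajectory in which every upper-leaflet
#' headgroup is independently buried with probability
#' \code{removal_prob / stiffness} per frame, opening packing gaps.
#'
#' @param n_frames number of frames.
#' @param removal_prob per-lipid, per-frame removal probability.
#' @param n_side lipids per leaflet edge.
#' @param membrane_jitter bead jitter s.d., nm.
#' @param stiffness gap-suppression factor (> 1 = stiffer membrane).
#' @param seed RNG seed.
#' @return list: \code{trajectory}, \code{removed} (list of per-frame
#'   removed site-id vectors).
#' @export
generateGapFrames <- function(n_frames = 50L, removal_prob = 0.05,
                              n_side = 8L, membrane_jitter = 0.02,
                              stiffness = 1, seed = 1L) {
  set.seed(seed)
  mem <- buildMembrane(n_side, first_resid = 1L)
  n_lip <- nrow(mem$sites)
  box <- c(mem$box_xy, mem$box_xy, 2 * (MEM_Z$head + 2.0))
  z_mid <- box[3] / 2
  arr <- array(NA_real_, dim = c(nrow(mem$atoms), 3, n_frames))
  removed <- vector("list", n_frames)
  p_eff <- removal_prob / stiffness
  for (k in seq_len(n_frames)) {
    mc <- mem$coords +
      matrix(stats::rnorm(length(mem$coords), 0, membrane_jitter), ncol = 3)
    rem <- which(stats::runif(n_lip) < p_eff)
    if (length(rem)) {
      res_rem <- mem$upper_resids[rem]
      hit <- mem$atoms$resid %in% res_rem &
      mem$atoms$name %in% c("NC3", "P", "EST1", "EST2")
      mc[hit, 3] <- mc[hit, 3] - 1.2
    }
    removed[[k]] <- rem
    arr[, , k] <- mc
    arr[, 3, k] <- arr[, 3, k] + z_mid
  }
  atoms <- mem$atoms
  atoms$mass <- guessMass(atoms$name)
  atoms$segment <- "lipid"
  roles <- resolveRoles(atoms, defaultConfig())
  traj <- new("Trajectory", coords = arr,
              box = matrix(rep(box, each = n_frames), n_frames, 3),
              times = (seq_len(n_frames) - 1L) * 100,
              atoms = atoms, roles = roles)
  list(trajectory = traj, removed = removed)
}
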