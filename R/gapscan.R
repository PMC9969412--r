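# Grid-based detection of transient headgroup gaps (lipid packing defects):
# each leaflet surface is rasterized from the solvent side, cells are
# classified as covered-polar / exposed-apolar / empty, and connected
# exposed-apolar cells (4-connectivity, periodic in x/y) form gaps.

# label connected components of TRUE cells on a periodic grid via
# union-find (path halving), 4-connectivity; returns an integer matrix
# (0 for FALSE cells)
periodicComponents <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nx, ny))
  parent <- seq_len(nx * ny)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cellOf <- function(i, j) (j - 1L) * nx + i
  for (k in idx) {
    i <- ((k - 1L) %% nx) + 1L
    j <- ((k - 1L) %/% nx) + 1L
    for (nb in list(c(i %% nx + 1L, j), c(i, j %% ny + 1L))) {
      if (mask[nb[1], nb[2]]) {
        a <- find(k)
        b <- find(cellOf(nb[1], nb[2]))
        if (a != b) parent[b] <- a
      }
    }
  }
  roots <- vapply(idx, find, integer(1))
  lab <- matrix(0L, nx, ny)
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Scan one leaflet surface for headgroup gaps
#'
#' Projects the leaflet's lipid atoms onto a periodic x/y grid, looking from
#' the solvent side: the first atom encountered within the interfacial depth
#' window decides each cell's class. Polar atoms (headgroup nitrogen,
#' phosphate, ester carbons) give covered-polar; tail atoms give
#' exposed-apolar; cells with no atom in the window stay empty. Connected
#' exposed-apolar cells (4-connectivity, periodic) form gaps whose area is
#' the member-cell count times the cell area.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param frame 0-based frame index.
#' @param leaflet \code{"upper"} or \code{"lower"}.
#' @param ref a \linkS4class{MembraneRef} (for surfaces and leaflet
#'   assignment); computed on the fly if \code{NULL}.
#' @param cell target grid spacing, nm (adjusted to divide the box evenly).
#' @param radii named numeric: footprint radii (nm) for roles \code{head},
#'   \code{phosphate}, \code{ester}, \code{tail}. The defaults give each
#'   pseudo-lipid a polar footprint that fully covers its tail footprint,
#'   so an intact surface shows no gaps, while the tail footprints of
#'   laterally adjacent lipids touch, so gaps of neighboring uncovered
#'   lipids merge.
#' @param depth_pad window extension beyond the head/tail surfaces, nm.
#' @return a \linkS4class{GapMap}.
#' @export
scanGaps <- function(traj, frame, leaflet = "upper", ref = NULL,
                     cell = 0.1,
                     radii = defaultConfig()$gapscan$radii,
                     depth_pad = 0.5) {
  if (cell <= 0) stop("grid spacing must be positive")
  stopifnot(leaflet %in% c("upper", "lower"))
  roles <- atomRoles(traj)
  if (is.null(ref)) {
    leaflets <- assignLeaflets(traj, frame)
    refrow <- referenceSurfaces(traj, frame, leaflets)
  } else {
    leaflets <- leafletOf(ref, frame)
    refrow <- refTable(ref)[frame + 1L, ]
  }
  box <- frameBox(traj, frame)
  nx <- max(1L, as.integer(round(box[1] / cell)))
  ny <- max(1L, as.integer(round(box[2] / cell)))
  cx <- box[1] / nx; cy <- box[2] / ny

  atom_idx <- c(roles@headN, roles@phosphate, roles@ester, roles@tail)
  cls <- c(rep(1L, length(roles@headN)), rep(1L, length(roles@phosphate)),
           rep(1L, length(roles@ester)), rep(2L, length(roles@tail)))
  rad <- c(rep(radii[["head"]], length(roles@headN)),
           rep(radii[["phosphate"]], length(roles@phosphate)),
           rep(radii[["ester"]], length(roles@ester)),
           rep(radii[["tail"]], length(roles@tail)))
  in_leaf <- leaflets[as.character(roles@lipidId[atom_idx])] == leaflet
  xyz <- frameCoords(traj, frame)
  z <- xyz[atom_idx, 3]
  if (leaflet == "upper") {
    lo <- refrow$z_tail_upper - depth_pad
    hi <- refrow$z_head_upper + depth_pad
  } else {
    lo <- refrow$z_head_lower - depth_pad
    hi <- refrow$z_tail_lower + depth_pad
  }
  keep <- which(in_leaf & z >= lo & z <= hi)
  ord <- keep[order(z[keep], decreasing = (leaflet == "upper"))]

  grid <- matrix(0L, nx, ny)
  for (k in ord) {
    a <- atom_idx[k]; r <- rad[k]
    x0 <- xyz[a, 1]; y0 <- xyz[a, 2]
    is_ <- floor((x0 - r) / cx):ceiling((x0 + r) / cx)
    js_ <- floor((y0 - r) / cy):ceiling((y0 + r) / cy)
    for (ii in is_) for (jj in js_) {
      ci <- (ii %% nx) + 1L; cj <- (jj %% ny) + 1L
      if (grid[ci, cj] != 0L) next
      dx <- (ii + 0.5) * cx - x0
      dy <- (jj + 0.5) * cy - y0
      if (dx * dx + dy * dy <= r * r) grid[ci, cj] <- cls[k]
    }
  }
  labels <- periodicComponents(grid == 2L)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  area_cell <- cx * cy
  gaps <- if (length(ids)) {
    ncells <- vapply(ids, function(g) sum(labels == g), integer(1))
    data.frame(gap_id = ids, n_cells = ncells, area_nm2 = ncells * area_cell)
  } else data.frame(gap_id = integer(), n_cells = integer(),
                    area_nm2 = numeric())
  new("GapMap", leaflet = leaflet, frame = as.integer(frame),
      cell = sqrt(area_cell), grid = grid, labels = labels, gaps = gaps)
}

#' Gap-size distribution with exponential-decay fit
#'
#' Pools the gap areas of a list of gap maps into a normalized probability
#' histogram and fits log-probability versus area by least squares,
#' reporting the decay constant (headgroup gap probability is expected to
#' fall off exponentially with gap size).
#'
#' @param gapmaps list of \linkS4class{GapMap} objects.
#' @param breaks histogram bin edges, nm^2 (default: Freedman-like fixed
#'   0.05 nm^2 bins up to the observed maximum).
#' @return list: \code{areas}, \code{mids}, \code{prob}, \code{max_area},
#'   \code{decay_constant} (per nm^2, \code{NA} if inestimable),
#'   \code{fit} the lm object or NULL.
#' @export
gapSizeDistribution <- function(gapmaps, breaks = NULL) {
  areas <- unlist(lapply(gapmaps, function(g) gapTable(g)$area_nm2))
  if (!length(areas))
    return(list(areas = numeric(), mids = numeric(), prob = numeric(),
                max_area = NA_real_, decay_constant = NA_real_, fit = NULL))
  if (is.null(breaks))
    breaks <- seq(0, max(areas) + 0.05, by = 0.05)
  h <- graphics::hist(areas, breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  keep <- prob > 0
  fit <- NULL; decay <- NA_real_
  if (sum(keep) >= 2L) {
    fit <- stats::lm(log(prob[keep]) ~ h$mids[keep])
    decay <- -unname(stats::coef(fit)[2])
  }
  list(areas = areas, mids = h$mids, prob = prob, max_area = max(areas),
       decay_constant = decay, fit = fit)
}

#' Is a gap large enough for an anchor side chain?
#'
#' @param area gap area, nm^2.
#' @param threshold minimum accessible area, nm^2; the default 0.23
#'   corresponds to a leucine side chain.
#' @return logical; \code{TRUE} iff \code{area >= threshold}.
#' @export
gapAccessibility <- function(area, threshold = 0.23) {
  stopifnot(threshold > 0)
  area >= threshold
}

#' Track gaps across frames and measure lifetimes
#'
#' Gaps in consecutive frames are linked when they share at least one grid
#' cell; a track's duration is (last - first frame) times the frame stride.
#'
#' @param gapmaps list of \linkS4class{GapMap} for consecutive frames
#'   (time-ordered, same grid).
#' @param stride_ps frame stride, ps.
#' @return data.frame: \code{track_id}, \code{first_frame},
#'   \code{last_frame}, \code{lifetime_ps}, \code{max_area_nm2}.
#' @export
gapLifetimes <- function(gapmaps, stride_ps = 1) {
  tracks <- list()   # each: list(cells, first, last, max_area, open)
  for (g in gapmaps) {
    fr <- g@frame
    ids <- gapTable(g)$gap_id
    cells_by_gap <- lapply(ids, function(id) which(g@labels == id))
    matched <- rep(FALSE, length(tracks))
    assigned <- rep(NA_integer_, length(ids))
    for (gi in seq_along(ids)) {
      for (ti in seq_along(tracks)) {
        tr <- tracks[[ti]]
        if (!tr$open || tr$last != fr - 1L) next
        if (length(intersect(tr$cells, cells_by_gap[[gi]]))) {
          assigned[gi] <- ti
          break
        }
      }
    }
    for (ti in seq_along(tracks)) {
      if (tracks[[ti]]$open && tracks[[ti]]$last < fr - 1L)
        tracks[[ti]]$open <- FALSE
    }
    for (gi in seq_along(ids)) {
      ar <- gapTable(g)$area_nm2[gi]
      if (is.na(assigned[gi])) {
        tracks[[length(tracks) + 1L]] <- list(
          cells = cells_by_gap[[gi]], first = fr, last = fr,
          max_area = ar, open = TRUE)
      } else {
        ti <- assigned[gi]
        tracks[[ti]]$cells <- cells_by_gap[[gi]]
        tracks[[ti]]$last <- fr
        tracks[[ti]]$max_area <- max(tracks[[ti]]$max_area, ar)
      }
    }
  }
  if (!length(tracks))
    return(data.frame(track_id = integer(), first_frame = integer(),
                      last_frame = integer(), lifetime_ps = numeric(),
                      max_area_nm2 = numeric()))
  data.frame(
    track_id = seq_along(tracks),
    first_frame = vapply(tracks, `[[`, integer(1), "first"),
    last_frame = vapply(tracks, `[[`, integer(1), "last"),
    lifetime_ps = vapply(tracks, function(t)
      (t$last - t$first) * stride_ps, numeric(1)),
    max_area_nm2 = vapply(tracks, `[[`, numeric(1), "max_area"))
}

#' Write a gap map grid as dense text
#'
#' @param gapmap a \linkS4class{GapMap}.
#' @param path output path (tab-separated integer matrix).
#' @return invisibly, \code{path}.
#' @export
writeGapGrid <- function(gapmap, path) {
  utils::write.table(gapmap@grid, path, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}
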