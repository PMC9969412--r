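#' Default analysis configuration
#'
#' Declarative settings for the whole pipeline: atom-selection rules
#' (residue-name and atom-name patterns, so the same pipeline handles POPC
#' naming dialects and the synthetic pseudo-lipids), residue annotations
#' (polarity classes, anchor-capable positions, orientation reporter
#' residues, bulky turn residues), geometric thresholds, event dwell times
#' in ns, gap-scan grid settings, and the canonical closed-state
#' intramolecular hydrogen-bond pattern.
#'
#' The defaults match the synthetic pseudo-system built by
#' \code{\link{generateScenario}}: pseudo-lipids named \code{PLIP} with one
#' choline-nitrogen bead \code{NC3}, one phosphate bead \code{P}, two
#' ester-succeeding carbon beads \code{EST1}/\code{EST2} and two tail beads
#' \code{T1}/\code{T2}; a 10-residue cyclic peptide with backbone beads
#' \code{CA}, \code{N}, \code{HN}, \code{O} and one side-chain bead
#' \code{CB} per residue.
#'
#' @return a nested list; see \code{\link{loadConfig}} for the YAML mirror.
#' @export
defaultConfig <- function() {
  list(
    selection = list(
      peptide = list(
        resnames = c("LEU", "ALA", "PRO", "PHE", "GLY", "VAL", "ILE"),
        backbone = c("CA", "N", "HN", "H", "O", "C"),
        ellipse = "^CA$",
        donor = "^N$", donor_h = "^(HN|H)$", acceptor = "^O$",
        sidechain = "^C[BGDEZ]"
      ),
      lipid = list(
        resnames = c("PLIP", "POPC", "POPE", "DOPC"),
        headgroup_n = "^(NC3|N4|N)$",
        phosphate = "^(P|P8|PO4)$",
        ester = "^(EST[12]|C1A|C1B|C2[12]|C3[12])$",
        tail = "^(T[0-9]|C[2-9][0-9]*|C1[0-9])$"
      ),
      solvent = list(resnames = c("SOL", "HOH", "WAT", "W", "TIP3"))
    ),
    residues = list(
      polarity = c(LEU = "apolar", PHE = "apolar", PRO = "apolar",
                   ALA = "polar", GLY = "polar", VAL = "apolar",
                   ILE = "apolar"),
      anchors = c(1L, 3L, 4L, 5L, 6L, 8L, 9L, 10L),
      reporters = c(4L, 9L),
      turns = c(5L, 10L)
    ),
    thresholds = list(
      rmsd_closed = 0.2,           # nm; open if RMSD to closed ref > this
      hb_dist = 0.35,              # nm donor-acceptor heavy-atom distance
      hb_angle = 150,              # degrees, donor-H-acceptor minimum
      contact_cutoff = 0.45,       # nm side-chain heavy atom to tail atom
      parallel_max_theta = 30,     # deg folded theta at/below which the ring
                                   # counts as parallel to the membrane plane
      gap_access_area = 0.23,      # nm^2, minimum gap area for a leucine
      leaflet_hysteresis = 0.2     # nm around midplane for leaflet carry-over
    ),
    dwell_ns = list(
      anchoring = 1, insertion = 2, conformation = 1, rotation = 1,
      crossing_persist = 5
    ),
    gapscan = list(
      cell = 0.1,                  # nm grid spacing
      radii = c(head = 0.47, phosphate = 0.35, ester = 0.35, tail = 0.42),
      depth_pad = 0.5              # nm beyond head/tail surfaces
    ),
    hbond_pattern = list(
      canonical = list(c(1L, 8L), c(8L, 1L), c(3L, 6L), c(6L, 3L))
    )
  )
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file with the structure of \code{\link{defaultConfig}} and
#' merges it over the defaults, so a user config only needs the keys it
#' changes.
#'
#' @param path path to a YAML file, or \code{NULL} for pure defaults.
#' @return nested configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  mergeLists(cfg, user)
}

#' Write a configuration to YAML
#'
#' @param config nested configuration list.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# recursive right-biased merge of nested named lists
mergeLists <- function(base, override) {
  if (!is.list(base) || !is.list(override) || is.null(names(override)))
    return(override)
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      mergeLists(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

# dwell in frames from a dwell in ns and the frame stride in ps
dwellFrames <- function(dwell_ns, dt_ps) {
  max(1L, as.integer(round(dwell_ns * 1000 / dt_ps)))
}

frameStride <- function(traj) {
  tt <- frameTimes(traj)
  if (length(tt) < 2L) return(1)
  stats::median(diff(tt))
}
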