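# Anchor-probability statistics over ensembles of pulling runs: pooled
# fractions of successful anchoring events per pulled residue position,
# split by start conformation.

#' Anchor probability per residue position
#'
#' Pools pulling-run results across peptides that share the residue at the
#' pulled position and reports, per (residue position, start conformation)
#' cell, the fraction of runs with a successful anchoring event. Run counts
#' are reported alongside; empty cells are omitted with a warning.
#'
#' @param runs data.frame of pulling-run results with columns
#'   \code{peptide}, \code{pulled_position} (integer ring position),
#'   \code{pulled_residue} (residue name, e.g. \code{"LEU"}),
#'   \code{start_conformation} (\code{"open"}/\code{"closed"}),
#'   \code{success} (logical), and optionally \code{first_anchor_frame}.
#' @param by either \code{"position"} (pool by ring position) or
#'   \code{"residue"} (pool by residue name).
#' @return data.frame: pooling key, \code{start_conformation},
#'   \code{n_runs}, \code{n_success}, \code{probability}.
#' @export
anchorProbability <- function(runs, by = c("position", "residue")) {
  by <- match.arg(by)
  key <- if (by == "position") runs$pulled_position else runs$pulled_residue
  if (any(runs$success & is.na(runs$first_anchor_frame)))
    stop("successful runs must carry a first_anchor_frame")
  split_keys <- interaction(key, runs$start_conformation, drop = TRUE)
  cells <- split(runs, split_keys)
  rows <- lapply(cells, function(cell) {
    data.frame(key = cell[[if (by == "position") "pulled_position"
                           else "pulled_residue"]][1],
               start_conformation = cell$start_conformation[1],
               n_runs = nrow(cell),
               n_success = sum(cell$success),
               probability = mean(cell$success))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- if (by == "position") "position" else "residue"
  rownames(out) <- NULL
  out[order(out$start_conformation, out[[1]]), , drop = FALSE]
}

#' Analyze a pulling-run ensemble with the anchoring detector
#'
#' Generates (or receives) the per-run mini-trajectories of a pulling
#' ensemble and runs \code{\link{detectAnchoring}} on each, producing the
#' \code{runs} table consumed by \code{\link{anchorProbability}}. A run is
#' successful when an anchoring event is detected that persists to the end
#' of the run.
#'
#' @param ensemble ensemble description from
#'   \code{\link{generatePullingEnsemble}}.
#' @param config configuration list.
#' @return data.frame of pulling-run results (one row per run) with the
#'   columns documented in \code{\link{anchorProbability}}.
#' @export
analyzePullingRuns <- function(ensemble, config = defaultConfig()) {
  rows <- lapply(seq_along(ensemble$runs), function(i) {
    spec <- ensemble$runs[[i]]
    traj <- generatePullingRun(spec)
    ref <- membraneReference(traj)
    desc <- computeDescriptors(traj, ref = ref, config = config)
    ev <- detectAnchoring(traj, ref, desc, config)
    persists <- nrow(ev) > 0 &&
      any(ev$end_frame >= nFrames(traj) - 1L)
    first_frame <- if (nrow(ev)) ev$start_frame[1] else NA_integer_
    data.frame(peptide = spec$peptide,
               pulled_position = spec$pulled_position,
               pulled_residue = spec$pulled_residue,
               start_conformation = spec$start_conformation,
               success = persists,
               first_anchor_frame = if (persists) first_frame else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
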