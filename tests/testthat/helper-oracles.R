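# Fixture builders and independent brute-force oracles used across the
# test files. Oracles deliberately use different algorithms/code paths than
# the implementation they check.

# minimal Trajectory from an atom table and a list of per-frame coordinate
# matrices
mkTraj <- function(atoms, coords_list, box = c(10, 10, 10), times = NULL,
                   config = defaultConfig()) {
  atoms$mass <- permeatrace:::guessMass(atoms$name)
  roles <- resolveRoles(atoms, config)
  atoms$segment <- "fixture"
  nfr <- length(coords_list)
  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nfr))
  for (i in seq_len(nfr)) arr[, , i] <- coords_list[[i]]
  if (is.null(times)) times <- (seq_len(nfr) - 1) * 100
  new("Trajectory", coords = arr,
      box = matrix(rep(box, each = nfr), nfr, 3),
      times = as.numeric(times), atoms = atoms, roles = roles)
}

# peptide-only one-frame trajectory from a conformer template, optionally
# rigidly transformed
peptideFixture <- function(conformer = "closed", R = diag(3),
                           shift = c(5, 5, 5)) {
  tpl <- permeatrace:::buildPeptideTemplate(conformer)
  xyz <- tpl$coords %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  mkTraj(tpl$atoms, list(xyz))
}

# flat membrane-only trajectory (optionally jittered / with buried sites)
membraneFixture <- function(n_side = 8L, jitter = 0, frames = 1L, seed = 1L,
                            removal_prob = 0) {
  generateGapFrames(n_frames = frames, removal_prob = removal_prob,
                    n_side = n_side, membrane_jitter = jitter, seed = seed)
}

# angle between two vectors, atan2 formulation (vs the acos one under test)
oracleAngleDeg <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

# optimal-superposition RMSD through bio3d (independent implementation)
oracleRmsd <- function(X, Y) {
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(X)),
                                            as.vector(t(Y))))
  sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - X)^2)))
}

# brute-force intramolecular H-bond scan over explicit donor/acceptor
# coordinates (plain loops, no early exits shared with the implementation)
oracleHbondPairs <- function(N, H, O, dmax = 0.35, amin = 150, n = 10) {
  hits <- matrix(integer(), ncol = 2)
  for (d in 1:n) {
    for (acp in 1:n) {
      sep <- min(abs(d - acp), n - abs(d - acp))
      if (sep < 2) next
      dist <- sqrt(sum((N[d, ] - O[acp, ])^2))
      v1 <- N[d, ] - H[d, ]
      v2 <- O[acp, ] - H[d, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (dist <= dmax && ang >= amin)
        hits <- rbind(hits, c(d, acp))
    }
  }
  hits
}

# connected components of a periodic boolean grid through igraph
oracleComponents <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(integer())
  id <- matrix(seq_len(nx * ny), nx, ny)
  edges <- c()
  for (k in idx) {
    i <- ((k - 1L) %% nx) + 1L
    j <- ((k - 1L) %/% nx) + 1L
    right <- c((i %% nx) + 1L, j)
    down <- c(i, (j %% ny) + 1L)
    if (mask[right[1], right[2]])
      edges <- c(edges, k, id[right[1], right[2]])
    if (mask[down[1], down[2]])
      edges <- c(edges, k, id[down[1], down[2]])
  }
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2,
                                          byrow = TRUE), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(idx),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  sort(as.integer(table(comp$membership)))
}

# run-length encoding of the dwell-filtered A/B subsequence: expected
# rotation event (from, to) pairs
oracleRotations <- function(labels, dwell) {
  labels <- labels[labels %in% c("A", "B")]
  if (!length(labels)) return(character())
  filt <- permeatrace:::dwellFilterLabels(labels, dwell)
  r <- rle(filt)
  out <- character()
  for (i in seq_along(r$values)[-1]) {
    from <- r$values[i - 1]; to <- r$values[i]
    if (from %in% c("A", "B") && to %in% c("A", "B") && from != to)
      out <- c(out, paste0(from, to))
  }
  out
}

# events of a given type, ordered
evOf <- function(events, type) {
  events[events$type %in% type, , drop = FALSE]
}
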