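# Independent brute-force oracles used to certify the implementation on
# small inputs.  These deliberately work from first principles (subset
# enumeration over the distance matrix) and share no code with the
# package's incremental algorithms.

# all vertex subsets of size 1..max_size with their diameters
oracle_subsets <- function(dmat, max_size) {
  n <- nrow(dmat)
  out <- list()
  for (m in seq_len(min(max_size, n))) {
    cmb <- combn(n, m)
    for (j in seq_len(ncol(cmb))) {
      s <- cmb[, j]
      diam <- if (m == 1L) 0 else max(dmat[s, s][upper.tri(diag(m))])
      out[[length(out) + 1L]] <- list(vertices = s, diam = diam)
    }
  }
  out
}

# maximal subsets (facets) of the complex at threshold t: a qualifying
# subset is maximal iff no further vertex is within t of all its members
oracle_maximal_at <- function(dmat, subs, t, max_report_size) {
  n <- nrow(dmat)
  keys <- character(0)
  for (s in subs) {
    if (s$diam > t) next
    v <- s$vertices
    extendable <- FALSE
    for (w in setdiff(seq_len(n), v)) {
      if (all(dmat[w, v] <= t)) {
        extendable <- TRUE
        break
      }
    }
    if (!extendable && length(v) <= max_report_size)
      keys <- c(keys, paste(v, collapse = " "))
  }
  sort(keys)
}

# vertex keys of implementation bars alive at t
bars_alive_at <- function(barcode, t) {
  alive <- barcode$birth <= t & (barcode$open | t < barcode$death)
  sort(vapply(barcode$vertices[alive], paste, "", collapse = " "))
}

# plain-R Delaunay oracle: empty-circumsphere test for every 4-subset
oracle_delaunay3 <- function(coords) {
  n <- nrow(coords)
  cells <- list()
  for (cmb in as.data.frame(combn(n, 4L))) {
    P <- coords[cmb, , drop = FALSE]
    E <- sweep(P[-1L, , drop = FALSE], 2L, P[1L, ])
    if (abs(det(E)) < 1e-9) next
    center <- P[1L, ] + drop(solve(2 * E, rowSums(E^2)))
    r2 <- sum((P[1L, ] - center)^2)
    others <- setdiff(seq_len(n), cmb)
    d2 <- rowSums(sweep(coords[others, , drop = FALSE], 2L, center)^2)
    if (all(d2 > r2)) cells[[length(cells) + 1L]] <- sort(cmb)
  }
  if (!length(cells)) return(matrix(integer(0), 0L, 4L))
  do.call(rbind, cells)
}

# helper to rigidly transform a PDB fixture, writing a new file
transform_pdb <- function(path, out, rot = diag(3), shift = c(0, 0, 0)) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE)
  xyz <- sweep(xyz %*% t(rot), 2L, shift, `+`)
  pdb$xyz <- as.vector(t(xyz))
  bio3d::write.pdb(pdb, file = out)
  out
}

# helper to permute the atom records of a PDB fixture
shuffle_pdb <- function(path, out, seed = 1L) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM")
  atom <- lines[is_atom]
  perm <- withr::with_seed(seed, sample(length(atom)))
  writeLines(c(atom[perm], "END"), out)
  out
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# a rigid motion that is exact in floating point AND at PDB's 3-decimal
# coordinate precision: axis permutation with sign flips plus a
# binary-fraction translation.  Using it for file round-trip tests keeps
# coordinate quantization out of the invariance question.
exact_rot <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, -1, 0))
exact_shift <- c(5.25, -2.5, 11.125)

# in-memory rigid motion of a labeled cloud (generic rotations allowed)
rotate_cloud <- function(cloud, rot, shift = c(0, 0, 0)) {
  out <- cloud
  out$coords <- sweep(cloud$coords %*% t(rot), 2L, shift, `+`)
  out
}
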