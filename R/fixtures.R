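# Deterministic generators for every geometric and biological input the
# test suite needs; nothing is downloaded.

#' Vertices of an axis-aligned cuboid
#'
#' The canonical 8-point motif: with the default 1 x 1 x 1.5 side lengths
#' its pairwise distance multiset is {1 (x8), sqrt(2) (x4), 1.5 (x4),
#' sqrt(3.25) (x8), sqrt(4.25) (x4)} and the minimal edge length is 1.
#'
#' @param a,b,c positive side lengths.
#' @return A [point_cloud()] with a `manifest` attribute recording the
#'   parameters and the generated pairwise distances.
#' @export
make_cuboid <- function(a = 1, b = 1, c = 1.5) {
  stopifnot(a > 0, b > 0, c > 0)
  g <- expand.grid(x = c(0, a), y = c(0, b), z = c(0, c))
  cloud <- point_cloud(as.matrix(g))
  attr(cloud, "manifest") <- list(
    name = "cuboid", parameters = list(a = a, b = b, c = c),
    n_points = 8L, distances = as.vector(dist(cloud$coords)))
  cloud
}

#' Vertices of a regular hexagon
#'
#' Six points in the z = 0 plane with the given side length (which equals
#' the circumradius).  Distance multiset: side (x6), side * sqrt(3) (x6),
#' 2 * side (x3).  This is the unique highly symmetric six-point
#' configuration in which six dimension-0 facet bars die at the side
#' length and triangles first form at side * sqrt(3).
#'
#' @param side positive side length.
#' @return A [point_cloud()] with a `manifest` attribute.
#' @export
make_hexagon <- function(side = 2) {
  stopifnot(side > 0)
  ang <- (0:5) * pi / 3
  cloud <- point_cloud(cbind(side * cos(ang), side * sin(ang), 0))
  attr(cloud, "manifest") <- list(
    name = "hexagon", parameters = list(side = side),
    n_points = 6L, distances = as.vector(dist(cloud$coords)))
  cloud
}

#' Uniform random point cloud
#'
#' @param n number of points.
#' @param seed RNG seed; the same seed reproduces the same cloud.
#' @param box coordinate range, applied per axis.
#' @param n_site optionally tag `n_site` randomly chosen points `SITE` and
#'   the rest `NEIGHBORHOOD` for modified-metric tests.
#' @return A [point_cloud()].
#' @export
make_random_cloud <- function(n, seed = 1L, box = c(0, 10), n_site = NULL) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    coords <- matrix(runif(3L * n, box[1L], box[2L]), n, 3L)
    group <- rep("NONE", n)
    if (!is.null(n_site)) {
      stopifnot(n_site >= 0, n_site <= n)
      group <- rep("NEIGHBORHOOD", n)
      group[sample.int(n, n_site)] <- "SITE"
    }
    point_cloud(coords, group = group)
  })
}

# side-chain heavy atoms of the standard amino acids (PDB atom names)
side_chain_atoms <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# deterministic coordinate wobble independent of RNG state, keyed by
# (seed, residue, atom, axis) so shared residues of a WT/MT pair coincide
fixture_wobble <- function(seed, i, k, amp = 0.08) {
  idx <- seed * 101 + i * 37 + k * 7 + 1:3
  u <- sin(idx * 12.9898) * 43758.5453
  amp * (2 * (u - floor(u)) - 1)
}

build_chain_atoms <- function(sequence, seed) {
  rows <- list()
  for (i in seq_along(sequence)) {
    aa3 <- sequence[i]
    x0 <- 3.8 * (i - 1)
    base <- rbind(
      N  = c(x0 - 1.0, 0.6, 0.0),
      CA = c(x0, 0.0, 0.0),
      C  = c(x0 + 1.1, 0.7, 0.0),
      O  = c(x0 + 1.4, 1.88, 0.0)
    )
    side <- side_chain_atoms[[aa3]]
    names_all <- c(rownames(base), side)
    coords <- base
    for (k in seq_along(side)) {
      coords <- rbind(coords,
                      c(x0 + 0.45 * (-1)^k, 0.6 + 1.1 * k, 0.35 * (k %% 2)))
    }
    for (k in seq_len(nrow(coords)))
      coords[k, ] <- coords[k, ] + fixture_wobble(seed, i, k)
    # quantize to PDB coordinate precision so files, manifest and
    # recomputed geometry agree exactly
    coords <- round(coords, 3L)
    rows[[i]] <- data.frame(
      resno = i, resid = aa3, atom = names_all,
      element = substr(names_all, 1L, 1L),
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

format_pdb_atoms <- function(at, chain = "A") {
  name_field <- ifelse(nchar(at$atom) < 4L,
                       sprintf(" %-3s", at$atom), at$atom)
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(at)), name_field, at$resid, chain, at$resno,
          at$x, at$y, at$z, 1.00, 0.00, at$element)
}

#' Generate a toy wild-type / mutant structure pair
#'
#' Writes two minimal PDB files for an idealized extended chain that
#' differ only in the atom records of the site residue, where the
#' wild-type amino acid is substituted by the mutant one.  Side chains use
#' idealized ladder geometry with per-residue heavy-atom compositions
#' matching the standard amino-acid tables; these are geometric stand-ins,
#' not physically minimized structures.
#'
#' @param seed integer seed controlling the (deterministic) coordinate
#'   wobble.
#' @param n_residues chain length.
#' @param site_index 1-based index of the mutated residue.
#' @param wt_aa,mt_aa one-letter codes of the wild-type and mutant residue.
#' @param sequence optional chain of one-letter codes (site position is
#'   overwritten); defaults to a fixed cycle of small residues.
#' @param dir output directory.
#' @return list with `wt_path`, `mt_path` and a `manifest` recording the
#'   parameters, per-residue element counts and consecutive CA-CA
#'   distances of the wild-type chain.
#' @export
make_mutation_pair <- function(seed = 1L, n_residues = 7L, site_index = 4L,
                               wt_aa = "A", mt_aa = "W", sequence = NULL,
                               dir = tempdir()) {
  stopifnot(site_index >= 1L, site_index <= n_residues)
  if (is.null(sequence))
    sequence <- rep_len(c("A", "G", "S", "L", "D", "K", "T"), n_residues)
  stopifnot(length(sequence) == n_residues)
  seq_wt <- sequence; seq_wt[site_index] <- wt_aa
  seq_mt <- sequence; seq_mt[site_index] <- mt_aa
  aa3_wt <- bio3d::aa123(seq_wt)
  aa3_mt <- bio3d::aa123(seq_mt)
  at_wt <- build_chain_atoms(aa3_wt, seed)
  at_mt <- build_chain_atoms(aa3_mt, seed)
  wt_path <- file.path(dir, sprintf("toy_s%d_%s%d%s_wt.pdb",
                                    seed, wt_aa, site_index, mt_aa))
  mt_path <- file.path(dir, sprintf("toy_s%d_%s%d%s_mt.pdb",
                                    seed, wt_aa, site_index, mt_aa))
  writeLines(c(format_pdb_atoms(at_wt), "END"), wt_path)
  writeLines(c(format_pdb_atoms(at_mt), "END"), mt_path)
  ca <- as.matrix(at_wt[at_wt$atom == "CA", c("x", "y", "z")])
  manifest <- list(
    name = "toy_mutation_pair",
    parameters = list(seed = seed, n_residues = n_residues,
                      site_index = site_index, wt_aa = wt_aa, mt_aa = mt_aa,
                      sequence = sequence),
    element_counts_wt = lapply(seq_len(n_residues), function(i)
      table(at_wt$element[at_wt$resno == i])),
    n_atoms = c(wt = nrow(at_wt), mt = nrow(at_mt)),
    ca_consecutive_dist = unname(sqrt(rowSums(diff(ca)^2)))
  )
  list(wt_path = wt_path, mt_path = mt_path, manifest = manifest)
}
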