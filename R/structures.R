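#' Load a protein structure as a labeled point cloud
#'
#' Parses a PDB or mmCIF file (by extension) with bio3d, keeping heavy
#' atoms of standard `ATOM` records only: hydrogens, waters and
#' heteroatoms are excluded, and alternate locations are resolved to the
#' highest-occupancy conformer.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @return A [point_cloud()] with element symbols and a residue table
#'   (`chain`, `resno`, `resid`, `atom`).
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE) else
    bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele) | ele == ""))
    ele <- bio3d::atom2ele(at$elety)
  ele <- toupper(trimws(ele))
  at <- at[!ele %in% c("H", "D", ""), , drop = FALSE]
  ele <- ele[!ele %in% c("H", "D", "")]
  # resolve altloc to the highest occupancy conformer
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -occ)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  point_cloud(
    cbind(at$x, at$y, at$z),
    element = ele,
    residue = data.frame(chain = at$chain, resno = at$resno,
                         resid = at$resid, atom = at$elety,
                         stringsAsFactors = FALSE)
  )
}

#' Mutation specification
#'
#' Describes one point mutation: the wild-type and mutant structure files,
#' the chain and 1-based residue position, the one-letter wild-type and
#' mutant amino acids, and the neighborhood cutoff radius (default 16
#' Angstrom).
#'
#' @param structure_path wild-type structure file.
#' @param mutant_structure_path mutant structure file.
#' @param chain chain identifier.
#' @param position 1-based residue number.
#' @param wild_aa,mutant_aa one-letter amino-acid codes.
#' @param cutoff neighborhood cutoff radius in Angstrom.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(structure_path, mutant_structure_path, chain,
                          position, wild_aa, mutant_aa, cutoff = 16) {
  ok_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  if (!wild_aa %in% ok_aa || !mutant_aa %in% ok_aa)
    stop("wild_aa and mutant_aa must be standard one-letter amino-acid codes")
  if (!(cutoff >= 0)) stop("cutoff must be nonnegative")
  structure(
    list(structure_path = structure_path,
         mutant_structure_path = mutant_structure_path,
         chain = as.character(chain), position = as.integer(position),
         wild_aa = wild_aa, mutant_aa = mutant_aa, cutoff = as.numeric(cutoff)),
    class = "mutation_spec"
  )
}

#' Tag mutation-site and neighborhood atoms
#'
#' Atoms of the residue at (`chain`, `position`) are tagged `SITE`; atoms
#' of every other residue within `cutoff` Angstrom of any site atom are
#' tagged `NEIGHBORHOOD`; all remaining atoms are dropped.  When
#' `expected_aa` is given, the residue found at the site must match it.
#'
#' @param cloud a [point_cloud()] from [load_structure()].
#' @param chain chain identifier.
#' @param position 1-based residue number.
#' @param cutoff neighborhood radius in Angstrom (default 16).
#' @param expected_aa optional one-letter code to validate the site residue.
#' @return The group-tagged, restricted `point_cloud`.
#' @export
select_site_sets <- function(cloud, chain, position, cutoff = 16,
                             expected_aa = NULL) {
  if (is.null(cloud$residue))
    stop("cloud carries no residue identifiers; load it with load_structure()")
  res <- cloud$residue
  site <- res$chain == chain & res$resno == position
  if (!any(site))
    stop("missing residue at the mutation site: chain ", chain,
         " position ", position,
         " has no atoms in the structure; cannot featurize this mutation")
  if (!is.null(expected_aa)) {
    found <- unique(res$resid[site])
    found1 <- suppressWarnings(bio3d::aa321(found))
    if (!expected_aa %in% found1)
      stop("residue mismatch at chain ", chain, " position ", position,
           ": found ", paste(found, collapse = "/"),
           ", expected ", expected_aa)
  }
  dmat <- as.matrix(dist(cloud$coords))
  near <- apply(dmat[, site, drop = FALSE], 1L, min) <= cutoff
  nbhd <- near & !site
  keep <- site | nbhd
  out <- subset_cloud(cloud, keep)
  out$group <- ifelse(site[keep], "SITE", "NEIGHBORHOOD")
  if (!any(nbhd))
    warning("empty neighborhood at cutoff ", cutoff,
            " Angstrom around chain ", chain, " position ", position)
  out
}

#' Element-specific site/neighborhood subcloud
#'
#' Keeps `SITE` atoms of element `e_site` and `NEIGHBORHOOD` atoms of
#' element `e_nbhd`.  Either side may come back empty.
#'
#' @param tagged a group-tagged [point_cloud()] from [select_site_sets()].
#' @param e_site,e_nbhd element symbols in `C`, `N`, `O`.
#' @return The restricted `point_cloud`.
#' @export
element_pair_subcloud <- function(tagged, e_site, e_nbhd) {
  e_site <- match.arg(e_site, c("C", "N", "O"))
  e_nbhd <- match.arg(e_nbhd, c("C", "N", "O"))
  keep <- (tagged$group == "SITE" & tagged$element == e_site) |
    (tagged$group == "NEIGHBORHOOD" & tagged$element == e_nbhd)
  subset_cloud(tagged, keep)
}
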