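#' Labeled 3-D point cloud
#'
#' The universal geometric input: atom (or bare point) coordinates in
#' Angstrom, with an optional chemical element symbol per point, a site
#' group tag per point (`"SITE"`, `"NEIGHBORHOOD"` or `"NONE"`), and an
#' optional residue identifier table for protein-derived clouds.
#'
#' @param coords numeric matrix with 3 columns (x, y, z in Angstrom).
#' @param element character vector of element symbols, recycled if length 1.
#' @param group character vector of group tags in `SITE`, `NEIGHBORHOOD`,
#'   `NONE`; recycled if length 1.
#' @param residue optional `data.frame` with one row per point and columns
#'   `chain`, `resno` (1-based residue number), `resid` (3-letter residue
#'   name) and `atom` (atom name).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(coords, element = "C", group = "NONE", residue = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0L, 3L)
  if (ncol(coords) != 3L)
    stop("coords must have exactly 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop("all coordinates must be finite")
  n <- nrow(coords)
  element <- rep_len(as.character(element), n)
  group <- rep_len(as.character(group), n)
  bad <- setdiff(unique(group), c("SITE", "NEIGHBORHOOD", "NONE"))
  if (length(bad))
    stop("unknown group tag(s): ", paste(bad, collapse = ", "))
  if (!is.null(residue)) {
    residue <- as.data.frame(residue)
    if (nrow(residue) != n)
      stop("residue table must have one row per point")
  }
  structure(
    list(coords = coords, element = element, group = group, residue = residue),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points", nrow(x$coords)))
  if (nrow(x$coords)) {
    tab <- table(x$element)
    cat("; elements:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
    if (any(x$group != "NONE")) {
      gt <- table(x$group)
      cat("; groups:", paste(sprintf("%s=%d", names(gt), gt), collapse = " "))
    }
  }
  cat("\n")
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' Subset a point cloud
#'
#' @param cloud a [point_cloud()].
#' @param idx integer or logical index over points.
#' @return The subsetted `point_cloud`.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$coords[idx, , drop = FALSE],
              cloud$element[idx], cloud$group[idx],
              if (!is.null(cloud$residue)) cloud$residue[idx, , drop = FALSE])
}

#' Read a point cloud from an XYZ file
#'
#' Standard XYZ layout: a count line, a comment line, then one
#' `element x y z` row per point.
#'
#' @param path file path.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(trimws(lines[1L])))
    stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ header in ", path)
  if (length(lines) < n + 2L) stop("truncated XYZ file: ", path)
  if (n == 0L) return(point_cloud(matrix(numeric(0), 0, 3)))
  rows <- strsplit(trimws(lines[seq_len(n) + 2L]), "\\s+")
  el <- vapply(rows, `[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  point_cloud(xyz, element = el)
}

#' Write a point cloud to an XYZ file
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path, comment = "") {
  n <- n_points(cloud)
  body <- sprintf("%s %.10g %.10g %.10g", cloud$element,
                  cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  writeLines(c(as.character(n), comment, if (n) body), path)
  invisible(path)
}

#' Read a point cloud from CSV
#'
#' Expects columns `x`, `y`, `z` and optionally `element` and `group`.
#'
#' @param path file path.
#' @return A [point_cloud()].
#' @export
read_point_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns x, y, z: ", path)
  point_cloud(as.matrix(df[, need]),
              element = if ("element" %in% names(df)) df$element else "C",
              group = if ("group" %in% names(df)) df$group else "NONE")
}
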