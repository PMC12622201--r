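#' Circumcenter and circumradius of a simplex
#'
#' Solves the Gram system for the unique circumsphere within the affine
#' hull of the vertices.
#'
#' @param P matrix with one vertex per row.
#' @return list with `center` (ambient coordinates) and `radius`.
#' @keywords internal
circumsphere <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) == 1L)
    return(list(center = drop(P), radius = 0))
  p0 <- P[1L, ]
  E <- sweep(P[-1L, , drop = FALSE], 2L, p0)
  G <- E %*% t(E)
  h <- rowSums(E^2) / 2
  x <- tryCatch(solve(G, h), error = function(e) {
    # degenerate (e.g. cocircular) vertex sets: minimum-norm solution,
    # whose limit is the circumcenter within the lower-dimensional hull
    s <- svd(G)
    inv <- ifelse(s$d > max(s$d) * 1e-12, 1 / s$d, 0)
    drop(s$v %*% (inv * crossprod(s$u, h)))
  })
  v <- drop(t(E) %*% x)
  list(center = p0 + v, radius = sqrt(sum(v^2)))
}

# Deterministic lexicographic ordering + symbolic jitter wrapper around the
# brute-force Delaunay kernels.  Sorting first makes the (rarely needed)
# perturbation independent of input point order, so downstream features are
# invariant under atom permutations.
delaunay_cells <- function(pts, dim) {
  pts <- as.matrix(pts)
  ord <- do.call(order, lapply(seq_len(ncol(pts)), function(j) pts[, j]))
  sorted <- pts[ord, , drop = FALSE]
  L <- sqrt(sum((apply(sorted, 2L, max) - apply(sorted, 2L, min))^2))
  if (L == 0) L <- 1
  n <- nrow(sorted)
  qnoise <- function(scale) {
    idx <- seq_len(n * dim)
    u <- sin(idx * 12.9898) * 43758.5453
    matrix(scale * (2 * (u - floor(u)) - 1), n, dim)
  }
  kern <- if (dim == 3L) .delaunay3_bf else .delaunay2_bf
  for (scale in c(0, 1e-7, 1e-6, 1e-5) * L) {
    jittered <- sorted + qnoise(scale)
    res <- kern(jittered)
    if (!res$degenerate) {
      cells <- res$cells
      cells[] <- ord[cells]
      coords <- jittered
      coords[ord, ] <- jittered
      return(list(cells = t(apply(cells, 1L, sort)), coords = coords))
    }
  }
  stop("Delaunay triangulation failed: the input remains degenerate after ",
       "symbolic perturbation; supply points in general position")
}

#' Alpha-complex filtration of a point cloud
#'
#' Builds the Delaunay triangulation of the cloud (brute-force
#' empty-circumsphere construction, certified cell by cell) and assigns each
#' simplex its alpha filtration value in radius units (Angstrom): top cells
#' get their circumradius, lower faces get their own circumradius when
#' Gabriel and otherwise inherit the minimum over their cofacets.  Vertices
#' appear at 0.  Exact duplicate points are collapsed with a warning;
#' collinear and coplanar inputs are routed through 1-D and 2-D
#' triangulations of their affine hull.  Near-degenerate (cospherical)
#' configurations are resolved by a deterministic symbolic perturbation.
#'
#' @param cloud a [point_cloud()] with at least one point.  The standard
#'   Euclidean metric is always used.
#' @param f_max filtration ceiling in Angstrom; simplices whose alpha value
#'   exceeds it are dropped.
#' @return A [filtered_complex()] (never truncated: every Delaunay cofacet
#'   below `f_max` is present).
#' @export
alpha_filtration <- function(cloud, f_max) {
  if (!(f_max > 0)) stop("f_max must be positive")
  n <- n_points(cloud)
  if (n < 1L) stop("alpha_filtration requires at least one point")
  coords <- cloud$coords
  dup <- duplicated(coords)
  if (any(dup)) {
    warning(sum(dup), " duplicate point(s) collapsed before triangulation")
    coords <- coords[!dup, , drop = FALSE]
    n <- nrow(coords)
  }

  if (n == 1L)
    return(filtered_complex(list(1L), 0, 0L, f_max, FALSE, n_vertices = 1L))

  ctr <- sweep(coords, 2L, colMeans(coords))
  sv <- svd(ctr, nu = 0L)
  rank <- sum(sv$d > 1e-8 * max(sv$d[1L], .Machine$double.eps))
  rank <- min(rank, n - 1L, 3L)

  if (rank <= 1L) {
    t1 <- drop(ctr %*% sv$v[, 1L])
    o <- order(t1)
    edges <- lapply(seq_len(n - 1L), function(i) sort(c(o[i], o[i + 1L])))
    evals <- vapply(seq_len(n - 1L), function(i)
      abs(t1[o[i + 1L]] - t1[o[i]]) / 2, 0)
    simplices <- c(as.list(seq_len(n)), edges)
    filt <- c(numeric(n), evals)
    keep <- filt <= f_max
    return(filtered_complex(simplices[keep], filt[keep], 1L, f_max,
                            FALSE, n_vertices = n))
  }

  tri <- if (rank == 2L) delaunay_cells(ctr %*% sv$v[, 1:2], 2L) else
    delaunay_cells(coords, 3L)
  cells <- tri$cells
  # alpha values are computed on the (possibly symbolically perturbed)
  # coordinates the triangulation certified, keeping both consistent
  work <- tri$coords
  if (nrow(cells) == 0L)
    stop("degenerate Delaunay triangulation: fewer than ", rank + 1L,
         " points in general position; perturb the input or reduce rank")

  # enumerate all faces of all cells, by dimension
  keys <- new.env(parent = emptyenv())
  by_dim <- rep(list(list()), rank + 1L)
  add_face <- function(s) {
    k <- paste(s, collapse = " ")
    if (is.null(keys[[k]])) {
      keys[[k]] <- TRUE
      d <- length(s)
      by_dim[[d]][[length(by_dim[[d]]) + 1L]] <<- s
    }
  }
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    for (m in seq_along(cell))
      for (sub in as.data.frame(combn(cell, m)))
        add_face(sort(sub))
  }
  # include isolated vertices (every vertex of the cloud is in the complex)
  for (v in seq_len(n)) add_face(v)

  val <- new.env(parent = emptyenv())
  for (s in by_dim[[1L]]) val[[paste(s, collapse = " ")]] <- 0
  for (d in seq(rank + 1L, 2L)) {
    for (s in by_dim[[d]]) {
      skey <- paste(s, collapse = " ")
      if (is.null(val[[skey]]))
        val[[skey]] <- circumsphere(work[s, , drop = FALSE])$radius
      if (d == 2L) next  # vertices stay at 0
      for (j in seq_along(s)) {
        f <- s[-j]
        fkey <- paste(f, collapse = " ")
        if (!is.null(val[[fkey]])) {
          val[[fkey]] <- min(val[[fkey]], val[[skey]])
        } else {
          cs <- circumsphere(work[f, , drop = FALSE])
          inside <- sqrt(sum((work[s[j], ] - cs$center)^2)) < cs$radius
          if (inside) val[[fkey]] <- val[[skey]]
        }
      }
    }
  }

  simplices <- list()
  filt <- numeric(0)
  for (d in seq_len(rank + 1L))
    for (s in by_dim[[d]]) {
      v <- val[[paste(s, collapse = " ")]]
      if (v <= f_max) {
        simplices[[length(simplices) + 1L]] <- s
        filt[length(filt) + 1L] <- v
      }
    }
  filtered_complex(simplices, filt, rank, f_max, FALSE, n_vertices = n)
}
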