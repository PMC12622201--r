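#' f-vector curve of a filtered complex
#'
#' For each grid value `t`, counts the faces of each dimension present in
#' the subcomplex at filtration value `t`:
#' `f(t) = (f_-1, f_0, ..., f_{d-1})` with `f_-1 = 1` for the empty face by
#' convention, and `f_i(t)` the number of `i`-simplices with filtration
#' value `<= t`.
#'
#' @param cx a [filtered_complex()].
#' @param grid ascending filtration values within `[0, f_max]`.
#' @param max_dim highest face dimension to report; defaults to the
#'   complex's `max_dim` attribute.
#' @return An `fvector_curve`: list with `grid` and an integer matrix
#'   `counts` (`length(grid)` rows; columns `f-1`, `f0`, ...,
#'   `f<max_dim>`).
#' @export
f_vector_curve <- function(cx, grid, max_dim = NULL) {
  f_max <- attr(cx, "f_max")
  if (any(grid < 0 | grid > f_max))
    stop("grid values must lie within [0, f_max]")
  if (is.null(max_dim)) max_dim <- attr(cx, "max_dim")
  counts <- matrix(0L, length(grid), max_dim + 2L,
                   dimnames = list(NULL, paste0("f", seq.int(-1L, max_dim))))
  counts[, 1L] <- 1L
  for (d in seq.int(0L, max_dim)) {
    fv <- sort(cx$filt[cx$dim == d])
    if (length(fv))
      counts[, d + 2L] <- findInterval(grid, fv, left.open = FALSE)
  }
  structure(list(grid = grid, counts = counts), class = "fvector_curve")
}

#' @export
print.fvector_curve <- function(x, ...) {
  cat(sprintf("<fvector_curve> %d grid points, dimensions %s..%s\n",
              length(x$grid), colnames(x$counts)[1L],
              colnames(x$counts)[ncol(x$counts)]))
  invisible(x)
}

#' Write f-vector curves as TSV
#'
#' First row is the grid; one row per face dimension follows.
#'
#' @param fv an `fvector_curve` from [f_vector_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
fvector_to_tsv <- function(fv, path) {
  m <- rbind(grid = fv$grid, t(fv$counts))
  df <- data.frame(series = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' h-vector of a simplicial complex from its f-vector
#'
#' Standard Stanley-Reisner transform
#' `h_j = sum_{i=0..j} (-1)^(j-i) C(d-i, j-i) f_{i-1}` for `j = 0..d`,
#' where `d` is the number of entries of `f` after the leading
#' `f_-1 = 1`.  The identity `sum_j h_j = f_{d-1}` holds.
#'
#' @param f numeric vector `(f_-1, f_0, ..., f_{d-1})`; the leading entry
#'   must be 1 and all entries nonnegative integers.
#' @return Numeric vector `(h_0, ..., h_d)`.
#' @export
h_vector <- function(f) {
  if (length(f) < 1L || f[1L] != 1)
    stop("malformed f-vector: the leading entry must be f_-1 = 1")
  if (any(f < 0) || any(f != round(f)))
    stop("malformed f-vector: entries must be nonnegative integers")
  d <- length(f) - 1L
  vapply(0:d, function(j)
    sum(vapply(0:j, function(i)
      (-1)^(j - i) * choose(d - i, j - i) * f[i + 1L], 0)), 0)
}
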