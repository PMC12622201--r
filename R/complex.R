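#' Filtered simplicial complex container
#'
#' Stores simplices as sorted integer vertex vectors (1-based indices into
#' the originating point cloud) with one filtration value each.  The set is
#' closed under taking faces and filtration values are monotone: a face
#' never appears later than any of its cofaces.  `truncated` records whether
#' simplices of dimension `max_dim + 1` would exist below `f_max` but were
#' not built; facet deaths in dimension `max_dim` can only be trusted when
#' the complex is not truncated.
#'
#' @param simplices list of integer vectors (ascending vertex indices).
#' @param filt numeric vector of filtration values (Angstrom).
#' @param max_dim dimension cap used to build the complex.
#' @param f_max filtration ceiling.
#' @param truncated logical; `TRUE` if higher-dimensional cofacets may exist.
#' @param n_vertices number of points in the underlying cloud.
#' @return An object of class `filtered_complex`.
#' @export
filtered_complex <- function(simplices, filt, max_dim, f_max,
                             truncated = FALSE, n_vertices = NULL) {
  stopifnot(length(simplices) == length(filt))
  dims <- vapply(simplices, length, 1L) - 1L
  o <- order(dims, filt)
  structure(
    list(simplices = simplices[o], filt = as.numeric(filt)[o], dim = dims[o]),
    class = "filtered_complex",
    max_dim = as.integer(max_dim), f_max = as.numeric(f_max),
    truncated = isTRUE(truncated),
    n_vertices = if (is.null(n_vertices)) {
      if (length(simplices)) max(unlist(simplices)) else 0L
    } else as.integer(n_vertices)
  )
}

simplex_key <- function(v) vapply(v, paste, "", collapse = " ")

#' @export
print.filtered_complex <- function(x, ...) {
  cat(sprintf("<filtered_complex> %d simplices, max_dim %d, f_max %g%s\n",
              length(x$simplices), attr(x, "max_dim"), attr(x, "f_max"),
              if (attr(x, "truncated")) " (truncated)" else ""))
  if (length(x$simplices)) {
    tab <- table(x$dim)
    cat("  by dimension:",
        paste(sprintf("dim%s=%s", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Check the structural invariants of a filtered complex
#'
#' Verifies face closure, filtration monotonicity, and the `f_max` ceiling.
#' Used by the test suite and available for defensive checks.
#'
#' @param cx a [filtered_complex()].
#' @param tol relative tolerance for monotonicity comparisons.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_complex <- function(cx, tol = 1e-9) {
  f_max <- attr(cx, "f_max")
  if (any(cx$filt > f_max * (1 + tol)))
    stop("simplex filtration value exceeds f_max")
  filt_of <- setNames(cx$filt, simplex_key(cx$simplices))
  slack <- tol * max(1, f_max)
  for (i in seq_along(cx$simplices)) {
    s <- cx$simplices[[i]]
    if (is.unsorted(s, strictly = TRUE)) stop("simplex vertices not sorted")
    if (length(s) > 1L) {
      for (j in seq_along(s)) {
        face <- paste(s[-j], collapse = " ")
        fv <- filt_of[face]
        if (is.na(fv)) stop("complex not closed under faces")
        if (fv > cx$filt[i] + slack) stop("filtration not monotone")
      }
    }
  }
  invisible(TRUE)
}

#' Serialize a filtered complex to JSON
#'
#' Writes a JSON list of `{vertices, filtration}` records.
#'
#' @param cx a [filtered_complex()].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
complex_to_json <- function(cx, path = NULL) {
  rec <- lapply(seq_along(cx$simplices), function(i)
    list(vertices = cx$simplices[[i]], filtration = cx$filt[i]))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
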