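#' Persistent facet-ideal barcode
#'
#' In the Stanley-Reisner decomposition of a filtered simplicial complex,
#' every facet (maximal simplex) of the complex at filtration value `t`
#' contributes a prime monomial ideal.  A simplex is born as a facet at its
#' own filtration value and stops being a facet when its first cofacet
#' appears, so each simplex yields the interval
#' `[filt(sigma), min over cofacets of filt(tau))`.  Simplices that remain
#' maximal at the ceiling are reported with `death = f_max` and `open =
#' TRUE`.  Bars with persistence at most `1e-9 * f_max` (zero persistence,
#' up to floating point) are dropped.
#'
#' @param cx a [filtered_complex()].
#' @param dims integer vector of bar dimensions to compute.  Defaults to
#'   every dimension whose cofacets are available: `0 .. max_dim - 1`, plus
#'   `max_dim` itself when the complex is not truncated.
#' @return A `facet_barcode`: a `data.frame` with columns `dim`, `birth`,
#'   `death`, `open` and a list column `vertices`, sorted by
#'   (dim, birth, death, vertices); attribute `f_max` carries the ceiling.
#' @export
facet_barcode <- function(cx, dims = NULL) {
  max_dim <- attr(cx, "max_dim")
  f_max <- attr(cx, "f_max")
  truncated <- attr(cx, "truncated")
  avail <- if (truncated) max_dim - 1L else max_dim
  if (is.null(dims)) {
    if (avail < 0L)
      stop("no facet dimension is computable: the complex is truncated at ",
           "max_dim 0; rebuild with a larger max_dim")
    dims <- seq.int(0L, avail)
  }
  if (truncated && any(dims > avail))
    stop("facet deaths in dimension ", max(dims), " require cofacets of ",
         "dimension ", max(dims) + 1L, "; rebuild the complex with max_dim >= ",
         max(dims) + 1L)
  tol <- 1e-9 * f_max

  bars <- list()
  for (d in dims) {
    idx <- which(cx$dim == d)
    if (!length(idx)) next
    keys <- simplex_key(cx$simplices[idx])
    death <- rep(f_max, length(idx))
    open <- rep(TRUE, length(idx))
    cof <- which(cx$dim == d + 1L)
    if (length(cof)) {
      fkeys <- character(0)
      fvals <- numeric(0)
      for (j in cof) {
        s <- cx$simplices[[j]]
        for (k in seq_along(s)) {
          fkeys[length(fkeys) + 1L] <- paste(s[-k], collapse = " ")
          fvals[length(fvals) + 1L] <- cx$filt[j]
        }
      }
      dmin <- tapply(fvals, fkeys, min)
      m <- match(keys, names(dmin))
      hit <- !is.na(m)
      death[hit] <- pmin(death[hit], dmin[m[hit]])
      open[hit] <- FALSE
    }
    birth <- cx$filt[idx]
    keep <- death - birth > tol
    if (!any(keep)) next
    bars[[length(bars) + 1L]] <- data.frame(
      dim = d, birth = birth[keep], death = unname(death[keep]),
      open = open[keep]
    )
    bars[[length(bars)]]$vertices <- unname(cx$simplices[idx][keep])
  }
  out <- if (length(bars)) do.call(rbind, bars) else
    data.frame(dim = integer(0), birth = numeric(0), death = numeric(0),
               open = logical(0), vertices = I(list()))
  vkey <- vapply(out$vertices, function(v)
    paste(sprintf("%09d", v), collapse = " "), "")
  out <- out[order(out$dim, out$birth, out$death, vkey), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, f_max = f_max, class = c("facet_barcode", "data.frame"))
}

#' @export
print.facet_barcode <- function(x, ...) {
  cat(sprintf("<facet_barcode> %d bars, f_max %g\n", nrow(x), attr(x, "f_max")))
  if (nrow(x)) {
    tab <- table(x$dim)
    cat("  by dimension:",
        paste(sprintf("dim%s=%s", names(tab), tab), collapse = " "), "\n")
    print.data.frame(head(as.data.frame(x[, c("dim", "birth", "death", "open")]), 10))
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Count alive facet bars on a filtration grid
#'
#' Entry `(t, i)` counts the dimension-`i` bars with `birth <= t < death`;
#' open bars (facets surviving to the ceiling) count as alive through
#' `f_max`.
#'
#' @param barcode a [facet_barcode()].
#' @param grid ascending filtration values within `[0, f_max]`.
#' @param dims integer vector of dimensions to report.
#' @return Integer matrix, `length(grid)` rows by `length(dims)` columns
#'   (named `dim0`, `dim1`, ...).
#' @export
facet_counts_on_grid <- function(barcode, grid, dims = c(0L, 1L)) {
  f_max <- attr(barcode, "f_max")
  if (any(grid < 0 | grid > f_max))
    stop("grid values must lie within [0, f_max]")
  out <- matrix(0L, length(grid), length(dims),
                dimnames = list(NULL, paste0("dim", dims)))
  for (j in seq_along(dims)) {
    b <- barcode[barcode$dim == dims[j], , drop = FALSE]
    if (!nrow(b)) next
    for (i in seq_along(grid)) {
      t <- grid[i]
      alive <- b$birth <= t & (b$open | t < b$death)
      out[i, j] <- sum(alive)
    }
  }
  out
}

#' Serialize a facet barcode to JSON
#'
#' @param barcode a [facet_barcode()].
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
barcode_to_json <- function(barcode, path = NULL) {
  rec <- list(
    f_max = attr(barcode, "f_max"),
    bars = lapply(seq_len(nrow(barcode)), function(i) list(
      dim = barcode$dim[i], birth = barcode$birth[i],
      death = barcode$death[i], open = barcode$open[i],
      vertices = barcode$vertices[[i]]
    ))
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
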