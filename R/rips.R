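#' Vietoris-Rips filtration from a distance matrix
#'
#' A simplex on vertex set `S` (with `|S| - 1 <= max_dim`) enters the
#' complex as soon as every pairwise distance within `S` is finite and at
#' most `f_max`; its filtration value is the largest pairwise distance
#' (the edge-length / diameter convention), and vertices appear at 0.
#' Entries of `+Inf` in a modified-metric distance matrix therefore block
#' the corresponding simplices entirely.
#'
#' @param dst a distance matrix from [pairwise_distances()] (or any
#'   symmetric numeric matrix with zero diagonal; `+Inf` allowed).
#' @param max_dim maximum simplex dimension to build (>= 0).
#' @param f_max filtration ceiling (> 0), Angstrom.
#' @return A [filtered_complex()].  The `truncated` attribute is `TRUE` when
#'   at least one simplex of dimension `max_dim + 1` exists below `f_max`
#'   but was not built.
#' @export
rips_filtration <- function(dst, max_dim, f_max) {
  if (max_dim < 0) stop("max_dim must be >= 0")
  if (!(f_max > 0)) stop("f_max must be positive")
  d <- unclass(dst)
  n <- nrow(d)
  if (is.null(n) || n == 0L)
    return(filtered_complex(list(), numeric(0), max_dim, f_max,
                            truncated = FALSE, n_vertices = 0L))
  adj <- is.finite(d) & d <= f_max
  diag(adj) <- FALSE
  up <- lapply(seq_len(n), function(i) which(adj[i, ] & seq_len(n) > i))

  simplices <- lapply(seq_len(n), function(i) i)
  filt <- numeric(n)
  level <- simplices
  lfilt <- filt
  truncated <- FALSE
  for (k in seq_len(max_dim + 1L)) {
    nxt <- list()
    nfilt <- numeric(0)
    for (i in seq_along(level)) {
      s <- level[[i]]
      cand <- Reduce(intersect, up[s])
      for (v in cand) {
        if (k <= max_dim) {
          nxt[[length(nxt) + 1L]] <- c(s, v)
          nfilt[length(nfilt) + 1L] <- max(lfilt[i], d[s, v])
        } else {
          truncated <- TRUE
          break
        }
      }
      if (truncated) break
    }
    if (k > max_dim || length(nxt) == 0L) break
    simplices <- c(simplices, nxt)
    filt <- c(filt, nfilt)
    level <- nxt
    lfilt <- nfilt
  }
  filtered_complex(simplices, filt, max_dim, f_max,
                   truncated = truncated, n_vertices = n)
}
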