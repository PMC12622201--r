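#' Default multiscale filtration grid
#'
#' The filtration range runs from 1 to 12 Angstrom with a 0.4 Angstrom
#' step.  Because the range is not an integer multiple of the step, the
#' grid holds the 28 points 1.0, 1.4, ..., 11.8 and the ceiling `f_max`
#' stays at 12, so feature vectors are reproducible bit for bit.
#'
#' @param from,to,by grid range and step in Angstrom.
#' @return Ascending numeric grid.
#' @export
filtration_grid <- function(from = 1, to = 12, by = 0.4) {
  g <- seq(from, to, by = by)
  g[g <= to]
}

psrt_elements <- c("C", "N", "O")
psrt_statistics <- c("facet_dim0", "facet_dim1", "f0", "f1")

#' Layout descriptor for a per-structure feature block
#'
#' @param grid filtration grid.
#' @param complexes complex kinds in the block.
#' @return `data.frame` with columns `complex`, `site_element`,
#'   `nbhd_element`, `statistic`, `grid_index`, `grid_value`, one row per
#'   feature, in block order.
#' @export
block_layout <- function(grid = filtration_grid(),
                         complexes = c("rips", "alpha")) {
  g <- seq_along(grid)
  out <- expand.grid(grid_index = g, statistic = psrt_statistics,
                     nbhd_element = psrt_elements, site_element = psrt_elements,
                     complex = complexes, stringsAsFactors = FALSE)
  out <- out[, c("complex", "site_element", "nbhd_element", "statistic",
                 "grid_index")]
  out$grid_value <- grid[out$grid_index]
  out
}

layout_names <- function(layout) {
  sprintf("%s.%s%s.%s.g%02d", layout$complex, layout$site_element,
          layout$nbhd_element, layout$statistic, layout$grid_index)
}

# facet-count + f-vector statistics for one complex on the grid, in
# (facet_dim0, facet_dim1, f0, f1) order
complex_statistics <- function(cx, grid) {
  bc <- facet_barcode(cx, dims = 0:1)
  counts <- facet_counts_on_grid(bc, grid, dims = 0:1)
  fv <- f_vector_curve(cx, grid, max_dim = 1L)
  c(counts[, "dim0"], counts[, "dim1"],
    fv$counts[, "f0"], fv$counts[, "f1"])
}

#' Per-structure commutative-algebra feature block
#'
#' For each of the nine (site element, neighborhood element) pairs over
#' C, N, O, builds a Vietoris-Rips complex under the modified
#' site/neighborhood metric and an alpha complex (standard Euclidean
#' metric) on the union of the pair's atoms, and samples four statistics on
#' the filtration grid: alive facet-bar counts in dimensions 0 and 1, and
#' the face counts `f_0` and `f_1`.  Empty subclouds contribute zero blocks
#' so the vector length is constant across samples.
#'
#' @param tagged group-tagged [point_cloud()] from [select_site_sets()].
#' @param grid filtration grid (Angstrom).
#' @param f_max filtration ceiling (Angstrom).
#' @param complexes subset of `c("rips", "alpha")`.
#' @return Named numeric vector with a `layout` attribute
#'   (see [block_layout()]); length `length(complexes) * 9 * 4 *
#'   length(grid)`.
#' @export
embed_structure <- function(tagged, grid = filtration_grid(), f_max = 12,
                            complexes = c("rips", "alpha")) {
  complexes <- match.arg(complexes, several.ok = TRUE)
  ng <- length(grid)
  zero <- numeric(4L * ng)
  blocks <- list()
  for (cpx in complexes) {
    for (es in psrt_elements) {
      for (en in psrt_elements) {
        sub <- element_pair_subcloud(tagged, es, en)
        n <- n_points(sub)
        val <- if (n == 0L) zero else if (cpx == "rips") {
          # one-sided pairs legitimately yield an edgeless complex; the
          # degenerate-group warning is informative interactively but
          # expected here
          dm <- suppressWarnings(pairwise_distances(sub, "modified"))
          complex_statistics(rips_filtration(dm, max_dim = 2L, f_max), grid)
        } else {
          complex_statistics(alpha_filtration(sub, f_max), grid)
        }
        blocks[[length(blocks) + 1L]] <- val
      }
    }
  }
  out <- unlist(blocks, use.names = FALSE)
  layout <- block_layout(grid, complexes)
  names(out) <- layout_names(layout)
  attr(out, "layout") <- layout
  out
}

#' Assemble the wild-type / mutant embedding vector
#'
#' Concatenates `[WT | MT | WT - MT]` blocks (the difference block is
#' defined as wild-type minus mutant) and appends any precomputed
#' auxiliary/transformer feature row verbatim.
#'
#' @param wt_block,mt_block per-structure blocks from [embed_structure()];
#'   their layouts must match.
#' @param aux optional named numeric vector of auxiliary features.
#' @return Named numeric vector of class `embedding_vector` with a
#'   `layout` attribute carrying a `structure` column
#'   (`WT`/`MT`/`DIFF`/`AUX`).
#' @export
assemble_feature_vector <- function(wt_block, mt_block, aux = NULL) {
  lw <- attr(wt_block, "layout")
  lm <- attr(mt_block, "layout")
  if (is.null(lw) || is.null(lm) || !identical(lw, lm))
    stop("wild-type and mutant blocks have mismatched layouts")
  vals <- c(wt_block, mt_block, wt_block - mt_block)
  layout <- do.call(rbind, lapply(c("WT", "MT", "DIFF"), function(s)
    cbind(structure = s, lw, stringsAsFactors = FALSE)))
  nm <- paste(layout$structure, layout_names(lw), sep = ".")
  if (!is.null(aux)) {
    aux <- as.numeric(aux)
    anm <- if (!is.null(names(aux)) && all(nzchar(names(aux))))
      names(aux) else sprintf("aux%04d", seq_along(aux))
    vals <- c(vals, aux)
    nm <- c(nm, paste0("AUX.", anm))
    layout <- rbind(layout, data.frame(
      structure = "AUX", complex = NA, site_element = NA, nbhd_element = NA,
      statistic = anm, grid_index = NA, grid_value = NA,
      stringsAsFactors = FALSE))
  }
  names(vals) <- nm
  structure(vals, layout = layout, class = "embedding_vector")
}

#' Featurize one mutation
#'
#' Loads the wild-type and mutant structures, tags site and neighborhood
#' atoms (validating the residue identity on both sides), embeds both and
#' assembles the `[WT | MT | DIFF | aux]` vector.
#'
#' @param spec a [mutation_spec()].
#' @param aux optional auxiliary feature row.
#' @param grid,f_max,complexes see [embed_structure()].
#' @return An `embedding_vector`.
#' @export
featurize_mutation <- function(spec, aux = NULL, grid = filtration_grid(),
                               f_max = 12, complexes = c("rips", "alpha")) {
  wt <- load_structure(spec$structure_path)
  mt <- load_structure(spec$mutant_structure_path)
  wt_tag <- select_site_sets(wt, spec$chain, spec$position, spec$cutoff,
                             expected_aa = spec$wild_aa)
  mt_tag <- select_site_sets(mt, spec$chain, spec$position, spec$cutoff,
                             expected_aa = spec$mutant_aa)
  wt_block <- embed_structure(wt_tag, grid, f_max, complexes)
  mt_block <- embed_structure(mt_tag, grid, f_max, complexes)
  assemble_feature_vector(wt_block, mt_block, aux)
}

#' Featurize a table of mutations
#'
#' @param mutations `data.frame` with columns `structure`,
#'   `mutant_structure`, `chain`, `position`, `wild_aa`, `mutant_aa` and
#'   optionally `id` and `cutoff`.
#' @param aux optional numeric matrix/data.frame of auxiliary features with
#'   rownames keyed by mutation id.
#' @param grid,f_max,complexes see [embed_structure()].
#' @return list with `features` (numeric matrix, one row per mutation; rows
#'   that failed are all-`NA`) and `errors` (named character vector of
#'   per-row failure messages).
#' @export
featurize_mutations <- function(mutations, aux = NULL,
                                grid = filtration_grid(), f_max = 12,
                                complexes = c("rips", "alpha")) {
  ids <- if ("id" %in% names(mutations)) as.character(mutations$id) else
    sprintf("mut%03d", seq_len(nrow(mutations)))
  rows <- vector("list", nrow(mutations))
  errors <- character(0)
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    arow <- if (!is.null(aux)) unlist(aux[ids[i], , drop = TRUE]) else NULL
    rows[[i]] <- tryCatch({
      sp <- mutation_spec(m$structure, m$mutant_structure, m$chain,
                          m$position, m$wild_aa, m$mutant_aa,
                          cutoff = if ("cutoff" %in% names(m)) m$cutoff else 16)
      featurize_mutation(sp, aux = arow, grid = grid, f_max = f_max,
                         complexes = complexes)
    }, error = function(e) {
      errors[[ids[i]]] <<- conditionMessage(e)
      NULL
    })
  }
  ok <- which(!vapply(rows, is.null, TRUE))
  if (!length(ok))
    stop("no mutation could be featurized; first error: ", errors[1L])
  p <- length(rows[[ok[1L]]])
  feat <- matrix(NA_real_, nrow(mutations), p,
                 dimnames = list(ids, names(rows[[ok[1L]]])))
  for (i in ok) feat[i, ] <- rows[[i]]
  list(features = feat, errors = errors,
       layout = attr(rows[[ok[1L]]], "layout"))
}

#' Write a feature matrix as TSV with a machine-readable layout header
#'
#' @param feat result of [featurize_mutations()] or a plain matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(feat, path) {
  m <- if (is.list(feat)) feat$features else feat
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#layout: structure.complex.<site><nbhd>.statistic.gNN", con)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
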