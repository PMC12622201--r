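#' Pairwise distance matrix, standard or site-modified
#'
#' The modified metric implements the site/neighborhood exclusion rule: the
#' distance between two atoms is set to `+Inf` whenever both belong to the
#' mutation-site set or both belong to the neighborhood set, so that only
#' cross-group (site vs neighborhood) interactions can create simplices in a
#' Vietoris-Rips filtration.  Otherwise the standard Euclidean distance is
#' used.
#'
#' @param cloud a [point_cloud()].
#' @param metric_kind `"euclidean"` or `"modified"`.
#' @return An n x n numeric matrix with zero diagonal and class
#'   `psr_dist`; attribute `metric_kind` records the metric.
#' @export
pairwise_distances <- function(cloud, metric_kind = c("euclidean", "modified")) {
  metric_kind <- match.arg(metric_kind)
  n <- n_points(cloud)
  d <- as.matrix(dist(cloud$coords))
  dimnames(d) <- NULL
  if (n == 0L) d <- matrix(numeric(0), 0L, 0L)
  if (metric_kind == "modified") {
    if (n > 0L && all(cloud$group == "NONE"))
      stop("modified metric requires SITE/NEIGHBORHOOD group tags")
    for (g in c("SITE", "NEIGHBORHOOD")) {
      in_g <- cloud$group == g
      if (any(in_g)) d[in_g, in_g] <- Inf
    }
    diag(d) <- 0
    if (n > 0L && length(unique(cloud$group)) == 1L)
      warning("all points share one group under the modified metric; ",
              "the resulting complex is edgeless")
  }
  structure(d, class = c("psr_dist", "matrix"), metric_kind = metric_kind)
}
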