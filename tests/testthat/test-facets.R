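test_that("two points give the textbook facet bars", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  cx <- rips_filtration(pairwise_distances(cl), 1L, 5)
  bc <- facet_barcode(cx)
  b0 <- bc[bc$dim == 0L, ]
  b1 <- bc[bc$dim == 1L, ]
  expect_equal(nrow(b0), 2L)
  expect_equal(b0$birth, c(0, 0))
  expect_equal(b0$death, c(2, 2))
  expect_false(any(b0$open))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$birth, 2)
  expect_equal(b1$death, 5)
  expect_true(b1$open)
})

test_that("cuboid barcode reproduces the two dimension-1 groups and no dimension-2 bars", {
  cu <- make_cuboid()
  cx <- rips_filtration(pairwise_distances(cu), 3L, 2.5)
  bc <- facet_barcode(cx, dims = 0:2)
  b0 <- bc[bc$dim == 0L, ]
  expect_equal(nrow(b0), 8L)
  expect_equal(b0$death, rep(1, 8L))
  b1 <- bc[bc$dim == 1L, ]
  first <- b1[abs(b1$birth - 1) < 1e-12, ]
  second <- b1[abs(b1$birth - 1.5) < 1e-12, ]
  expect_equal(nrow(first), 8L)
  expect_equal(first$death, rep(sqrt(2), 8L))
  expect_equal(nrow(second), 4L)
  expect_equal(second$death, rep(sqrt(3.25), 4L))
  expect_equal(nrow(b1), 12L)
  expect_equal(sum(bc$dim == 2L), 0L)
})

test_that("hexagon barcode matches the six-point narrative and the oracle", {
  hx <- make_hexagon(side = 2)
  dmat <- unclass(pairwise_distances(hx))
  cx <- rips_filtration(pairwise_distances(hx), 3L, 5)
  bc <- facet_barcode(cx, dims = 0:2)
  b0 <- bc[bc$dim == 0L, ]
  expect_equal(nrow(b0), 6L)
  expect_equal(b0$death, rep(2, 6L))
  b1 <- bc[bc$dim == 1L, ]
  expect_equal(nrow(b1), 6L)
  expect_equal(b1$birth, rep(2, 6L))
  expect_equal(b1$death, rep(2 * sqrt(3), 6L))
  expect_true(all(b1$death <= 3.5))
  # against the maximal-subset oracle at every critical value
  subs <- oracle_subsets(dmat, 5L)
  for (t in c(0, sort(unique(dmat[upper.tri(dmat)])))) {
    if (t > 5) next
    expect_identical(bars_alive_at(bc, t), oracle_maximal_at(dmat, subs, t, 4L))
  }
})

test_that("facet counts on the grid follow alive-bar semantics", {
  cu <- make_cuboid()
  cx <- rips_filtration(pairwise_distances(cu), 3L, 2.5)
  bc <- facet_barcode(cx, dims = 0:2)
  cnt <- facet_counts_on_grid(bc, c(0.5, 1.2, 1.45, 2.2), dims = 0:2)
  expect_equal(unname(cnt[, "dim1"]), c(0L, 8L, 0L, 0L))
  expect_equal(unname(cnt[, "dim0"]), c(8L, 0L, 0L, 0L))
  expect_equal(unname(cnt[, "dim2"]), c(0L, 0L, 0L, 0L))
  # empty barcode gives an all-zero matrix
  empty <- facet_barcode(rips_filtration(pairwise_distances(point_cloud(
    matrix(numeric(0), 0L, 3L))), 1L, 1))
  expect_equal(sum(facet_counts_on_grid(empty, c(0.1, 0.5))), 0L)
})

test_that("facet deaths in the top dimension require cofacets unless structurally absent", {
  cl <- make_random_cloud(6L, seed = 5L)
  cx <- rips_filtration(pairwise_distances(cl), 1L, 30)
  expect_true(attr(cx, "truncated"))
  expect_error(facet_barcode(cx, dims = 0:1), "max_dim")
  # bipartite complexes are structurally cofacet-free in dimension 2
  bi <- make_random_cloud(6L, seed = 5L, n_site = 3L)
  cxb <- rips_filtration(pairwise_distances(bi, "modified"), 2L, 30)
  expect_false(attr(cxb, "truncated"))
  expect_silent(facet_barcode(cxb, dims = 0:1))
})

test_that("every dimension-1 bar survives to the ceiling under the modified metric", {
  for (seed in 1:20) {
    n <- 4L + seed %% 5L
    cl <- make_random_cloud(n, seed = 100L + seed,
                            n_site = 1L + seed %% (n - 1L))
    cx <- rips_filtration(pairwise_distances(cl, "modified"), 2L, 25)
    expect_true(max(cx$dim) <= 1L)
    bc <- facet_barcode(cx, dims = 0:1)
    b1 <- bc[bc$dim == 1L, ]
    if (nrow(b1)) {
      expect_true(all(b1$open))
      expect_equal(b1$death, rep(25, nrow(b1)))
    }
  }
})

test_that("alive facets cover the complex at sampled filtration values", {
  cl <- make_random_cloud(8L, seed = 42L)
  dmat <- unclass(pairwise_distances(cl))
  f_max <- quantile(dmat[upper.tri(dmat)], 0.8)
  # build the complex without a dimension cap so no facet is hidden
  cx <- rips_filtration(pairwise_distances(cl), 7L, f_max)
  expect_false(attr(cx, "truncated"))
  bc <- facet_barcode(cx, dims = 0:7)
  for (t in quantile(dmat[upper.tri(dmat)], c(0.1, 0.3, 0.5, 0.7))) {
    if (t > f_max) next
    alive <- bc[bc$birth <= t & (bc$open | t < bc$death), ]
    in_complex <- which(cx$filt <= t)
    covered <- vapply(in_complex, function(i) {
      s <- cx$simplices[[i]]
      any(vapply(alive$vertices, function(f) all(s %in% f), TRUE))
    }, TRUE)
    expect_true(all(covered))
  }
})

test_that("barcode JSON serialization is stable and well-formed", {
  cu <- make_cuboid()
  bc <- facet_barcode(rips_filtration(pairwise_distances(cu), 3L, 2.5))
  js <- jsonlite::fromJSON(barcode_to_json(bc), simplifyVector = FALSE)
  expect_equal(js$f_max, 2.5)
  expect_equal(length(js$bars), nrow(bc))
  expect_equal(js$bars[[1L]]$dim, 0L)
  expect_identical(barcode_to_json(bc), barcode_to_json(bc))
})
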