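test_that("point cloud construction enforces invariants and round-trips files", {
  expect_error(point_cloud(matrix(c(0, 0, NA), 1L, 3L)), "finite")
  expect_error(point_cloud(matrix(0, 1L, 3L), group = "BAD"), "group tag")
  cl <- point_cloud(rbind(c(0, 0, 0), c(1, 2, 3)), element = c("C", "O"))
  expect_equal(n_points(cl), 2L)

  tmp <- tempfile(fileext = ".xyz")
  write_xyz(cl, tmp)
  back <- read_xyz(tmp)
  expect_equal(back$coords, cl$coords)
  expect_equal(back$element, cl$element)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(0, 3), y = c(0, 4), z = 0,
                       element = "N", group = c("SITE", "NEIGHBORHOOD")),
            csv, row.names = FALSE)
  cl2 <- read_point_csv(csv)
  expect_equal(cl2$group, c("SITE", "NEIGHBORHOOD"))
})

test_that("modified metric blanks within-group pairs and keeps cross pairs", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(3, 4, 0)),
                    group = c("SITE", "NEIGHBORHOOD"))
  d <- pairwise_distances(cl, "modified")
  expect_equal(d[1L, 2L], 5)

  both_site <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)), group = "SITE")
  expect_warning(d2 <- pairwise_distances(both_site, "modified"),
                 "edgeless")
  expect_equal(d2[1L, 2L], Inf)

  # 2 SITE + 2 NEIGHBORHOOD: hand-enumerated 4x4 pattern
  cl4 <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 2, 0)),
                     group = c("SITE", "SITE", "NEIGHBORHOOD", "NEIGHBORHOOD"))
  d4 <- pairwise_distances(cl4, "modified")
  expect_equal(d4[1L, 2L], Inf)
  expect_equal(d4[3L, 4L], Inf)
  expect_equal(d4[1L, 3L], 2)
  expect_equal(d4[2L, 4L], 2)
  expect_equal(d4[1L, 4L], sqrt(5))
  expect_equal(diag(d4), rep(0, 4L))
  expect_true(isSymmetric(unclass(d4)))

  expect_error(pairwise_distances(point_cloud(matrix(0, 1, 3)), "modified"),
               "group tags")
})

test_that("Rips filtration matches the diameter convention on known shapes", {
  # equilateral triangle, side 1
  tri <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  cx <- rips_filtration(pairwise_distances(tri), max_dim = 2L, f_max = 2)
  expect_equal(sum(cx$dim == 0L), 3L)
  expect_equal(sum(cx$dim == 1L), 3L)
  expect_equal(sum(cx$dim == 2L), 1L)
  expect_equal(cx$filt[cx$dim == 0L], rep(0, 3L))
  expect_equal(cx$filt[cx$dim == 1L], rep(1, 3L))
  expect_equal(cx$filt[cx$dim == 2L], 1)
  expect_silent(validate_complex(cx))

  # cuboid with f_max above the space diagonal: the full simplex appears
  cu <- make_cuboid()
  full <- rips_filtration(pairwise_distances(cu), max_dim = 3L, f_max = 2.5)
  for (k in 0:3)
    expect_equal(sum(full$dim == k), choose(8L, k + 1L))
})

test_that("Rips complexes equal brute-force subset enumeration on random clouds", {
  for (seed in 1:6) {
    n <- 5L + (seed %% 4L)
    cl <- make_random_cloud(n, seed = seed, box = c(0, 4))
    dmat <- unclass(pairwise_distances(cl))
    f_max <- quantile(dmat[upper.tri(dmat)], 0.7)
    cx <- rips_filtration(pairwise_distances(cl), max_dim = 3L, f_max = f_max)
    subs <- oracle_subsets(dmat, 4L)
    expected <- Filter(function(s) s$diam <= f_max, subs)
    expect_equal(length(cx$simplices), length(expected))
    got <- sort(vapply(cx$simplices, paste, "", collapse = " "))
    want <- sort(vapply(expected, function(s)
      paste(s$vertices, collapse = " "), ""))
    expect_identical(got, want)
    # filtration value is the diameter
    diam_of <- setNames(vapply(expected, `[[`, 0, "diam"),
                        vapply(expected, function(s)
                          paste(s$vertices, collapse = " "), ""))
    expect_equal(cx$filt, unname(diam_of[vapply(cx$simplices, paste, "",
                                                collapse = " ")]))
    expect_silent(validate_complex(cx))
  }
})

test_that("modified metric caps simplex dimension at 1 with two groups", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                    group = c("SITE", "SITE", "NEIGHBORHOOD", "NEIGHBORHOOD"))
  cx <- rips_filtration(pairwise_distances(cl, "modified"), 3L, 10)
  expect_equal(max(cx$dim), 1L)
  expect_false(attr(cx, "truncated"))
})

test_that("alpha filtration handles degenerate and generic inputs", {
  # one point
  single <- alpha_filtration(point_cloud(matrix(1:3, 1L, 3L)), 5)
  expect_equal(length(single$simplices), 1L)
  expect_equal(single$filt, 0)

  # unit square: planar and cocircular; triangles at circumradius sqrt(2)/2
  sq <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  cx <- alpha_filtration(sq, 5)
  expect_silent(validate_complex(cx))
  expect_equal(cx$filt[cx$dim == 0L], rep(0, 4L))
  tri_vals <- cx$filt[cx$dim == 2L]
  expect_equal(length(tri_vals), 2L)
  expect_true(all(abs(tri_vals - sqrt(2) / 2) < 1e-4))

  # collinear input routed through the 1-D hull
  line <- alpha_filtration(point_cloud(cbind(c(0, 1, 3), 0, 0)), 5)
  expect_equal(sort(line$filt[line$dim == 1L]), c(0.5, 1))

  # duplicates collapsed with a warning
  expect_warning(alpha_filtration(point_cloud(rbind(c(0, 0, 0), c(0, 0, 0),
                                                    c(1, 0, 0))), 5),
                 "duplicate")
})

test_that("alpha cells are Delaunay cells and filtration values are monotone", {
  for (seed in c(11L, 12L, 13L)) {
    cl <- make_random_cloud(9L, seed = seed, box = c(0, 5))
    f_max <- 20
    cx <- alpha_filtration(cl, f_max)
    expect_silent(validate_complex(cx))
    got <- t(vapply(cx$simplices[cx$dim == 3L], identity, integer(4L)))
    want <- oracle_delaunay3(cl$coords)
    # sliver cells whose circumradius exceeds the ceiling are cut
    want_r <- apply(want, 1L, function(v)
      psrt:::circumsphere(cl$coords[v, ])$radius)
    want <- want[want_r <= f_max, , drop = FALSE]
    expect_equal(got[do.call(order, as.data.frame(got)), , drop = FALSE],
                 want[do.call(order, as.data.frame(want)), , drop = FALSE])
    # cell value is its circumradius
    for (i in which(cx$dim == 3L)) {
      cs <- psrt:::circumsphere(cl$coords[cx$simplices[[i]], ])
      expect_equal(cx$filt[i], cs$radius, tolerance = 1e-9)
    }
    # vertices at zero
    expect_equal(cx$filt[cx$dim == 0L], rep(0, 9L))
  }
})
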