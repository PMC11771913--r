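test_that("eps-neighbourhood is strict and self-inclusive", {
  # isolated point: only itself
  pts <- data.frame(x = c(0, 100), y = c(0, 0))
  expect_identical(eps_neighborhood(pts, 1, 5), 1L)

  # two points exactly eps apart exclude each other (strict <)
  pts2 <- data.frame(x = c(0, 1), y = c(0, 0))
  expect_identical(eps_neighborhood(pts2, 1, 1), 1L)
  expect_identical(eps_neighborhood(pts2, 2, 1), 2L)
  # just inside the radius they are neighbours
  expect_identical(eps_neighborhood(pts2, 1, 1 + 1e-9), c(1L, 2L))

  expect_error(eps_neighborhood(pts2, 1, 0), "eps > 0")

  # 200 uniform points against the exhaustive pairwise scan
  set.seed(23)
  u <- data.frame(x = runif(200), y = runif(200))
  d <- as.matrix(dist(cbind(u$x, u$y)))
  for (i in c(1, 57, 200)) {
    expect_identical(eps_neighborhood(u, i, 0.1),
                     unname(which(d[i, ] < 0.1)))
  }
})

test_that("core/border/noise classification matches the literal definition", {
  one <- data.frame(x = 0, y = 0)
  expect_identical(classify_points(one, 1, 2), "noise")
  expect_identical(classify_points(one, 1, 1), "core")

  # planted two-blob fixture: re-evaluate the definition per point
  set.seed(29)
  blob <- rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
                matrix(rnorm(100, 10, 0.5), ncol = 2),
                matrix(runif(40, -5, 15), ncol = 2))
  eps <- 1; mp <- 5
  got <- classify_points(blob, eps, mp)
  o <- oracle_dbscan(blob, eps, mp)
  expect_identical(got, unname(o$point_class))
})

test_that("clustering recovers planted structure and handles degenerate input", {
  # two discs far apart + sparse background
  gen <- generate_point_pattern(two_disc_config(seed = 33))
  r <- dbscan(gen$points, eps = 50, min_pts = 5)
  expect_equal(length(r$clusters), 2)

  # all points coincident: one cluster holding everything
  co <- data.frame(x = rep(1, 8), y = rep(2, 8))
  rc <- dbscan(co, eps = 0.5, min_pts = 8)
  expect_equal(length(rc$clusters), 1)
  expect_true(all(rc$cluster == 1L))

  # empty input: empty result, no error
  re <- dbscan(data.frame(x = numeric(0), y = numeric(0)), 1, 2)
  expect_equal(length(re$clusters), 0)
  expect_equal(length(re$cluster), 0)
})

test_that("random instances agree with the literal-definition oracle", {
  for (s in 1:8) {
    pts <- random_instance(n = sample(30:300, 1), seed = 40 + s)
    eps <- runif(1, 2, 15)
    mp <- sample(2:8, 1)
    impl <- suppressMessages(dbscan(pts, eps, mp))
    o <- oracle_dbscan(pts, eps, mp)
    expect_true(isTRUE(partitions_equivalent(impl, o)),
                info = sprintf("seed %d eps %.2f minPts %d: %s", s, eps, mp,
                               partitions_equivalent(impl, o)))
  }
})

test_that("core labels and core partition are invariant to input order", {
  pts <- random_instance(150, seed = 61)
  eps <- 8; mp <- 4
  r1 <- suppressMessages(dbscan(pts, eps, mp))
  set.seed(62)
  perm <- sample(nrow(pts))
  r2 <- suppressMessages(dbscan(pts[perm, ], eps, mp))
  # core flags map through the permutation
  expect_identical((r2$point_class == "core"),
                   (r1$point_class == "core")[perm])
  # partition restricted to cores identical up to relabeling
  core1 <- which(r1$point_class == "core")
  a <- r1$cluster[core1]
  b <- r2$cluster[match(core1, perm)]
  expect_equal(rand_index(a, b), 1)
})

test_that("cluster members are density-reachable from the cluster's cores", {
  pts <- random_instance(120, seed = 71)
  eps <- 9; mp <- 4
  r <- suppressMessages(dbscan(pts, eps, mp))
  o <- oracle_dbscan(pts, eps, mp)
  for (ci in seq_along(r$clusters)) {
    for (q in r$clusters[[ci]]) {
      if (o$core[q]) next
      # border member must be in the neighbourhood of some core of its cluster
      cores <- intersect(r$clusters[[ci]], which(o$core))
      expect_true(any(vapply(cores, function(p) q %in% o$nb[[p]], logical(1))))
    }
  }
})

test_that("sensitivity sweep shape and monotonicity laws", {
  gen <- generate_point_pattern(two_disc_config(seed = 83))
  # degenerate 1x1 grid equals a direct call
  sw1 <- sensitivity_sweep(gen$points, 50, 5)
  direct <- dbscan(gen$points, 50, 5)
  expect_equal(nrow(sw1), 1)
  expect_equal(sw1$n_clusters, length(direct$clusters))
  expect_equal(sw1$n_core, sum(direct$point_class == "core"))

  sw <- sensitivity_sweep(gen$points, c(20, 35, 50), c(3, 6, 9))
  expect_equal(nrow(sw), 9)
  # cores non-increasing in min_pts at fixed eps
  for (e in unique(sw$eps)) {
    expect_true(all(diff(sw$n_core[sw$eps == e]) <= 0))
  }
  # cores non-decreasing in eps at fixed min_pts
  for (m in unique(sw$min_pts)) {
    expect_true(all(diff(sw$n_core[sw$min_pts == m][order(unique(sw$eps))]) >= 0))
  }
})

test_that("cluster hulls: exact small cases and oracle area agreement", {
  tri <- data.frame(x = c(0, 4, 0), y = c(0, 0, 3))
  r <- list(clusters = list(1:3), point_class = rep("core", 3))
  h <- cluster_hulls(tri, r)[[1]]
  expect_equal(h$geometry, "polygon")
  expect_equal(h$area, 6)
  expect_equal(nrow(h$vertices), 3)

  sq <- data.frame(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5))
  r2 <- list(clusters = list(1:5), point_class = rep("core", 5))
  h2 <- cluster_hulls(sq, r2)[[1]]
  expect_equal(nrow(h2$vertices), 4)
  expect_equal(h2$area, 1)

  # degenerate: collinear -> segment; single location -> point
  seg <- data.frame(x = c(0, 1, 2), y = c(0, 1, 2))
  h3 <- cluster_hulls(seg, list(clusters = list(1:3),
                                point_class = rep("core", 3)))[[1]]
  expect_true(h3$degenerate)
  expect_equal(h3$geometry, "segment")
  pt <- data.frame(x = c(1, 1), y = c(2, 2))
  h4 <- cluster_hulls(pt, list(clusters = list(1:2),
                               point_class = rep("core", 2)))[[1]]
  expect_equal(h4$geometry, "point")

  # random cluster against an independent monotone-chain hull
  set.seed(91)
  rc <- data.frame(x = rnorm(60), y = rnorm(60))
  h5 <- cluster_hulls(rc, list(clusters = list(1:60),
                               point_class = rep("core", 60)))[[1]]
  expect_equal(h5$area, oracle_hull_area(cbind(rc$x, rc$y)), tolerance = 1e-10)
})

test_that("label file and GeoJSON exports are well-formed", {
  gen <- generate_point_pattern(two_disc_config(seed = 97))
  r <- dbscan(gen$points, 50, 5)
  td <- withr::local_tempdir()
  lf <- file.path(td, "labels.tsv")
  write_cluster_labels(gen$points, r, lf)
  lab <- read.delim(lf)
  expect_equal(nrow(lab), nrow(gen$points))
  expect_identical(lab$cluster, r$cluster)

  gj <- file.path(td, "hulls.geojson")
  write_hulls_geojson(cluster_hulls(gen$points, r), gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_equal(length(parsed$features), length(r$clusters))
  f1 <- parsed$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  ring <- f1$geometry$coordinates[[1]]
  expect_identical(ring[[1]], ring[[length(ring)]])  # closed ring
  expect_equal(f1$properties$member_count, length(r$clusters[[1]]))
})
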