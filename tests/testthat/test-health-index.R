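grid_segmap <- function(nr, nc, blocks, pixel_size = 0.1) {
  # blocks: list of list(rows=, cols=, label=)
  lg <- matrix(-1L, nr, nc)
  for (b in blocks) lg[b$rows, b$cols] <- b$label
  structure(list(label_grid = lg,
                 segments = data.frame(label = sort(unique(as.vector(lg[lg >= 0])))),
                 band_names = character(),
                 origin = c(0, nr * pixel_size),
                 pixel_size = rep(pixel_size, 2), crs_id = "local"),
            class = "segment_map")
}

test_that("disc membership is exact against rectangle-disc geometry", {
  # p deep inside one segment, tiny r -> only that segment
  sm <- grid_segmap(10, 10, list(list(rows = 1:10, cols = 1:5, label = 0L),
                                 list(rows = 1:10, cols = 6:10, label = 1L)))
  expect_identical(segments_near_point(c(0.25, 0.5), 0.01, sm), 0L)

  # r = 0 degenerates to the containing segment
  expect_identical(segments_near_point(c(0.75, 0.5), 0, sm), 1L)

  # boundary touch counts: disc reaching exactly the segment edge at x = 0.5
  expect_identical(segments_near_point(c(0.25, 0.5), 0.25, sm), c(0L, 1L))

  # random rectangles vs closed-form rectangle-disc oracle
  set.seed(43)
  nrects <- 20
  lgs <- lapply(seq_len(nrects), function(i) {
    r0 <- sample(1:8, 1); c0 <- sample(1:8, 1)
    list(rows = r0:min(10, r0 + sample(1:3, 1)),
         cols = c0:min(10, c0 + sample(1:3, 1)), label = NULL)
  })
  for (trial in 1:50) {
    p <- runif(2, -0.2, 1.2)
    r <- runif(1, 0, 0.4)
    for (i in seq_len(nrects)) {
      b <- lgs[[i]]
      smi <- grid_segmap(10, 10, list(list(rows = b$rows, cols = b$cols,
                                           label = 0L)))
      x0 <- (min(b$cols) - 1) * 0.1; x1 <- max(b$cols) * 0.1
      y1 <- 1 - (min(b$rows) - 1) * 0.1; y0 <- 1 - max(b$rows) * 0.1
      expect_equal(length(segments_near_point(p, r, smi)) == 1L,
                   oracle_rect_disc(x0, x1, y0, y1, p[1], p[2], r))
    }
  }
})

test_that("neighborhood membership grows monotonically with the radius", {
  sm <- grid_segmap(10, 10, list(list(rows = 1:5, cols = 1:5, label = 0L),
                                 list(rows = 1:5, cols = 6:10, label = 1L),
                                 list(rows = 6:10, cols = 1:5, label = 2L),
                                 list(rows = 6:10, cols = 6:10, label = 3L)))
  p <- c(0.42, 0.58)
  radii <- sort(runif(6, 0, 0.8))
  prev <- integer(0)
  for (r in radii) {
    cur <- segments_near_point(p, r, sm)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the health index averages levels of qualifying segments", {
  sm <- grid_segmap(10, 10, list(list(rows = 1:10, cols = 1:3, label = 0L),
                                 list(rows = 1:10, cols = 4:6, label = 1L),
                                 list(rows = 1:10, cols = 7:10, label = 2L)))
  labels <- c(`0` = "HL3", `1` = "HL3", `2` = "HL3")
  h <- health_index(c(0.45, 0.5), sm, labels, health_params(r = 0.2))
  expect_equal(h$index, 3)
  expect_equal(h$class, 3L)

  labels2 <- c(`0` = "HL2", `1` = "HL4", `2` = "Soil")
  h2 <- health_index(c(0.35, 0.5), sm, labels2, health_params(r = 0.1))
  expect_equal(h2$index, 3)          # mean of HL2, HL4
  expect_equal(h2$n, 2L)

  # soil-only neighborhood is the no-plant marker
  h3 <- health_index(c(0.9, 0.5), sm, c(`0` = "Soil", `1` = "Soil", `2` = "Soil"),
                     health_params(r = 0.05))
  expect_true(is.na(h3$index))
  expect_equal(h3$n, 0L)

  # including non-vegetation members dilutes the denominator
  h4 <- health_index(c(0.45, 0.5), sm, labels2,
                     health_params(r = 0.2, include_nonvegetation = TRUE))
  expect_equal(h4$n, 3L)
  expect_equal(h4$index, (2 + 4) / 3)
})

test_that("hand-enumerated five-rectangle scene reproduces the disc average", {
  blocks <- list(list(rows = 1:4, cols = 1:4, label = 0L),
                 list(rows = 1:4, cols = 5:10, label = 1L),
                 list(rows = 5:10, cols = 1:4, label = 2L),
                 list(rows = 5:7, cols = 5:10, label = 3L),
                 list(rows = 8:10, cols = 5:10, label = 4L))
  sm <- grid_segmap(10, 10, blocks)
  labels <- c(`0` = "HL1", `1` = "HL2", `2` = "Soil", `3` = "HL5", `4` = "HL4")
  p <- c(0.48, 0.55); r <- 0.12
  # oracle: rectangle-disc test per block
  rects <- list(c(0, 0.4, 0.6, 1.0), c(0.4, 1.0, 0.6, 1.0),
                c(0, 0.4, 0, 0.6), c(0.4, 1.0, 0.3, 0.6), c(0.4, 1.0, 0, 0.3))
  hit <- vapply(rects, function(rc)
    oracle_rect_disc(rc[1], rc[2], rc[3], rc[4], p[1], p[2], r), TRUE)
  hv <- health_value(labels)
  expected <- mean(hv[hit & !is.na(hv)])
  h <- health_index(p, sm, labels, health_params(r = r))
  expect_identical(sort(segments_near_point(p, r, sm)), which(hit) - 1L)
  expect_equal(h$index, expected)
})

test_that("raising any member segment's level never lowers the index", {
  sm <- grid_segmap(10, 10, list(list(rows = 1:10, cols = 1:5, label = 0L),
                                 list(rows = 1:10, cols = 6:10, label = 1L)))
  labels <- c(`0` = "HL2", `1` = "HL3")
  base <- health_index(c(0.5, 0.5), sm, labels, health_params(r = 0.2))$index
  for (lift in c("HL3", "HL4", "HL5")) {
    up <- labels; up["0"] <- lift
    expect_gte(health_index(c(0.5, 0.5), sm, up, health_params(r = 0.2))$index,
               base)
  }
})

test_that("index_all fills every point and ignores point order", {
  sm <- grid_segmap(10, 10, list(list(rows = 1:10, cols = 1:5, label = 0L),
                                 list(rows = 1:10, cols = 6:10, label = 1L)))
  labels <- c(`0` = "HL2", `1` = "HL5")
  pts <- data.frame(x = c(0.2, 0.8, 0.5), y = c(0.5, 0.5, 0.5))
  out <- index_all(pts, sm, labels, health_params(r = 0.1))
  expect_equal(out$health_class, c(2L, 5L, 4L))
  perm <- sample(3)
  out_p <- index_all(pts[perm, ], sm, labels, health_params(r = 0.1))
  expect_equal(out_p$health_index, out$health_index[perm])

  empty <- index_all(pts[0, ], sm, labels)
  expect_equal(nrow(empty), 0L)
})

test_that("NDVI is the normalized band ratio with guarded division", {
  r <- make_raster(c(1, 0.2, 0.5, 0.6), nr = 3, nc = 3)
  nd <- ndvi(r)
  expect_equal(nd$bands$NDVI[1, 1], (0.6 - 0.2) / (0.6 + 0.2))
  r2 <- make_raster(c(1, 0.5, 0.5, 0.5), nr = 2, nc = 2)
  expect_equal(ndvi(r2)$bands$NDVI[1, 1], 0)
  r3 <- make_raster(c(1, 0, 0.5, 0.7), nr = 2, nc = 2)
  expect_equal(ndvi(r3)$bands$NDVI[1, 1], 1)
  r4 <- make_raster(c(1, 0, 0.5, 0), nr = 2, nc = 2)
  expect_true(all(is.na(ndvi(r4)$bands$NDVI)))
  set.seed(47)
  r5 <- rand_raster(15, 15, nb = 4, lo = 0, hi = 50, seed = 47)
  v <- ndvi(r5)$bands$NDVI
  expect_true(all(v[!is.na(v)] >= -1 & v[!is.na(v)] <= 1))
  expect_error(ndvi(ms_raster(list(G = matrix(1, 2, 2)))), "configuration error")
})

test_that("reference matching pairs greedily and flags gaps", {
  ref <- data.frame(x = (1:5) * 0.3, y = 0)
  det <- data.frame(x = (1:3) * 0.3 + 0.02, y = 0.01)
  m <- match_to_reference(det, ref, tol = 0.15)
  expect_equal(nrow(m$pairs), 3L)
  expect_equal(sort(m$unmatched_ref), 4:5)
  expect_length(m$spurious_det, 0L)

  exact <- match_to_reference(ref, ref, tol = 0.15)
  expect_equal(nrow(exact$pairs), 5L)
  expect_length(exact$unmatched_ref, 0L)
  expect_true(all(exact$pairs$dist == 0))

  # tiny jittered instances agree with the brute-force optimal assignment
  for (s in 1:4) {
    set.seed(s * 53)
    n <- sample(4:6, 1)
    refr <- data.frame(x = seq_len(n) * 0.3, y = runif(n, -0.02, 0.02))
    detr <- data.frame(x = seq_len(n) * 0.3 + rnorm(n, 0, 0.03),
                       y = runif(n, -0.02, 0.02))
    keep <- sort(sample(n, n - 1))
    detr <- detr[keep, ]
    got <- match_to_reference(detr, refr, tol = 0.15)$pairs
    opt <- oracle_optimal_pairing(refr, detr, tol = 0.15)
    expect_equal(unname(as.matrix(got[order(got$ref), c("ref", "det")])),
                 unname(opt))
  }
})

test_that("per-row count tables conserve totals in the published layout", {
  pts <- data.frame(health_class = c(1L, 1L, NA, 3L, 5L, NA, 2L),
                    row_id = c(1L, 1L, 1L, 2L, 2L, 2L, 2L))
  tab <- health_count_table(pts)
  expect_equal(dim(tab), c(6L, 3L))
  expect_equal(sum(tab[, "Sum"]), 7)
  expect_equal(unname(tab["\u2205", "Sum"]), 2)
  expect_equal(unname(tab["1", "R1"]), 2)
})
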