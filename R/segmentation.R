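#' Mean-shift parameters
#'
#' @param hs spatial range in pixels (kernel support radius in the image
#'   plane); default 5.
#' @param hr spectral range in raw band units; default 15. Both ranges
#'   normalize the joint spatial-spectral distance, so `hr` must be on the
#'   scale of the raster's values.
#' @param kernel `"epanechnikov"` (default) or `"gaussian"`.
#' @param max_iter maximum mode-seeking iterations per pixel; default 100.
#' @param conv_threshold stop when the joint normalized displacement of a
#'   pixel's mode estimate falls below this; default 0.1.
#' @param min_segment_size segments smaller than this many pixels are merged
#'   into the spectrally nearest adjacent segment; default 4.
#' @param merge_tol two adjacent pixels belong to the same segment when their
#'   spectral modes differ by at most `merge_tol` in range-normalized distance
#'   (Euclidean distance divided by `hr`); default 0.5.
#' @return a `ms_params` object.
#' @export
ms_params <- function(hs = 5, hr = 15, kernel = c("epanechnikov", "gaussian"),
                      max_iter = 100L, conv_threshold = 0.1,
                      min_segment_size = 4L, merge_tol = 0.5) {
  kernel <- match.arg(kernel)
  stopifnot(hs > 0, hr > 0, max_iter >= 1, conv_threshold >= 0,
            min_segment_size >= 0, merge_tol >= 0)
  structure(list(hs = hs, hr = hr, kernel = kernel, max_iter = as.integer(max_iter),
                 conv_threshold = conv_threshold,
                 min_segment_size = as.integer(min_segment_size),
                 merge_tol = merge_tol),
            class = "ms_params")
}

band_matrix <- function(raster) {
  do.call(cbind, lapply(raster$bands, as.vector))
}

#' Mean-shift filtering of a multispectral raster
#'
#' Runs the joint spatial-spectral mode-seeking iteration for every pixel:
#' starting from the pixel's own position and spectral vector, the estimate
#' repeatedly moves to the kernel-weighted mean of the neighboring pixels
#' lying within spatial range `hs` and spectral range `hr`, until the
#' displacement drops below `conv_threshold` or `max_iter` is reached.
#'
#' @param raster an [ms_raster].
#' @param params an [ms_params].
#' @return list with `spatial` (n-pixel x 2 matrix of converged (col, row)
#'   positions, 0-based pixel units), `spectral` (n-pixel x n-band matrix of
#'   spectral modes), `iterations`, and the grid dimensions. Pixel order is
#'   column-major (R matrix order).
#' @export
mean_shift_filter <- function(raster, params = ms_params()) {
  bm <- band_matrix(raster)
  valid <- !as.vector(raster$nodata_mask)
  if (any(!is.finite(bm[valid, ])))
    stop("input validation error: non-finite pixel values outside nodata mask",
         call. = FALSE)
  d <- raster_dim(raster)
  res <- ms_filter_cpp(bm, d[1], d[2], params$hs, params$hr,
                       if (params$kernel == "epanechnikov") 0L else 1L,
                       params$max_iter, params$conv_threshold,
                       as.vector(raster$nodata_mask))
  colnames(res$spectral) <- names(raster$bands)
  res$dim <- d
  res
}

#' Merge filtered modes into a segment map
#'
#' Adjacent (4-connected) pixels whose spectral modes agree within the merge
#' tolerance are unified into one segment; segments smaller than
#' `min_segment_size` pixels are absorbed by the adjacent segment with the
#' nearest spectral mode (ties broken by lower label). Labels are dense
#' integers from 0 in raster scan order of first occurrence; nodata pixels
#' get label -1.
#'
#' @param modes output of [mean_shift_filter()].
#' @param params the [ms_params] used for filtering.
#' @param raster the source [ms_raster] (for world georeferencing).
#' @return a `segment_map`: list with `label_grid` (integer matrix), and
#'   `segments` (data.frame: `label`, `pixel_count`, `sx`, `sy` spatial mode
#'   in pixel units, one `mode_<band>` column per band).
#' @export
merge_modes_to_segments <- function(modes, params, raster) {
  nr <- modes$dim[1]; nc <- modes$dim[2]
  npix <- nr * nc
  spec <- modes$spectral
  valid <- !as.vector(raster$nodata_mask)

  edges <- adjacency_edges(nr, nc, spec, valid, params$hr * params$merge_tol)
  membership <- pixel_components(npix, edges, valid)

  lab <- membership
  lab[!valid] <- NA_integer_

  if (params$min_segment_size > 0L)
    lab <- absorb_small_segments(lab, nr, nc, spec, params$min_segment_size)

  lab <- relabel_scan_order(lab, nr, nc)
  segment_map_from_labels(lab, nr, nc, spec, modes$spatial, raster)
}

# 4-neighbor pixel pairs whose spectral modes are within tol (raw band units)
adjacency_edges <- function(nr, nc, spec, valid, tol) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pair_block <- function(a, b) {
    ok <- valid[a] & valid[b]
    a <- a[ok]; b <- b[ok]
    d2 <- rowSums((spec[a, , drop = FALSE] - spec[b, , drop = FALSE])^2)
    keep <- d2 <= tol^2
    cbind(a[keep], b[keep])
  }
  e <- NULL
  if (nr > 1L) e <- pair_block(as.vector(idx[-nr, ]), as.vector(idx[-1L, ]))
  if (nc > 1L) e <- rbind(e, pair_block(as.vector(idx[, -nc]), as.vector(idx[, -1L])))
  e
}

pixel_components <- function(npix, edges, valid) {
  g <- igraph::make_empty_graph(n = npix, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  comp[!valid] <- NA_integer_
  as.integer(comp)
}

absorb_small_segments <- function(lab, nr, nc, spec, min_size) {
  repeat {
    sizes <- table(lab)
    small <- as.integer(names(sizes)[sizes < min_size])
    if (!length(small)) break
    means <- segment_mode_means(lab, spec)
    nbrs <- label_adjacency(lab, nr, nc)
    # union-find keeps chained merges within one pass adjacency-correct: a
    # candidate that was itself absorbed resolves to its live root, whose
    # region still touches s
    maxl <- max(lab, na.rm = TRUE)
    parent <- seq_len(maxl + 1L)
    find_root <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    changed <- FALSE
    for (s in sort(small)) {
      if (find_root(s + 1L) != s + 1L) next      # absorbed earlier this pass
      cand <- nbrs[[as.character(s)]]
      if (is.null(cand)) next
      cand <- setdiff(unique(vapply(cand + 1L, find_root, 0L)) - 1L, s)
      if (!length(cand)) next
      d <- sqrt(colSums((t(means[as.character(cand), , drop = FALSE]) -
                           means[as.character(s), ])^2))
      target <- cand[order(d, cand)][1]
      parent[s + 1L] <- target + 1L
      changed <- TRUE
    }
    if (!changed) break                     # isolated small islands stay
    roots <- vapply(seq_len(maxl + 1L), find_root, 0L)
    lab <- roots[lab + 1L] - 1L
  }
  lab
}

segment_mode_means <- function(lab, spec) {
  ok <- !is.na(lab)
  m <- rowsum(spec[ok, , drop = FALSE], lab[ok])
  cnt <- as.vector(table(lab[ok])[rownames(m)])
  m / cnt
}

label_adjacency <- function(lab, nr, nc) {
  lg <- matrix(lab, nr, nc)
  pairs <- rbind(cbind(as.vector(lg[-nr, ]), as.vector(lg[-1L, ])),
                 cbind(as.vector(lg[, -nc]), as.vector(lg[, -1L])))
  pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1]))
  split(pairs[, 2], as.character(pairs[, 1]))
}

relabel_scan_order <- function(lab, nr, nc) {
  scan <- as.vector(t(matrix(seq_len(nr * nc), nr, nc)))  # row-major order
  seen <- lab[scan]
  old <- unique(seen[!is.na(seen)])
  match(lab, old) - 1L
}

segment_map_from_labels <- function(lab, nr, nc, spec, spatial, raster) {
  ok <- !is.na(lab)
  key <- lab[ok]
  sm <- rowsum(cbind(spatial[ok, , drop = FALSE], spec[ok, , drop = FALSE]), key)
  cnt <- as.vector(table(key)[rownames(sm)])
  sm <- sm / cnt
  labs <- as.integer(rownames(sm))
  o <- order(labs)
  seg <- data.frame(label = labs[o], pixel_count = cnt[o],
                    sx = sm[o, 1], sy = sm[o, 2])
  modes <- sm[o, -(1:2), drop = FALSE]
  colnames(modes) <- paste0("mode_", colnames(spec))
  seg <- cbind(seg, as.data.frame(modes))
  rownames(seg) <- NULL
  lg <- matrix(ifelse(is.na(lab), -1L, lab), nr, nc)
  structure(list(label_grid = lg, segments = seg,
                 band_names = colnames(spec),
                 origin = raster$origin, pixel_size = raster$pixel_size,
                 crs_id = raster$crs_id),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d x %d px, %d segment(s)\n",
              nrow(x$label_grid), ncol(x$label_grid), nrow(x$segments)))
  invisible(x)
}

#' Segment a raster (mean-shift filter + mode merging)
#'
#' @inheritParams mean_shift_filter
#' @return a `segment_map` (see [merge_modes_to_segments()]).
#' @export
segment_raster <- function(raster, params = ms_params()) {
  merge_modes_to_segments(mean_shift_filter(raster, params), params, raster)
}

#' Tiled large-scale segmentation
#'
#' Processes the raster tile by tile (each tile filtered with a surrounding
#' margin of context pixels, of which only the core is kept), then merges the
#' assembled mode grids globally so segments crossing tile borders are
#' unified. Equivalent to the untiled run wherever a pixel's mode does not
#' depend on context farther than `margin` pixels away.
#'
#' @inheritParams mean_shift_filter
#' @param tile tile edge length in pixels; must exceed `2 * margin`.
#' @param margin overlap margin in pixels; default
#'   `ceiling(2 * hs * sqrt(max_iter))` capped at `tile / 2 - 1`.
#' @return a `segment_map`.
#' @export
segment_tiled <- function(raster, params = ms_params(), tile = 512L,
                          margin = NULL) {
  d <- raster_dim(raster)
  if (is.null(margin))
    margin <- min(ceiling(2 * params$hs * sqrt(params$max_iter)),
                  floor(tile / 2) - 1L)
  margin <- as.integer(margin)
  if (tile <= 2L * margin)
    stop("configuration error: tile must exceed 2 * margin", call. = FALSE)
  if (tile < 2 * params$hs + 1)
    stop("configuration error: tile smaller than kernel support", call. = FALSE)

  nb <- length(raster$bands)
  spat <- matrix(NA_real_, d[1] * d[2], 2)
  spec <- matrix(NA_real_, d[1] * d[2], nb)
  iters <- integer(d[1] * d[2])
  for (r0 in seq(1L, d[1], by = tile)) {
    for (c0 in seq(1L, d[2], by = tile)) {
      r1 <- min(r0 + tile - 1L, d[1]); c1 <- min(c0 + tile - 1L, d[2])
      rr <- max(1L, r0 - margin):min(d[1], r1 + margin)
      cc <- max(1L, c0 - margin):min(d[2], c1 + margin)
      sub <- ms_raster(lapply(raster$bands, function(b) b[rr, cc, drop = FALSE]),
                       origin = c(0, 0), pixel_size = raster$pixel_size,
                       nodata_mask = raster$nodata_mask[rr, cc, drop = FALSE])
      m <- mean_shift_filter(sub, params)
      # keep the core, translating tile-local modes back to global coordinates
      core_r <- r0:r1; core_c <- c0:c1
      loc_r <- core_r - rr[1] + 1L; loc_c <- core_c - cc[1] + 1L
      loc_idx <- as.vector(outer(loc_r, (loc_c - 1L) * length(rr), `+`))
      glob_idx <- as.vector(outer(core_r, (core_c - 1L) * d[1], `+`))
      spat[glob_idx, 1] <- m$spatial[loc_idx, 1] + (cc[1] - 1L)
      spat[glob_idx, 2] <- m$spatial[loc_idx, 2] + (rr[1] - 1L)
      spec[glob_idx, ] <- m$spectral[loc_idx, , drop = FALSE]
      iters[glob_idx] <- m$iterations[loc_idx]
    }
  }
  colnames(spec) <- names(raster$bands)
  modes <- list(spatial = spat, spectral = spec, iterations = iters, dim = d)
  merge_modes_to_segments(modes, params, raster)
}

#' Segment footprint polygons
#'
#' Traces the outer boundary of each segment's pixel region as a rectilinear
#' ring in world coordinates (holes, which are rare for mean-shift segments,
#' are not carried; the outer ring is the footprint).
#'
#' @param segmap a `segment_map`.
#' @return named list: segment label (as character) -> closed ring matrix
#'   (n x 2, world coordinates).
#' @export
segment_footprints <- function(segmap) {
  lg <- segmap$label_grid
  nr <- nrow(lg); nc <- ncol(lg)
  labs <- segmap$segments$label
  out <- vector("list", length(labs))
  names(out) <- as.character(labs)
  for (i in seq_along(labs)) {
    out[[i]] <- trace_outer_ring(lg == labs[i], segmap)
  }
  out
}

# Outer boundary ring of a 4-connected pixel region, via directed edge
# chaining on integer cell corners (interior kept on the left).
trace_outer_ring <- function(mask, segmap) {
  nr <- nrow(mask); nc <- ncol(mask)
  pix <- which(mask, arr.ind = TRUE)
  r <- pix[, 1] - 1L; c <- pix[, 2] - 1L          # 0-based
  inside <- function(rr, cc) {
    ok <- rr >= 0L & rr < nr & cc >= 0L & cc < nc
    res <- logical(length(rr))
    res[ok] <- mask[cbind(rr[ok] + 1L, cc[ok] + 1L)]
    res
  }
  # corner key: (col, row) with col in 0..nc, row in 0..nr
  key <- function(cc, rr) cc * (nr + 1L) + rr
  es <- list()
  top <- !inside(r - 1L, c)
  es[[1]] <- cbind(key(c + 1L, r), key(c, r))[top, , drop = FALSE]
  bot <- !inside(r + 1L, c)
  es[[2]] <- cbind(key(c, r + 1L), key(c + 1L, r + 1L))[bot, , drop = FALSE]
  lef <- !inside(r, c - 1L)
  es[[3]] <- cbind(key(c, r), key(c, r + 1L))[lef, , drop = FALSE]
  rig <- !inside(r, c + 1L)
  es[[4]] <- cbind(key(c + 1L, r + 1L), key(c + 1L, r))[rig, , drop = FALSE]
  edges <- do.call(rbind, es)

  used <- rep(FALSE, nrow(edges))
  starts <- split(seq_len(nrow(edges)), edges[, 1])
  rings <- list(); areas <- numeric()
  while (any(!used)) {
    e0 <- which(!used)[1]
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, edges[e, 1])
      nxt <- starts[[as.character(edges[e, 2])]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      e <- nxt[1]
    }
    path <- c(path, edges[e, 2])
    cc <- path %/% (nr + 1L); rr <- path %% (nr + 1L)
    x <- segmap$origin[1] + cc * segmap$pixel_size[1]
    y <- segmap$origin[2] - rr * segmap$pixel_size[2]
    ring <- cbind(x, y)
    a <- sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)]) / 2
    rings[[length(rings) + 1L]] <- ring
    areas <- c(areas, abs(a))
  }
  rings[[which.max(areas)]]
}

#' Export segments as a polygon vector layer
#'
#' @param segmap a `segment_map`.
#' @param labels optional named vector (segment label as name -> class token)
#'   added as a `class` attribute.
#' @return a [vector_layer] of polygon features with attributes `label`,
#'   `pixel_count` and the per-band spectral modes.
#' @export
segments_to_layer <- function(segmap, labels = NULL) {
  fp <- segment_footprints(segmap)
  feats <- lapply(seq_len(nrow(segmap$segments)), function(i) {
    s <- segmap$segments[i, ]
    attrs <- c(list(label = s$label, pixel_count = s$pixel_count),
               as.list(s[grep("^mode_", names(s))]))
    if (!is.null(labels)) attrs$class <- unname(labels[as.character(s$label)])
    f <- polygon_feature(fp[[as.character(s$label)]])
    f$attributes <- attrs
    f
  })
  vector_layer(feats, segmap$crs_id)
}

#' Check segment-map structural invariants
#'
#' Asserts the partition property (every non-nodata pixel has exactly one
#' dense label), 4-connectivity of every segment, pixel-count conservation,
#' and containment of each spectral mode in the raster's per-band envelope.
#' Used by tests and callable on any pipeline run.
#'
#' @param segmap a `segment_map`.
#' @param raster the source [ms_raster] (optional; enables the envelope check).
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_segment_map <- function(segmap, raster = NULL) {
  lg <- segmap$label_grid
  seg <- segmap$segments
  labs <- sort(unique(as.vector(lg[lg >= 0L])))
  if (!identical(labs, sort(seg$label)))
    stop("label grid and segment table disagree", call. = FALSE)
  if (length(labs) && !identical(as.integer(labs), seq_along(labs) - 1L))
    stop("labels are not dense integers from 0", call. = FALSE)
  if (sum(seg$pixel_count) != sum(lg >= 0L))
    stop("pixel counts do not sum to non-nodata pixels", call. = FALSE)
  for (l in seg$label) {
    m <- lg == l
    comp <- connected_true_regions(m)
    if (max(comp) != 1L)
      stop("segment ", l, " is not 4-connected", call. = FALSE)
  }
  if (!is.null(raster)) {
    for (b in seq_along(segmap$band_names)) {
      bn <- segmap$band_names[b]
      v <- raster$bands[[bn]][!raster$nodata_mask]
      mo <- seg[[paste0("mode_", bn)]]
      if (any(mo < min(v) - 1e-9 | mo > max(v) + 1e-9))
        stop("spectral mode outside input envelope for band ", bn, call. = FALSE)
    }
  }
  invisible(TRUE)
}
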